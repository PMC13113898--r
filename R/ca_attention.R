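# Coordinate attention: factorizes global pooling into two directional 1-D
# pools so the channel gates retain position along one axis each, then
# reweights the map multiplicatively with both gates.

#' Directional global average pooling
#'
#' Pools a C x H x W feature map along each spatial axis separately: `z_h`
#' averages every row over the width, `z_w` averages every column over the
#' height. These are the direction-aware descriptors that coordinate attention
#' builds its gates from.
#'
#' @param x numeric array with dim c(C, H, W)
#' @return list with `z_h` (C x H matrix) and `z_w` (C x W matrix)
#' @examples
#' x <- array(1:4, dim = c(1, 2, 2))
#' directional_pool(x)
#' @export
directional_pool <- function(x) {
  d <- dim(x)
  if (length(d) != 3L || any(d < 1L)) stop("x must be a C x H x W array with positive dims")
  list(z_h = apply(x, c(1, 2), mean), z_w = apply(x, c(1, 3), mean))
}

#' Coordinate attention module
#'
#' Builds the attention block: directional pooling, a shared 1x1 transform
#' (with BN and hard-swish) over the concatenated descriptors, two restoring
#' 1x1 transforms, logistic gates, and multiplicative reweighting. The
#' intermediate width is `max(floor_channels, channels / reduction)`.
#'
#' @param channels input/output channel count
#' @param reduction reduction ratio for the shared transform (default 32)
#' @param floor_channels lower bound on the intermediate width (default 8)
#' @return an edgebcs module
#' @export
ca_module <- function(channels, reduction = 32L, floor_channels = 8L) {
  mid <- max(as.integer(floor_channels), channels %/% as.integer(reduction), 1L)
  new_module("m_ca", channels = channels, mid = mid,
             conv1 = m_conv(channels, mid, 1, act = "hardswish", bn = TRUE),
             conv_h = m_conv(mid, channels, 1, act = "identity", bn = FALSE, bias = TRUE),
             conv_w = m_conv(mid, channels, 1, act = "identity", bn = FALSE, bias = TRUE))
}

fwd.m_ca <- function(m, x, train = FALSE) {
  d <- dim(x$value)
  H <- d[2]; W <- d[3]
  z_h <- op_mean_dim(x, 3L)                      # (C, H, 1)
  z_w <- op_reshape(op_mean_dim(x, 2L), c(d[1], W, 1L))  # (C, W, 1)
  f <- fwd(m$conv1, op_cat(list(z_h, z_w), 2L), train)   # (mid, H+W, 1)
  f_h <- op_narrow(f, 2L, 1L, H)
  f_w <- op_narrow(f, 2L, H + 1L, W)
  g_h <- op_act(fwd(m$conv_h, f_h, train), "sigmoid")            # (C, H, 1)
  g_w <- op_act(fwd(m$conv_w, f_w, train), "sigmoid")            # (C, W, 1)
  g_w <- op_reshape(g_w, c(d[1], 1L, W))
  op_mul(op_mul(x, g_h), g_w)
}

mod_profile.m_ca <- function(m, inshape) {
  C <- inshape[1]; H <- inshape[2]; W <- inshape[3]
  p1 <- mod_profile(m$conv1, c(C, H + W, 1L))
  ph <- mod_profile(m$conv_h, c(m$mid, H, 1L))
  pw <- mod_profile(m$conv_w, c(m$mid, W, 1L))
  elt <- 2 * C * H * W  # two gate multiplications per element
  prof(inshape, p1$flops + ph$flops + pw$flops + elt,
       p1$params + ph$params + pw$params)
}

mod_params.m_ca <- function(m)
  collect_params(list(conv1 = m$conv1, conv_h = m$conv_h, conv_w = m$conv_w))

mod_fuse.m_ca <- function(m) {
  mod_fuse(m$conv1); mod_fuse(m$conv_h); mod_fuse(m$conv_w)
  invisible(m)
}

#' Apply a coordinate attention module to a feature map
#'
#' @param module a module from [ca_module()]
#' @param x numeric array with dim c(C, H, W)
#' @param train logical; use batch statistics for BN when TRUE
#' @return array of the same shape as `x`
#' @export
ca_forward <- function(module, x, train = FALSE) {
  if (dim(x)[1] != module$channels) stop("channel mismatch between input and module")
  fwd(module, tz_const(x), train)$value
}
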