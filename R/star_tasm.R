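# Star-operation texture block and the TASM stage that replaces C3k2
# bottleneck units. The star core maps features onto an implicitly
# high-dimensional space via the elementwise product of two linear
# projections; large-kernel depthwise convolutions bracket it (BN before the
# core, deliberately no BN after, so the refined high-frequency response is
# not re-normalized) and a residual connection closes the block.

#' Star texture block
#'
#' 7x7 depthwise pre-convolution (with BN), two parallel 1x1 expansions to
#' `expansion * channels`, ReLU6-gated elementwise product, 1x1 projection
#' back to `channels`, 7x7 depthwise post-convolution (no BN), residual add.
#'
#' @param channels feature channels C
#' @param expansion branch width multiplier (C' = expansion * C)
#' @param kernel depthwise kernel size (odd; default 7)
#' @return an edgebcs module
#' @export
star_block <- function(channels, expansion = 3, kernel = 7L) {
  stopifnot(kernel %% 2L == 1L)
  cexp <- max(as.integer(round(channels * expansion)), channels)
  new_module("m_star", channels = channels, cexp = cexp, kernel = kernel,
             dw_in = m_conv(channels, channels, kernel, g = channels,
                            act = "identity", bn = TRUE),
             w1 = m_conv(channels, cexp, 1, act = "identity", bn = FALSE, bias = TRUE),
             w2 = m_conv(channels, cexp, 1, act = "identity", bn = FALSE, bias = TRUE),
             wout = m_conv(cexp, channels, 1, act = "identity", bn = FALSE, bias = TRUE),
             dw_out = m_conv(channels, channels, kernel, g = channels,
                             act = "identity", bn = FALSE, bias = TRUE))
}

fwd.m_star <- function(m, x, train = FALSE) {
  xp <- fwd(m$dw_in, x, train)
  x1 <- fwd(m$w1, xp, train)
  x2 <- fwd(m$w2, xp, train)
  ystar <- op_mul(op_act(x1, "relu6"), x2)
  yref <- fwd(m$dw_out, fwd(m$wout, ystar, train), train)
  op_add(yref, x)
}

mod_profile.m_star <- function(m, inshape) {
  C <- inshape[1]; H <- inshape[2]; W <- inshape[3]
  fl <- 0; np <- 0
  for (ch in list(m$dw_in, m$w1, m$w2, m$wout, m$dw_out)) {
    shp <- c(ch$cin, H, W)
    p <- mod_profile(ch, shp)
    fl <- fl + p$flops; np <- np + p$params
  }
  fl <- fl + m$cexp * H * W + C * H * W  # star product + residual add
  prof(inshape, fl, np)
}

mod_params.m_star <- function(m)
  collect_params(list(dw_in = m$dw_in, w1 = m$w1, w2 = m$w2,
                      wout = m$wout, dw_out = m$dw_out))

mod_fuse.m_star <- function(m) {
  fuse_children(list(m$dw_in, m$w1, m$w2, m$wout, m$dw_out))
  invisible(m)
}

#' Apply a star block to a feature map
#' @param module a module from [star_block()]
#' @param x numeric array, dim c(C, H, W)
#' @param train logical; BN in batch-statistics mode when TRUE
#' @return array of the same shape
#' @export
star_forward <- function(module, x, train = FALSE) {
  if (dim(x)[1] != module$channels) stop("channel mismatch between input and module")
  fwd(module, tz_const(x), train)$value
}

#' Pixelwise star core on plain arrays (reference surface)
#'
#' Computes relu6(W1 x + b1) * (W2 x + b2) per pixel for 1x1 projections,
#' exposed so the high-order mapping can be inspected without the surrounding
#' depthwise convolutions.
#'
#' @param x array c(C, H, W)
#' @param W1,W2 matrices C' x C
#' @param b1,b2 length-C' bias vectors
#' @return array c(C', H, W)
#' @export
star_core <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])        # C x (H*W)
  y1 <- pmin(pmax(W1 %*% xm + b1, 0), 6)
  y2 <- W2 %*% xm + b2
  array(y1 * y2, dim = c(nrow(W1), d[2], d[3]))
}

#' TASM stage: C3k2 topology with star-block bottleneck units
#'
#' Keeps the split/merge skeleton of the C3k2 stage (1x1 expansion to two
#' branches, n sequential units on one branch with every intermediate output
#' retained, 1x1 merge) and replaces each bottleneck unit with a
#' [star_block()].
#'
#' @param c1,c2 input and output channels
#' @param n number of star units (>= 1)
#' @param e hidden split ratio (default 0.5)
#' @param expansion star branch width multiplier
#' @return an edgebcs module
#' @export
tasm_module <- function(c1, c2, n = 1L, e = 0.5, expansion = 3) {
  if (n < 1L) stop("n must be >= 1")
  ch <- max(as.integer(round(c2 * e)), 1L)
  new_module("m_tasm", c1 = c1, c2 = c2, n = as.integer(n), ch = ch,
             cv1 = m_conv(c1, 2L * ch, 1),
             blocks = lapply(seq_len(n), function(i) star_block(ch, expansion)),
             cv2 = m_conv((2L + n) * ch, c2, 1))
}

fwd.m_tasm <- function(m, x, train = FALSE) {
  y <- fwd(m$cv1, x, train)
  parts <- list(op_narrow(y, 1L, 1L, m$ch), op_narrow(y, 1L, m$ch + 1L, m$ch))
  for (b in m$blocks)
    parts[[length(parts) + 1L]] <- fwd(b, parts[[length(parts)]], train)
  fwd(m$cv2, op_cat(parts, 1L), train)
}

mod_profile.m_tasm <- function(m, inshape) {
  p1 <- mod_profile(m$cv1, inshape)
  H <- p1$out[2]; W <- p1$out[3]
  fl <- p1$flops; np <- p1$params
  for (b in m$blocks) {
    pb <- mod_profile(b, c(m$ch, H, W))
    fl <- fl + pb$flops; np <- np + pb$params
  }
  p2 <- mod_profile(m$cv2, c((2L + m$n) * m$ch, H, W))
  prof(p2$out, fl + p2$flops, np + p2$params)
}

mod_params.m_tasm <- function(m) {
  ch <- c(list(cv1 = m$cv1), stats::setNames(m$blocks, sprintf("star%d", seq_along(m$blocks))),
          list(cv2 = m$cv2))
  collect_params(ch)
}

mod_fuse.m_tasm <- function(m) {
  fuse_children(c(list(m$cv1, m$cv2), m$blocks))
  invisible(m)
}

#' Apply a TASM stage to a feature map
#' @param module a module from [tasm_module()]
#' @param x numeric array, dim c(C, H, W)
#' @param train logical
#' @return array with `module$c2` channels and unchanged spatial dims
#' @export
tasm_forward <- function(module, x, train = FALSE) {
  if (dim(x)[1] != module$c1) stop("channel mismatch between input and module")
  fwd(module, tz_const(x), train)$value
}
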