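# Position-sensitive feature fusion neck. Every fusion node calibrates the
# lateral (skip) stream with coordinate attention, gates it multiplicatively
# by a logistic 1x1 transform of the resampled incoming stream, and adds the
# incoming stream back:
#
#     F = CA(L) * sigmoid(Conv1x1(U)) + U
#
# Channels are constant through every node (a 1x1 adapter maps mismatched
# laterals onto the node width) and no channel concatenation occurs anywhere
# between pyramid levels. Upsampling is a learned transposed convolution;
# downsampling a stride-2 3x3 convolution. A TASM stage follows each node.

#' PSFF fusion node
#'
#' @param lateral_channels channels of the lateral (skip) feature
#' @param c node channels (gate, fused output and incoming stream channels)
#' @param reduction coordinate-attention reduction ratio
#' @return an edgebcs module; forward takes list(lateral, incoming)
#' @export
psff_fuse_node <- function(lateral_channels, c, reduction = 32L) {
  new_module("m_psff_node", channels = c,
             adapter = if (lateral_channels != c) m_conv(lateral_channels, c, 1) else NULL,
             ca = ca_module(c, reduction),
             gate = m_conv(c, c, 1, act = "identity", bn = FALSE, bias = TRUE))
}

fwd.m_psff_node <- function(m, x, train = FALSE) {
  lateral <- x[[1]]; incoming <- x[[2]]
  if (!identical(dim(lateral$value)[2:3], dim(incoming$value)[2:3]))
    stop("spatial mismatch between lateral and incoming streams")
  if (!is.null(m$adapter)) lateral <- fwd(m$adapter, lateral, train)
  g <- op_act(fwd(m$gate, incoming, train), "sigmoid")
  op_add(op_mul(fwd(m$ca, lateral, train), g), incoming)
}

mod_profile.m_psff_node <- function(m, inshape) {
  # inshape: list(lateral shape, incoming shape)
  fl <- 0; np <- 0
  s <- inshape[[1]]
  if (!is.null(m$adapter)) { p <- mod_profile(m$adapter, s); s <- p$out; fl <- fl + p$flops; np <- np + p$params }
  pca <- mod_profile(m$ca, s)
  pg <- mod_profile(m$gate, inshape[[2]])
  fl <- fl + pca$flops + pg$flops + 2 * prod(s)  # gate mul + add
  np <- np + pca$params + pg$params
  prof(s, fl, np)
}
mod_params.m_psff_node <- function(m) {
  ch <- list(ca = m$ca, gate = m$gate)
  if (!is.null(m$adapter)) ch$adapter <- m$adapter
  collect_params(ch)
}
mod_fuse.m_psff_node <- function(m) {
  fuse_children(list(m$adapter, m$ca, m$gate))
  invisible(m)
}

#' Learned stride-2 upsampling module (transposed convolution)
#' @param cin,cout channel counts
#' @param k kernel size (default 2; 2 and 4 both partition unity on constants)
#' @return an edgebcs module
#' @export
psff_upsample <- function(cin, cout, k = 2L) {
  m_convT(cin, cout, k = k, s = 2L, p = as.integer((k - 2L) %/% 2L))
}

#' PSFF neck over a three-level feature pyramid
#'
#' PAN-style top-down then bottom-up pass; every fusion is a [psff_fuse_node()]
#' followed by a [tasm_module()] stage. Output strides and channel counts
#' equal the input pyramid's.
#'
#' @param channels per-level node channels c(P3, P4, P5)
#' @param lateral_channels channels of the incoming backbone laterals
#'   (defaults to `channels`; a 1x1 adapter bridges any mismatch)
#' @param expansion star-block expansion ratio inside the TASM stages
#' @param up_kernel transposed-convolution kernel size
#' @return an edgebcs module; forward takes/returns a list of three maps
#' @export
psff_neck <- function(channels, lateral_channels = channels,
                      expansion = 3, up_kernel = 2L,
                      repeats = c(1L, 1L, 1L, 1L)) {
  c3 <- channels[1]; c4 <- channels[2]; c5 <- channels[3]
  new_module("m_psff_neck", channels = channels,
    up54 = psff_upsample(lateral_channels[3], c4, up_kernel),
    node4 = psff_fuse_node(lateral_channels[2], c4),
    stage4 = tasm_module(c4, c4, n = repeats[2], expansion = expansion),
    up43 = psff_upsample(c4, c3, up_kernel),
    node3 = psff_fuse_node(lateral_channels[1], c3),
    stage3 = tasm_module(c3, c3, n = repeats[1], expansion = expansion),
    down34 = m_conv(c3, c4, 3, s = 2),
    node4b = psff_fuse_node(c4, c4),
    stage4b = tasm_module(c4, c4, n = repeats[3], expansion = expansion),
    down45 = m_conv(c4, c5, 3, s = 2),
    node5 = psff_fuse_node(lateral_channels[3], c5),
    stage5 = tasm_module(c5, c5, n = repeats[4], expansion = expansion))
}

fwd.m_psff_neck <- function(m, x, train = FALSE) {
  p3 <- x[[1]]; p4 <- x[[2]]; p5 <- x[[3]]
  u4 <- fwd(m$up54, p5, train)
  n4 <- fwd(m$stage4, fwd(m$node4, list(p4, u4), train), train)
  u3 <- fwd(m$up43, n4, train)
  n3 <- fwd(m$stage3, fwd(m$node3, list(p3, u3), train), train)
  d4 <- fwd(m$down34, n3, train)
  n4b <- fwd(m$stage4b, fwd(m$node4b, list(n4, d4), train), train)
  d5 <- fwd(m$down45, n4b, train)
  n5 <- fwd(m$stage5, fwd(m$node5, list(p5, d5), train), train)
  list(n3, n4b, n5)
}

mod_profile.m_psff_neck <- function(m, inshape) {
  s3 <- inshape[[1]]; s4 <- inshape[[2]]; s5 <- inshape[[3]]
  fl <- 0; np <- 0; cc <- 0
  acc <- function(p) {
    force(p)  # nested acc() promises must update the totals before we read them
    fl <<- fl + p$flops; np <<- np + p$params; cc <<- cc + p$concats
    p$out
  }
  u4 <- acc(mod_profile(m$up54, s5))
  n4 <- acc(mod_profile(m$stage4, acc(mod_profile(m$node4, list(s4, u4)))))
  u3 <- acc(mod_profile(m$up43, n4))
  n3 <- acc(mod_profile(m$stage3, acc(mod_profile(m$node3, list(s3, u3)))))
  d4 <- acc(mod_profile(m$down34, n3))
  n4b <- acc(mod_profile(m$stage4b, acc(mod_profile(m$node4b, list(n4, d4)))))
  d5 <- acc(mod_profile(m$down45, n4b))
  n5 <- acc(mod_profile(m$stage5, acc(mod_profile(m$node5, list(s5, d5)))))
  prof(list(n3, n4b, n5), fl, np, cc)
}

psff_children <- function(m)
  list(up54 = m$up54, node4 = m$node4, stage4 = m$stage4,
       up43 = m$up43, node3 = m$node3, stage3 = m$stage3,
       down34 = m$down34, node4b = m$node4b, stage4b = m$stage4b,
       down45 = m$down45, node5 = m$node5, stage5 = m$stage5)

mod_params.m_psff_neck <- function(m) collect_params(psff_children(m))
mod_fuse.m_psff_neck <- function(m) { fuse_children(psff_children(m)); invisible(m) }

#' Gated fusion of a lateral and an incoming stream (array interface)
#' @param node a module from [psff_fuse_node()]
#' @param lateral,incoming arrays c(C, H, W) with equal spatial dims
#' @param train logical
#' @return fused array with the node's channel count
#' @export
gated_fuse <- function(node, lateral, incoming, train = FALSE) {
  fwd(node, list(tz_const(lateral), tz_const(incoming)), train)$value
}

#' Learned upsampling (array interface)
#' @param module a module from [psff_upsample()]
#' @param x array c(C, H, W)
#' @param train logical
#' @return array with doubled spatial dims
#' @export
upsample_learned <- function(module, x, train = FALSE)
  fwd(module, tz_const(x), train)$value
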