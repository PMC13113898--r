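# Efficient grouped detection head: a grouped-convolution stem with a
# learnable alpha-weighted identity residual, one grouped refinement layer,
# and bias-only 1x1 prediction maps (no normalization after refinement, so BN
# folds losslessly into the convolutions at inference).

#' FLOPs of a standard vs. grouped convolution layer
#'
#' For a K x K convolution with C input and C output channels on an H x W map,
#' the dense multiply-accumulate count is H * W * K^2 * C^2; partitioning the
#' channels into g independent groups divides it by g.
#'
#' @param H,W spatial dims of the output map
#' @param K kernel size
#' @param C channel count (input = output)
#' @param g number of groups (C must be divisible by g)
#' @return named numeric vector with `flops_std` and `flops_gc`
#' @examples
#' grouped_conv_flops(8, 8, 3, 16, 1)
#' @export
grouped_conv_flops <- function(H, W, K, C, g) {
  args <- c(H = H, W = W, K = K, C = C, g = g)
  if (any(args <= 0) || any(args != as.integer(args)))
    stop("all arguments must be positive integers")
  if (C %% g != 0) stop("C must be divisible by g")
  std <- H * W * K^2 * C^2
  c(flops_std = std, flops_gc = std / g)
}

# round channel count up to a multiple of the group width
ceil_to <- function(c, w) as.integer(ceiling(c / w) * w)

#' Single-level efficient grouped detection head
#'
#' @param c input channels at this level; if not divisible by `group_width` a
#'   1x1 adapter lifts it to the next multiple
#' @param nc number of classes
#' @param reg_max regression bins per box side (distribution-focal encoding)
#' @param group_width fixed channels per convolution group (default 16)
#' @return an edgebcs module producing class logits and box-regression maps
#' @export
egdh_level <- function(c, nc, reg_max = 16L, group_width = 16L) {
  adapter <- NULL
  cw <- c
  if (c %% group_width != 0L) {
    cw <- ceil_to(c, group_width)
    adapter <- m_conv(c, cw, 1)
  }
  g <- cw %/% group_width
  new_module("m_egdh_level", cin = c, cw = cw, g = g, nc = nc, reg_max = reg_max,
             adapter = adapter,
             stem1 = m_conv(cw, cw, 3, g = g),
             stem2 = m_conv(cw, cw, 3, g = g),
             alpha = tz_param(array(1, 1L)),
             refine = m_conv(cw, cw, 3, g = g, act = "identity"),
             cls = m_conv(cw, nc, 1, act = "identity", bn = FALSE, bias = TRUE),
             reg = m_conv(cw, 4L * reg_max, 1, act = "identity", bn = FALSE, bias = TRUE))
}

# family-standard prediction bias priors: classification starts at the sparse
# foreground prior for its stride, box-distribution logits at 1
init_head_biases <- function(cls_conv, reg_conv, nc, stride) {
  cls_conv$b$value <- rep(log(5 / nc / (640 / stride)^2), nc)
  reg_conv$b$value <- rep(1, length(reg_conv$b$value))
  invisible(NULL)
}

fwd.m_egdh_level <- function(m, x, train = FALSE) {
  if (!is.null(m$adapter)) x <- fwd(m$adapter, x, train)
  s <- fwd(m$stem2, fwd(m$stem1, x, train), train)
  f <- op_add(op_mul(x, m$alpha), s)
  r <- fwd(m$refine, f, train)
  list(cls = fwd(m$cls, r, train), reg = fwd(m$reg, r, train))
}

mod_profile.m_egdh_level <- function(m, inshape) {
  fl <- 0; np <- 1  # alpha
  s <- inshape
  if (!is.null(m$adapter)) { p <- mod_profile(m$adapter, s); s <- p$out; fl <- fl + p$flops; np <- np + p$params }
  for (ch in list(m$stem1, m$stem2)) { p <- mod_profile(ch, s); fl <- fl + p$flops; np <- np + p$params }
  fl <- fl + 2 * prod(s)  # alpha-scaled residual: one mul + one add per element
  pr <- mod_profile(m$refine, s)
  pc <- mod_profile(m$cls, s)
  pg <- mod_profile(m$reg, s)
  fl <- fl + pr$flops + pc$flops + pg$flops
  np <- np + pr$params + pc$params + pg$params
  prof(list(cls = pc$out, reg = pg$out), fl, np)
}

mod_params.m_egdh_level <- function(m) {
  ch <- list(stem1 = m$stem1, stem2 = m$stem2, refine = m$refine,
             cls = m$cls, reg = m$reg, alpha = m$alpha)
  if (!is.null(m$adapter)) ch$adapter <- m$adapter
  collect_params(ch)
}

mod_fuse.m_egdh_level <- function(m) {
  fuse_children(list(m$adapter, m$stem1, m$stem2, m$refine, m$cls, m$reg))
  invisible(m)
}

#' Multi-level efficient grouped detection head
#' @param channels per-level input channels
#' @param nc class count
#' @param reg_max regression bins per side
#' @return an edgebcs module
#' @export
egdh_head <- function(channels, nc, reg_max = 16L) {
  levels <- lapply(channels, egdh_level, nc = nc, reg_max = reg_max)
  for (i in seq_along(levels))
    init_head_biases(levels[[i]]$cls, levels[[i]]$reg, nc, c(8, 16, 32)[i])
  new_module("m_egdh", nc = nc, reg_max = reg_max, channels = channels,
             levels = levels)
}

fwd.m_egdh <- function(m, x, train = FALSE)
  lapply(seq_along(x), function(i) fwd(m$levels[[i]], x[[i]], train))

mod_profile.m_egdh <- function(m, inshape) {
  fl <- 0; np <- 0
  outs <- vector("list", length(inshape))
  for (i in seq_along(inshape)) {
    p <- mod_profile(m$levels[[i]], inshape[[i]])
    outs[[i]] <- p$out; fl <- fl + p$flops; np <- np + p$params
  }
  prof(outs, fl, np)
}
mod_params.m_egdh <- function(m)
  collect_params(stats::setNames(m$levels, sprintf("level%d", seq_along(m$levels))))
mod_fuse.m_egdh <- function(m) { fuse_children(m$levels); invisible(m) }
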