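# ---------------------------------------------------------------------------
# Module framework: a module is an environment with parameters, children and a
# class-dispatched forward. Three generics cover the lifecycle:
#   fwd(m, x, train)        value forward on tz_tensors
#   mod_profile(m, inshape) shape propagation + FLOP/parameter accounting
#   mod_params(m)           named list of trainable tensors
#   mod_fuse(m)             fold BN into the preceding convolution (inference)
#
# FLOP convention (frozen): multiply-accumulates x 2 for convolution,
# transposed convolution and matrix products on the BN-fused inference graph;
# explicit elementwise fusion adds/multiplies counted once per element;
# activations, bias adds and pooling not counted.
# ---------------------------------------------------------------------------

new_module <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "edgebcs_module")
  e
}

fwd <- function(m, x, train = FALSE) UseMethod("fwd")
mod_profile <- function(m, inshape) UseMethod("mod_profile")
mod_params <- function(m) UseMethod("mod_params")
mod_fuse <- function(m) UseMethod("mod_fuse")

prof <- function(out, flops = 0, params = 0, concats = 0) {
  list(out = out, flops = flops, params = params, concats = concats)
}

autopad <- function(k) as.integer(k %/% 2)

conv_out_hw <- function(hw, k, s, p) as.integer((hw + 2 * p - k) %/% s + 1)

# Kaiming-normal initialization for a conv weight of dim c(cout, cin_g, k, k)
init_conv_w <- function(cout, cin_g, k) {
  fan_in <- cin_g * k * k
  array(stats::rnorm(cout * cin_g * k * k, sd = sqrt(2 / fan_in)),
        dim = c(cout, cin_g, k, k))
}

new_bn_stats <- function(c) {
  s <- new.env(parent = emptyenv())
  s$mean <- rep(0, c); s$var <- rep(1, c)
  s
}

# -- Conv (+BN +activation) --------------------------------------------------

m_conv <- function(cin, cout, k = 1L, s = 1L, p = NULL, g = 1L,
                   act = "silu", bn = TRUE, bias = !bn) {
  p <- p %||% autopad(k)
  m <- new_module("m_conv", cin = cin, cout = cout, k = as.integer(k),
                  s = as.integer(s), p = as.integer(p), g = as.integer(g),
                  act = act, bn = bn,
                  w = tz_param(init_conv_w(cout, cin %/% g, k)),
                  b = if (bias) tz_param(rep(0, cout)) else NULL,
                  gamma = if (bn) tz_param(rep(1, cout)) else NULL,
                  beta = if (bn) tz_param(rep(0, cout)) else NULL,
                  stats = if (bn) new_bn_stats(cout) else NULL)
  m
}

fwd.m_conv <- function(m, x, train = FALSE) {
  y <- op_conv2d(x, m$w, m$b, stride = m$s, pad = m$p, groups = m$g)
  if (m$bn) y <- op_bn2d(y, m$gamma, m$beta, m$stats, training = train)
  op_act(y, m$act)
}

mod_profile.m_conv <- function(m, inshape) {
  stopifnot(inshape[1] == m$cin)
  ho <- conv_out_hw(inshape[2], m$k, m$s, m$p)
  wo <- conv_out_hw(inshape[3], m$k, m$s, m$p)
  flops <- 2 * ho * wo * m$k^2 * (m$cin / m$g) * m$cout
  npar <- length(m$w$value) +
    (if (!is.null(m$b)) m$cout else 0) + (if (m$bn) 2 * m$cout else 0)
  prof(c(m$cout, ho, wo), flops, npar)
}

mod_params.m_conv <- function(m) {
  ps <- list(w = m$w)
  if (!is.null(m$b)) ps$b <- m$b
  if (m$bn) { ps$gamma <- m$gamma; ps$beta <- m$beta }
  ps
}

#' Fold frozen batch-norm statistics into convolution weights
#'
#' Returns convolution parameters that reproduce the conv -> BN composite
#' exactly (up to floating point), applied per output channel and therefore
#' valid groupwise for grouped convolutions.
#'
#' @param conv_params list with `w` (array cout x cin/g x k x k) and optional `b`
#' @param bn_params list with `gamma`, `beta`, `mean`, `var`, optional `eps`
#' @return list with fused `w` and `b`
#' @export
fuse_conv_bn <- function(conv_params, bn_params) {
  eps <- bn_params$eps %||% 1e-3
  scale <- bn_params$gamma / sqrt(bn_params$var + eps)
  w <- conv_params$w
  d <- dim(w)
  wf <- array(w * scale[slice.index(w, 1)], dim = d)
  b0 <- conv_params$b %||% rep(0, d[1])
  bf <- bn_params$beta + (b0 - bn_params$mean) * scale
  list(w = wf, b = bf)
}

mod_fuse.m_conv <- function(m) {
  if (!m$bn) return(invisible(m))
  fused <- fuse_conv_bn(
    list(w = m$w$value, b = if (!is.null(m$b)) m$b$value else NULL),
    list(gamma = m$gamma$value, beta = m$beta$value,
         mean = m$stats$mean, var = m$stats$var))
  m$w <- tz_param(fused$w)
  m$b <- tz_param(fused$b)
  m$bn <- FALSE; m$gamma <- NULL; m$beta <- NULL; m$stats <- NULL
  invisible(m)
}

# -- Transposed convolution (learned upsampling) -----------------------------

m_convT <- function(cin, cout, k = 2L, s = 2L, p = 0L, act = "silu", bn = TRUE,
                    bias = !bn) {
  fan_in <- cin * k * k
  w <- array(stats::rnorm(cin * cout * k * k, sd = sqrt(2 / fan_in)),
             dim = c(cin, cout, k, k))
  new_module("m_convT", cin = cin, cout = cout, k = as.integer(k),
             s = as.integer(s), p = as.integer(p), act = act, bn = bn,
             w = tz_param(w),
             b = if (bias) tz_param(rep(0, cout)) else NULL,
             gamma = if (bn) tz_param(rep(1, cout)) else NULL,
             beta = if (bn) tz_param(rep(0, cout)) else NULL,
             stats = if (bn) new_bn_stats(cout) else NULL)
}

fwd.m_convT <- function(m, x, train = FALSE) {
  y <- op_convT2d(x, m$w, m$b, stride = m$s, pad = m$p)
  if (m$bn) y <- op_bn2d(y, m$gamma, m$beta, m$stats, training = train)
  op_act(y, m$act)
}

mod_profile.m_convT <- function(m, inshape) {
  stopifnot(inshape[1] == m$cin)
  ho <- (inshape[2] - 1L) * m$s - 2L * m$p + m$k
  wo <- (inshape[3] - 1L) * m$s - 2L * m$p + m$k
  flops <- 2 * inshape[2] * inshape[3] * m$k^2 * m$cin * m$cout
  npar <- length(m$w$value) +
    (if (!is.null(m$b)) m$cout else 0) + (if (m$bn) 2 * m$cout else 0)
  prof(c(m$cout, ho, wo), flops, npar)
}

mod_params.m_convT <- mod_params.m_conv

mod_fuse.m_convT <- function(m) {
  if (!m$bn) return(invisible(m))
  eps <- 1e-3
  scale <- m$gamma$value / sqrt(m$stats$var + eps)
  w <- m$w$value
  wf <- array(w * scale[slice.index(w, 2)], dim = dim(w))
  b0 <- if (!is.null(m$b)) m$b$value else rep(0, m$cout)
  bf <- m$beta$value + (b0 - m$stats$mean) * scale
  m$w <- tz_param(wf); m$b <- tz_param(bf)
  m$bn <- FALSE; m$gamma <- NULL; m$beta <- NULL; m$stats <- NULL
  invisible(m)
}

# -- parameter-free modules --------------------------------------------------

m_upsample <- function() new_module("m_upsample")
fwd.m_upsample <- function(m, x, train = FALSE) op_upsample_nearest2(x)
mod_profile.m_upsample <- function(m, inshape)
  prof(c(inshape[1], 2L * inshape[2], 2L * inshape[3]))
mod_params.m_upsample <- function(m) list()
mod_fuse.m_upsample <- function(m) invisible(m)

m_concat <- function() new_module("m_concat")
fwd.m_concat <- function(m, x, train = FALSE) op_cat(x, 1L)
mod_profile.m_concat <- function(m, inshape) {
  # inshape: list of shapes
  cs <- sum(vapply(inshape, `[`, numeric(1), 1))
  prof(c(cs, inshape[[1]][2], inshape[[1]][3]), concats = 1)
}
mod_params.m_concat <- function(m) list()
mod_fuse.m_concat <- function(m) invisible(m)

# -- generic helpers over children -------------------------------------------

collect_params <- function(children) {
  out <- list()
  for (nm in names(children)) {
    ch <- children[[nm]]
    ps <- if (inherits(ch, "edgebcs_module")) mod_params(ch)
          else if (inherits(ch, "tz_tensor")) list(ch)
          else next
    if (length(ps)) {
      names(ps) <- paste0(nm, ".", names(ps) %||% seq_along(ps))
      out <- c(out, ps)
    }
  }
  out
}

fuse_children <- function(children) {
  for (ch in children) if (inherits(ch, "edgebcs_module")) mod_fuse(ch)
  invisible(NULL)
}

m_seq <- function(mods) new_module("m_seq", mods = mods)
fwd.m_seq <- function(m, x, train = FALSE) {
  for (mm in m$mods) x <- fwd(mm, x, train)
  x
}
mod_profile.m_seq <- function(m, inshape) {
  fl <- 0; np <- 0; cc <- 0
  for (mm in m$mods) {
    p <- mod_profile(mm, inshape)
    inshape <- p$out; fl <- fl + p$flops; np <- np + p$params; cc <- cc + p$concats
  }
  prof(inshape, fl, np, cc)
}
mod_params.m_seq <- function(m) {
  ch <- m$mods; names(ch) <- sprintf("m%d", seq_along(ch))
  collect_params(ch)
}
mod_fuse.m_seq <- function(m) { for (mm in m$mods) mod_fuse(mm); invisible(m) }
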