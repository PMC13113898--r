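#' @useDynLib edgebcs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode autodiff over dense arrays.
#
# A tz_tensor is an environment holding $value (numeric array, feature maps use
# dim c(C, H, W)), $grad, the parent nodes and a backward closure. Graphs are
# built eagerly by the op_* constructors; tz_backward() runs the reverse sweep
# in decreasing creation order. Nodes whose ancestry contains no trainable
# parameter skip bookkeeping entirely, so inference costs almost nothing extra.
# ---------------------------------------------------------------------------

.tz <- new.env(parent = emptyenv())
.tz$id <- 0L

new_tensor <- function(value, requires_grad = FALSE, parents = list(), bwd = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- isTRUE(requires_grad)
  keep <- e$requires_grad || any(vapply(parents, function(p) p$needs, logical(1)))
  e$needs <- keep
  e$parents <- if (keep) parents else list()
  e$bwd <- if (keep) bwd else NULL
  .tz$id <- .tz$id + 1L
  e$id <- .tz$id
  class(e) <- "tz_tensor"
  e
}

#' Create a constant (non-trainable) tensor
#' @param value numeric array
#' @return a tz_tensor
#' @keywords internal
tz_const <- function(value) new_tensor(value)

#' Create a trainable parameter tensor
#' @param value numeric array
#' @return a tz_tensor with gradient tracking enabled
#' @keywords internal
tz_param <- function(value) new_tensor(value, requires_grad = TRUE)

tz_dim <- function(x) { d <- dim(x$value); if (is.null(d)) length(x$value) else d }

#' Run the reverse sweep from a scalar loss
#'
#' Accumulates gradients into every reachable tensor with gradient tracking.
#' @param loss a tz_tensor holding a single number
#' @keywords internal
tz_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # collect reachable grad-carrying nodes
  nodes <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    for (p in n$parents) if (p$needs) stack[[length(stack) + 1L]] <- p
  }
  ord <- ls(nodes)
  ord <- ord[order(as.numeric(ord), decreasing = TRUE)]
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (key in ord) {
    n <- nodes[[key]]
    if (is.null(n$bwd) || is.null(n$grad)) next
    gs <- n$bwd(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!p$needs || is.null(gs[[i]])) next
      g <- gs[[i]]
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
  }
  invisible(loss)
}

#' Null-coalescing helper
#' @param a,b values; `b` is returned when `a` is NULL
#' @return `a` unless it is NULL
#' @name null-coalesce
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

tz_zero_grad <- function(params) for (p in params) p$grad <- NULL

# -- broadcasting helpers ----------------------------------------------------

expand_to <- function(v, d) {
  dv <- dim(v) %||% length(v)
  if (identical(as.integer(dv), as.integer(d))) return(v)
  if (length(v) == 1L) return(array(as.vector(v), dim = d))
  stopifnot(length(dv) == length(d))
  idx <- lapply(seq_along(d), function(i) if (dv[i] == d[i]) seq_len(d[i]) else rep(1L, d[i]))
  array(do.call(`[`, c(list(v), idx)), dim = d)
}

reduce_to <- function(g, d_target) {
  dg <- dim(g) %||% length(g)
  if (length(d_target) == 1L && d_target == 1L) return(array(sum(g), dim = 1L))
  if (identical(as.integer(dg), as.integer(d_target))) return(g)
  keep <- which(as.integer(d_target) == as.integer(dg))
  out <- apply(g, keep, sum)
  array(out, dim = d_target)
}

# -- elementwise arithmetic --------------------------------------------------

op_add <- function(a, b) {
  d <- dim(a$value) %||% length(a$value)
  v <- a$value + expand_to(b$value, d)
  new_tensor(v, parents = list(a, b), bwd = function(g) {
    list(g, reduce_to(g, dim(b$value) %||% length(b$value)))
  })
}

op_sub <- function(a, b) {
  d <- dim(a$value) %||% length(a$value)
  v <- a$value - expand_to(b$value, d)
  new_tensor(v, parents = list(a, b), bwd = function(g) {
    list(g, -reduce_to(g, dim(b$value) %||% length(b$value)))
  })
}

op_mul <- function(a, b) {
  d <- dim(a$value) %||% length(a$value)
  bv <- expand_to(b$value, d)
  v <- a$value * bv
  av <- a$value
  new_tensor(v, parents = list(a, b), bwd = function(g) {
    list(g * bv, reduce_to(g * av, dim(b$value) %||% length(b$value)))
  })
}

op_div <- function(a, b) {
  d <- dim(a$value) %||% length(a$value)
  bv <- expand_to(b$value, d)
  v <- a$value / bv
  av <- a$value
  new_tensor(v, parents = list(a, b), bwd = function(g) {
    list(g / bv, reduce_to(-g * av / (bv * bv), dim(b$value) %||% length(b$value)))
  })
}

op_scale <- function(x, k) {  # k plain numeric scalar
  new_tensor(x$value * k, parents = list(x), bwd = function(g) list(g * k))
}

op_shift <- function(x, k) {
  new_tensor(x$value + k, parents = list(x), bwd = function(g) list(g))
}

op_square <- function(x) {
  xv <- x$value
  new_tensor(xv * xv, parents = list(x), bwd = function(g) list(2 * g * xv))
}

op_sqrt <- function(x, eps = 1e-12) {
  v <- sqrt(x$value + eps)
  new_tensor(v, parents = list(x), bwd = function(g) list(g / (2 * v)))
}

op_abs <- function(x) {
  xv <- x$value
  new_tensor(abs(xv), parents = list(x), bwd = function(g) list(g * sign(xv)))
}

op_atan <- function(x) {
  xv <- x$value
  new_tensor(atan(xv), parents = list(x), bwd = function(g) list(g / (1 + xv * xv)))
}

op_log <- function(x, eps = 0) {
  xv <- x$value + eps
  new_tensor(log(xv), parents = list(x), bwd = function(g) list(g / xv))
}

op_exp <- function(x) {
  v <- exp(x$value)
  new_tensor(v, parents = list(x), bwd = function(g) list(g * v))
}

op_neg <- function(x) op_scale(x, -1)

op_clamp <- function(x, lo = -Inf, hi = Inf) {
  xv <- x$value
  mask <- (xv > lo) & (xv < hi)
  new_tensor(pmin(pmax(xv, lo), hi), parents = list(x), bwd = function(g) list(g * mask))
}

op_pmax <- function(a, b) {
  take_a <- a$value >= b$value
  new_tensor(pmax(a$value, b$value), parents = list(a, b),
             bwd = function(g) list(g * take_a, g * (!take_a)))
}

op_pmin <- function(a, b) {
  take_a <- a$value <= b$value
  new_tensor(pmin(a$value, b$value), parents = list(a, b),
             bwd = function(g) list(g * take_a, g * (!take_a)))
}

op_sum <- function(x) {
  d <- dim(x$value) %||% length(x$value)
  new_tensor(array(sum(x$value), 1L), parents = list(x),
             bwd = function(g) list(array(as.numeric(g), d)))
}

op_mean <- function(x) op_scale(op_sum(x), 1 / length(x$value))

# mean over one margin of a (C,H,W) array, keeping it as size 1
op_mean_dim <- function(x, dim_idx) {
  d <- dim(x$value)
  v <- switch(dim_idx,
    colMeans(matrix(x$value, d[1])),                         # over C -> (H,W)
    rowMeans(matrix(aperm(x$value, c(1, 3, 2)), d[1] * d[3])),  # over H -> (C,W)
    rowMeans(matrix(x$value, d[1] * d[2])))                  # over W -> (C,H)
  dn <- d; dn[dim_idx] <- 1L  # flat order of the kept margins matches dn
  new_tensor(array(v, dim = dn), parents = list(x), bwd = function(g) {
    list(expand_to(array(g, dn), d) / d[dim_idx])
  })
}

# -- activations -------------------------------------------------------------

op_act <- function(x, type) {
  xv <- x$value
  switch(type,
    relu = {
      m <- xv > 0
      new_tensor(xv * m, parents = list(x), bwd = function(g) list(g * m))
    },
    relu6 = {
      m <- (xv > 0) & (xv < 6)
      new_tensor(pmin(pmax(xv, 0), 6), parents = list(x), bwd = function(g) list(g * m))
    },
    sigmoid = {
      s <- 1 / (1 + exp(-xv))
      new_tensor(s, parents = list(x), bwd = function(g) list(g * s * (1 - s)))
    },
    silu = {
      s <- 1 / (1 + exp(-xv))
      new_tensor(xv * s, parents = list(x),
                 bwd = function(g) list(g * (s + xv * s * (1 - s))))
    },
    hardswish = {
      # x * relu6(x + 3) / 6
      r <- pmin(pmax(xv + 3, 0), 6)
      dr <- (xv > -3) & (xv < 3)
      new_tensor(xv * r / 6, parents = list(x),
                 bwd = function(g) list(g * (r / 6 + xv * dr / 6)))
    },
    identity = x,
    stop("unknown activation: ", type)
  )
}

# -- structural ops ----------------------------------------------------------

op_reshape <- function(x, d) {
  d0 <- dim(x$value) %||% length(x$value)
  new_tensor(array(x$value, dim = d), parents = list(x),
             bwd = function(g) list(array(g, dim = d0)))
}

op_cat <- function(xs, dim_idx) {
  ds <- lapply(xs, function(x) dim(x$value))
  v <- do.call(abind3, c(xs_values(xs), list(along = dim_idx)))
  sizes <- vapply(ds, function(d) d[dim_idx], numeric(1))
  new_tensor(v, parents = xs, bwd = function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      idx <- lapply(1:3, function(k) if (k == dim_idx) at + seq_len(sizes[i]) else seq_len(dim(g)[k]))
      out[[i]] <- array(do.call(`[`, c(list(g), idx)), dim = ds[[i]])
      at <- at + sizes[i]
    }
    out
  })
}

xs_values <- function(xs) lapply(xs, function(x) x$value)

# bind 3-d arrays along a margin (base R, no abind dependency)
abind3 <- function(..., along) {
  arrs <- list(...)
  ds <- lapply(arrs, dim)
  dout <- ds[[1]]
  dout[along] <- sum(vapply(ds, function(d) d[along], numeric(1)))
  out <- array(0, dim = dout)
  at <- 0L
  for (a in arrs) {
    d <- dim(a)
    idx <- lapply(1:3, function(k) if (k == along) at + seq_len(d[k]) else seq_len(d[k]))
    out <- do.call(`[<-`, c(list(out), idx, list(a)))
    at <- at + d[along]
  }
  out
}

op_narrow <- function(x, dim_idx, start, len) {
  d <- dim(x$value)
  idx <- lapply(1:3, function(k) if (k == dim_idx) start - 1L + seq_len(len) else seq_len(d[k]))
  dn <- d; dn[dim_idx] <- len
  v <- array(do.call(`[`, c(list(x$value), idx)), dim = dn)
  new_tensor(v, parents = list(x), bwd = function(g) {
    full <- array(0, dim = d)
    full <- do.call(`[<-`, c(list(full), idx, list(array(g, dn))))
    list(full)
  })
}

# gather elements by flat index (used by target assembly in losses)
op_gather <- function(x, flat_idx) {
  d <- dim(x$value) %||% length(x$value)
  v <- x$value[flat_idx]
  new_tensor(array(v, length(flat_idx)), parents = list(x), bwd = function(g) {
    full <- array(0, dim = d)
    for (i in seq_along(flat_idx)) full[flat_idx[i]] <- full[flat_idx[i]] + g[i]
    list(full)
  })
}

# -- linear algebra ----------------------------------------------------------

op_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  new_tensor(av %*% bv, parents = list(a, b), bwd = function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

op_tmat <- function(a) {
  new_tensor(t(a$value), parents = list(a), bwd = function(g) list(t(g)))
}

# softmax along a margin (1 = over rows within each column, 2 = within each row)
op_softmax <- function(x, margin = 1) {
  xv <- x$value
  if (is.null(dim(xv))) xv <- matrix(xv, ncol = 1)
  if (margin == 1) {
    m <- apply(xv, 2, max)
    e <- exp(sweep(xv, 2, m))
    s <- sweep(e, 2, colSums(e), "/")
  } else {
    m <- apply(xv, 1, max)
    e <- exp(sweep(xv, 1, m))
    s <- sweep(e, 1, rowSums(e), "/")
  }
  d0 <- dim(x$value) %||% length(x$value)
  new_tensor(array(s, dim = dim(xv)), parents = list(x), bwd = function(g) {
    g <- array(g, dim = dim(s))
    if (margin == 1) {
      dot <- colSums(g * s)
      list(array(s * sweep(g, 2, dot), dim = d0))
    } else {
      dot <- rowSums(g * s)
      list(array(s * sweep(g, 1, dot), dim = d0))
    }
  })
}

# -- conv / pool / resize ----------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  bias <- if (!is.null(b)) as.numeric(b$value) else NULL
  v <- cpp_conv2d(x$value, w$value, bias, as.integer(stride), as.integer(pad),
                  as.integer(groups))
  d_in <- dim(x$value); wd <- dim(w$value)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  xv <- x$value; wv <- w$value
  new_tensor(v, parents = parents, bwd = function(g) {
    g <- array(g, dim = dim(v))
    gx <- cpp_conv2d_bwd_input(g, wv, as.integer(stride), as.integer(pad),
                               as.integer(groups), d_in[2], d_in[3])
    gw <- cpp_conv2d_bwd_weight(g, xv, wd[3], wd[4], as.integer(stride),
                                as.integer(pad), as.integer(groups))
    out <- list(gx, gw)
    if (length(parents) == 3L) out[[3]] <- apply(g, 1, sum)
    out
  })
}

op_convT2d <- function(x, w, b = NULL, stride = 2L, pad = 0L) {
  bias <- if (!is.null(b)) as.numeric(b$value) else NULL
  v <- cpp_convT2d(x$value, w$value, bias, as.integer(stride), as.integer(pad))
  d_in <- dim(x$value); wd <- dim(w$value)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  xv <- x$value; wv <- w$value
  new_tensor(v, parents = parents, bwd = function(g) {
    g <- array(g, dim = dim(v))
    gx <- cpp_convT2d_bwd_input(g, wv, as.integer(stride), as.integer(pad),
                                d_in[2], d_in[3])
    gw <- cpp_convT2d_bwd_weight(g, xv, wd[3], wd[4], as.integer(stride),
                                 as.integer(pad))
    out <- list(gx, gw)
    if (length(parents) == 3L) out[[3]] <- apply(g, 1, sum)
    out
  })
}

op_maxpool <- function(x, k = 5L, stride = 1L, pad = 2L) {
  r <- cpp_maxpool(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  d <- dim(x$value)
  new_tensor(r$y, parents = list(x), bwd = function(g) {
    list(cpp_maxpool_bwd(array(g, dim = dim(r$y)), r$argmax, d[1], d[2], d[3]))
  })
}

op_upsample_nearest2 <- function(x) {
  d <- dim(x$value)
  hidx <- rep(seq_len(d[2]), each = 2)
  widx <- rep(seq_len(d[3]), each = 2)
  v <- x$value[, hidx, widx, drop = FALSE]
  new_tensor(v, parents = list(x), bwd = function(g) {
    g <- array(g, dim = c(d[1], 2L * d[2], 2L * d[3]))
    gx <- array(0, dim = d)
    for (a in 1:2) for (b in 1:2)
      gx <- gx + g[, seq(a, 2 * d[2], by = 2), seq(b, 2 * d[3], by = 2), drop = FALSE]
    list(gx)
  })
}

# Batch normalization. Desk-scale training runs image-by-image, so the batch
# statistics are the image's spatial moments (exactly what standard BN
# computes at batch size one); running moments are tracked for the inference
# graph and conv-BN fusion. Setting .tz$bn_batch_stats makes an inference
# forward normalize by the input's own spatial moments as well - the mode the
# training loop's internal validation uses, since a net trained at batch one
# is fit under per-image normalization.
op_bn2d <- function(x, gamma, beta, stats, training = FALSE,
                    momentum = 0.03, eps = 1e-3) {
  d <- dim(x$value)
  C <- d[1]; n <- d[2] * d[3]
  xm <- matrix(x$value, nrow = C)  # channels x spatial; vectors recycle per row
  use_batch <- (training || isTRUE(.tz$bn_batch_stats)) && n > 1
  if (use_batch) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    if (training) {
      # during calibration the k-th pass contributes weight 1/k, making the
      # running moments the exact average of the batch moments seen so far
      if (!is.null(.tz$bn_calib) && .tz$bn_calib > 0) momentum <- 1 / .tz$bn_calib
      stats$mean <- (1 - momentum) * stats$mean + momentum * mu
      stats$var <- (1 - momentum) * stats$var + momentum * va * n / max(n - 1, 1)
    }
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  v <- array(xhat * gamma$value + beta$value, dim = d)
  gv <- gamma$value
  new_tensor(v, parents = list(x, gamma, beta), bwd = function(g) {
    gm <- matrix(g, nrow = C)
    ggamma <- rowSums(gm * xhat)
    gbeta <- rowSums(gm)
    if (use_batch) {
      gxhat <- gm * gv
      m1 <- rowMeans(gxhat)
      m2 <- rowMeans(gxhat * xhat)
      gx <- array((gxhat - m1 - xhat * m2) * istd, dim = d)
    } else {
      gx <- array(gm * (gv * istd), dim = d)
    }
    list(gx, ggamma, gbeta)
  })
}

#' Evaluate an expression with BN normalizing by per-input spatial moments
#' @param expr expression to evaluate
#' @return the expression's value
#' @keywords internal
with_batch_stats <- function(expr) {
  old <- .tz$bn_batch_stats
  .tz$bn_batch_stats <- TRUE
  on.exit(.tz$bn_batch_stats <- old)
  expr
}

# -- loss primitives ---------------------------------------------------------

# binary cross-entropy with logits, elementwise weights; returns the sum
op_bce_logits <- function(x, target, weight = NULL) {
  xv <- x$value; tv <- target
  w <- weight %||% 1
  loss <- sum(w * (pmax(xv, 0) - xv * tv + log1p(exp(-abs(xv)))))
  s <- 1 / (1 + exp(-xv))
  new_tensor(array(loss, 1L), parents = list(x), bwd = function(g) {
    list(as.numeric(g) * w * (s - tv))
  })
}

op_logsoftmax <- function(x, margin = 1) {
  xv <- x$value
  if (margin == 1) {
    m <- apply(xv, 2, max)
    z <- sweep(xv, 2, m)
    lse <- log(colSums(exp(z)))
    v <- sweep(z, 2, lse)
  } else stop("margin 2 not needed")
  s <- exp(v)
  new_tensor(v, parents = list(x), bwd = function(g) {
    g <- array(g, dim = dim(v))
    list(g - sweep(s, 2, colSums(g), "*"))
  })
}

# -- utilities ---------------------------------------------------------------

#' Numerical gradient check by central finite differences
#'
#' @param f function taking no arguments, returning a scalar tz_tensor; must
#'   rebuild the graph on each call
#' @param param the parameter tensor to perturb
#' @param eps step size
#' @param n_probe number of randomly probed coordinates
#' @return max absolute difference between autodiff and numeric gradient
#' @keywords internal
tz_grad_check <- function(f, param, eps = 1e-4, n_probe = 5L) {
  loss <- f()
  tz_zero_grad(list(param))
  tz_backward(loss)
  ga <- param$grad
  idx <- sample(length(param$value), min(n_probe, length(param$value)))
  worst <- 0
  for (i in idx) {
    orig <- param$value[i]
    param$value[i] <- orig + eps; up <- as.numeric(f()$value)
    param$value[i] <- orig - eps; dn <- as.numeric(f()$value)
    param$value[i] <- orig
    gn <- (up - dn) / (2 * eps)
    worst <- max(worst, abs(gn - ga[i]))
  }
  worst
}
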