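# Independent reference implementations used as oracles. Each is written as
# plain loops / direct formula transcriptions, deliberately separate from the
# package's compute paths.

ns <- asNamespace("edgebcs")

rand_tensor <- function(C, H, W, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(C * H * W), dim = c(C, H, W))
}

# loop-based directional pooling
oracle_directional_pool <- function(x) {
  d <- dim(x)
  z_h <- matrix(0, d[1], d[2]); z_w <- matrix(0, d[1], d[3])
  for (c in seq_len(d[1])) {
    for (h in seq_len(d[2])) z_h[c, h] <- mean(x[c, h, ])
    for (w in seq_len(d[3])) z_w[c, w] <- mean(x[c, , w])
  }
  list(z_h = z_h, z_w = z_w)
}

# straight-line transcription of the coordinate-attention equations, reading
# raw parameter arrays from a built module (inference-mode BN)
oracle_ca <- function(mod, x) {
  d <- dim(x)
  p <- oracle_directional_pool(x)
  zc <- cbind(p$z_h, p$z_w)                      # C x (H+W)
  w1 <- matrix(mod$conv1$w$value, dim(mod$conv1$w$value)[1])  # mid x C
  f <- w1 %*% zc                                  # shared 1x1 transform
  f <- (f - mod$conv1$stats$mean) / sqrt(mod$conv1$stats$var + 1e-3) *
    mod$conv1$gamma$value + mod$conv1$beta$value  # BN, running statistics
  f <- f * pmin(pmax(f + 3, 0), 6) / 6            # hard-swish
  f_h <- f[, seq_len(d[2]), drop = FALSE]
  f_w <- f[, d[2] + seq_len(d[3]), drop = FALSE]
  wh <- matrix(mod$conv_h$w$value, d[1])
  ww <- matrix(mod$conv_w$w$value, d[1])
  g_h <- 1 / (1 + exp(-(wh %*% f_h + mod$conv_h$b$value)))
  g_w <- 1 / (1 + exp(-(ww %*% f_w + mod$conv_w$b$value)))
  y <- x
  for (c in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    y[c, i, j] <- x[c, i, j] * g_h[c, i] * g_w[c, j]
  y
}

# pixelwise star core: relu6(W1 x + b1) * (W2 x + b2)
oracle_star_core <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  out <- array(0, dim = c(nrow(W1), d[2], d[3]))
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    v <- x[, i, j]
    a <- W1 %*% v + b1
    out[, i, j] <- pmin(pmax(a, 0), 6) * (W2 %*% v + b2)
  }
  out
}

# transposed convolution as zero-stuffing followed by ordinary convolution
oracle_convT <- function(x, w, stride, pad) {
  d <- dim(x); wd <- dim(w)  # w: (Cin, Cout, k, k)
  k <- wd[3]
  Hs <- (d[2] - 1) * stride + 1; Ws <- (d[3] - 1) * stride + 1
  xs <- array(0, dim = c(d[1], Hs, Ws))
  xs[, seq(1, Hs, by = stride), seq(1, Ws, by = stride)] <- x
  # ordinary convolution (flipped-kernel correlation) over the stuffed map
  Ho <- Hs + k - 1 - 2 * pad; Wo <- Ws + k - 1 - 2 * pad
  out <- array(0, dim = c(wd[2], Ho, Wo))
  for (co in seq_len(wd[2])) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- 0
    for (ci in seq_len(d[1])) for (i in seq_len(k)) for (j in seq_len(k)) {
      hi <- ho + pad - (i - 1); wi <- wo + pad - (j - 1)
      if (hi >= 1 && hi <= Hs && wi >= 1 && wi <= Ws)
        acc <- acc + xs[ci, hi, wi] * w[ci, co, i, j]
    }
    out[co, ho, wo] <- acc
  }
  out
}

# dense multiply-accumulate enumeration for a grouped convolution
oracle_grouped_macs <- function(H, W, K, C, g) {
  macs <- 0
  cpg <- C / g
  for (gi in seq_len(g)) macs <- macs + H * W * cpg * cpg * K * K
  macs
}

# O(n^2) exhaustive NMS
oracle_nms <- function(dets, thr) {
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (j <= i || !keep[j] || d$class[j] != d$class[i]) next
      if (box_iou(as.numeric(d[i, c("x_min", "y_min", "x_max", "y_max")]),
                  as.numeric(d[j, c("x_min", "y_min", "x_max", "y_max")])) > thr)
        keep[j] <- FALSE
    }
  }
  d[keep, , drop = FALSE]
}

# AP by explicit threshold sweep: P and R are recounted from scratch at every
# distinct confidence cut; interpolated precision at recall r is the maximum
# precision among operating points with recall >= r
oracle_ap_sweep <- function(tp, conf, n_truth) {
  cuts <- sort(unique(conf))
  ops <- t(sapply(cuts, function(ct) {
    sel <- conf >= ct
    c(p = if (any(sel)) sum(tp[sel]) / sum(sel) else 0,
      r = sum(tp[sel]) / n_truth)
  }))
  pts <- seq(0, 1, by = 0.01)
  mean(sapply(pts, function(r) {
    ok <- ops[, "r"] >= r
    if (any(ok)) max(ops[ok, "p"]) else 0
  }))
}

# direct 2-D convolution loop with reflected borders
oracle_filter2_reflect <- function(img, ker) {
  H <- nrow(img); W <- ncol(img); kh <- nrow(ker); kw <- ncol(ker)
  ch <- kh %/% 2; cw <- kw %/% 2
  out <- matrix(0, H, W)
  refl <- function(i, n) { if (i < 1) 2 - i else if (i > n) 2 * n - i else i }
  for (h in seq_len(H)) for (w in seq_len(W)) {
    acc <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      hi <- refl(h + i - 1 - ch, H); wi <- refl(w + j - 1 - cw, W)
      acc <- acc + img[hi, wi] * ker[i, j]
    }
    out[h, w] <- acc
  }
  out
}

# set every learnable value of a module (tree) to a constant
zero_module <- function(m, bn_identity = TRUE) {
  ps <- ns$mod_params(m)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    p$value <- p$value * 0
    if (bn_identity && grepl("gamma$", nm)) p$value <- p$value + 1
  }
  invisible(m)
}
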