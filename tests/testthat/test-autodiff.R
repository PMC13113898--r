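test_that("compiled convolution agrees with a direct nested-loop computation", {
  set.seed(1)
  x <- rand_tensor(3, 6, 7, seed = 1)
  w <- array(rnorm(4 * 3 * 3 * 3), dim = c(4, 3, 3, 3))
  b <- rnorm(4)
  got <- ns$cpp_conv2d(x, w, b, 2L, 1L, 1L)
  Ho <- 3; Wo <- 4
  want <- array(0, dim = c(4, Ho, Wo))
  for (co in 1:4) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (ci in 1:3) for (i in 1:3) for (j in 1:3) {
      hi <- (ho - 1) * 2 - 1 + i; wi <- (wo - 1) * 2 - 1 + j
      if (hi >= 1 && hi <= 6 && wi >= 1 && wi <= 7)
        acc <- acc + x[ci, hi, wi] * w[co, ci, i, j]
    }
    want[co, ho, wo] <- acc
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("backward pass matches finite differences across layer types", {
  set.seed(2)
  x <- ns$tz_const(rand_tensor(4, 6, 6, seed = 3))
  conv <- ns$m_conv(4, 6, 3, g = 2)
  ps <- ns$mod_params(conv)
  for (p in ps) p$requires_grad <- TRUE
  f <- function() ns$op_mean(ns$op_square(ns$fwd(conv, x)))
  for (nm in names(ps)) expect_lt(ns$tz_grad_check(f, ps[[nm]]), 1e-5)

  ct <- ns$m_convT(4, 3, k = 2, s = 2)
  pt <- ns$mod_params(ct)
  for (p in pt) p$requires_grad <- TRUE
  ft <- function() ns$op_mean(ns$op_square(ns$fwd(ct, x)))
  expect_lt(ns$tz_grad_check(ft, pt[["w"]]), 1e-5)

  at <- ns$m_attn(8, 2)
  pa <- ns$mod_params(at)
  for (p in pa) p$requires_grad <- TRUE
  xa <- ns$tz_const(rand_tensor(8, 4, 4, seed = 4))
  fa <- function() ns$op_mean(ns$op_square(ns$fwd(at, xa)))
  expect_lt(ns$tz_grad_check(fa, pa[["qkv.w"]]), 1e-5)
  expect_lt(ns$tz_grad_check(fa, pa[["pe.w"]]), 1e-5)
})

test_that("maxpool, upsample and softmax match base-R references and backprop", {
  set.seed(5)
  x <- rand_tensor(2, 5, 5, seed = 5)
  mp <- ns$op_maxpool(ns$tz_const(x), 3L, 1L, 1L)
  want <- array(0, dim = c(2, 5, 5))
  for (c in 1:2) for (h in 1:5) for (w in 1:5)
    want[c, h, w] <- max(x[c, max(1, h - 1):min(5, h + 1), max(1, w - 1):min(5, w + 1)])
  expect_equal(mp$value, want)

  up <- ns$op_upsample_nearest2(ns$tz_const(x))
  expect_equal(dim(up$value), c(2L, 10L, 10L))
  expect_equal(up$value[, 1, 1], x[, 1, 1])
  expect_equal(up$value[, 10, 10], x[, 5, 5])

  m <- matrix(rnorm(12), 3)
  sm <- ns$op_softmax(ns$tz_const(m), margin = 1)
  expect_equal(colSums(sm$value), rep(1, 4))
  expect_equal(sm$value, apply(m, 2, function(v) exp(v) / sum(exp(v))))
  # gradient of softmax through a weighted sum
  p <- ns$tz_param(m)
  fg <- function() ns$op_sum(ns$op_mul(ns$op_softmax(p, 1), ns$tz_const(matrix(1:12, 3))))
  expect_lt(ns$tz_grad_check(fg, p), 1e-6)
})

test_that("fp16 packing is IEEE binary16 round-to-nearest-even", {
  v <- c(0, 1, -1, 0.5, 65504, 1e-8, pi, -2.718)
  back <- ns$cpp_fp16_unpack(ns$cpp_fp16_pack(v))
  expect_equal(back[1:4], c(0, 1, -1, 0.5))
  expect_equal(back[5], 65504)           # largest finite half
  expect_lt(abs(back[7] - pi) / pi, 2^-11 + 1e-9)  # half-precision ulp bound
  r <- ns$cpp_fp16_pack(1.0)
  expect_identical(as.integer(r), c(0L, 60L))  # 0x3C00 little-endian
})

test_that("batch-norm running moments converge to the data moments", {
  set.seed(6)
  bn_mod <- ns$m_conv(3, 3, 1, act = "identity", bn = TRUE)
  bn_mod$w$value <- array(diag(3), dim = c(3, 3, 1, 1))
  x <- rand_tensor(3, 8, 8, seed = 7) + c(1, -2, 0.5)  # distinct channel means
  for (k in 1:300) invisible(ns$fwd(bn_mod, ns$tz_const(x), train = TRUE))
  mu <- apply(x, 1, mean)
  va <- apply(x, 1, function(v) stats::var(as.numeric(v)))
  expect_equal(bn_mod$stats$mean, mu, tolerance = 1e-3)
  expect_equal(bn_mod$stats$var, va, tolerance = 1e-2)
  # once converged, training-mode output is normalized per channel
  y <- ns$fwd(bn_mod, ns$tz_const(x), train = TRUE)$value
  for (c in 1:3) expect_lt(abs(mean(y[c, , ])), 1e-2)
})
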