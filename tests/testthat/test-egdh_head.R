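test_that("grouped-convolution FLOP formula and the 1/g ratio", {
  r <- grouped_conv_flops(8, 8, 3, 16, 1)
  expect_equal(unname(r["flops_std"]), 147456)
  expect_equal(unname(r["flops_gc"]), 147456)
  r2 <- grouped_conv_flops(8, 8, 3, 64, 4)
  expect_equal(unname(r2["flops_gc"] / r2["flops_std"]), 0.25)
  for (g in c(1, 2, 4, 8)) {
    r3 <- grouped_conv_flops(5, 7, 3, 32, g)
    expect_equal(unname(r3["flops_gc"]), oracle_grouped_macs(5, 7, 3, 32, g))
    expect_equal(unname(r3["flops_gc"]), unname(r3["flops_std"]) / g)
  }
  expect_error(grouped_conv_flops(8, 8, 3, 30, 4), "divisible")
  expect_error(grouped_conv_flops(-1, 8, 3, 16, 1), "positive")
})

test_that("head level produces correctly shaped class and regression maps", {
  set.seed(1)
  lvl <- egdh_level(64, nc = 5, reg_max = 16)
  x <- rand_tensor(64, 20, 20, seed = 2)
  out <- ns$fwd(lvl, ns$tz_const(x))
  expect_equal(dim(out$cls$value), c(5L, 20L, 20L))
  expect_equal(dim(out$reg$value), c(64L, 20L, 20L))
  expect_equal(lvl$g, 4L)  # 64 channels / group width 16
  # non-multiple channel count gets adapted up to the next multiple of 16
  lvl2 <- egdh_level(24, nc = 5)
  expect_equal(lvl2$cw, 32L)
  expect_equal(lvl2$g, 2L)
})

test_that("zero stem/refine weights reduce the class map to the prediction bias", {
  set.seed(3)
  lvl <- egdh_level(32, nc = 5)
  zero_module(lvl)
  lvl$alpha$value <- array(1, 1L)
  lvl$cls$b$value <- c(-1, 0.5, 2, -0.25, 0.125)
  x <- rand_tensor(32, 6, 6, seed = 4)
  out <- ns$fwd(lvl, ns$tz_const(x))
  for (k in 1:5) expect_true(all(abs(out$cls$value[k, , ] - lvl$cls$b$value[k]) < 1e-12))
})

test_that("profiled head FLOPs equal the per-layer grouped-conv accounting", {
  set.seed(5)
  lvl <- egdh_level(64, nc = 5, reg_max = 16)
  H <- 20; W <- 20
  p <- ns$mod_profile(lvl, c(64L, H, W))
  g <- lvl$g
  by_hand <- 2 * (3 * unname(grouped_conv_flops(H, W, 3, 64, g)["flops_gc"]) +  # stem x2 + refine
                  H * W * 64 * 5 + H * W * 64 * 64) +                            # 1x1 preds (MACs x2)
             2 * H * W * 64                                                      # alpha residual
  expect_equal(p$flops, by_hand)
})

test_that("grouped layers touch only their own channel group", {
  set.seed(6)
  conv <- ns$m_conv(32, 32, 3, g = 4, act = "identity", bn = FALSE, bias = TRUE)
  x <- rand_tensor(32, 6, 6, seed = 7)
  y0 <- ns$fwd(conv, ns$tz_const(x))$value
  xp <- x; xp[9:16, , ] <- xp[9:16, , ] + 1  # perturb group 2 inputs
  y1 <- ns$fwd(conv, ns$tz_const(xp))$value
  expect_equal(y0[-(9:16), , ], y1[-(9:16), , ], tolerance = 1e-12)
  expect_gt(max(abs(y1[9:16, , ] - y0[9:16, , ])), 0)
})

test_that("alpha is trainable: nonzero gradient for generic input", {
  set.seed(8)
  lvl <- egdh_level(32, nc = 3)
  lvl$alpha$requires_grad <- TRUE
  x <- ns$tz_const(rand_tensor(32, 4, 4, seed = 9))
  out <- ns$fwd(lvl, x, train = FALSE)
  loss <- ns$op_mean(ns$op_square(out$cls))
  ns$tz_backward(loss)
  expect_gt(abs(as.numeric(lvl$alpha$grad)), 0)
  expect_lt(ns$tz_grad_check(function() {
    o <- ns$fwd(lvl, x); ns$op_mean(ns$op_square(o$cls))
  }, lvl$alpha), 1e-5)
})

test_that("conv-BN fusion is exact, groupwise, and idempotent once BN is gone", {
  # identity BN leaves weights unchanged
  w <- array(rnorm(8 * 2 * 3 * 3), dim = c(8, 2, 3, 3))
  f <- fuse_conv_bn(list(w = w, b = NULL),
                    list(gamma = rep(1, 8), beta = rep(0, 8),
                         mean = rep(0, 8), var = rep(1, 8), eps = 0))
  expect_equal(f$w, w)
  expect_equal(f$b, rep(0, 8))
  # random conv + random BN stats: fused output matches composite <= 1e-5
  set.seed(10)
  conv <- ns$m_conv(8, 8, 3, g = 4, act = "identity", bn = TRUE)
  conv$stats$mean <- rnorm(8)
  conv$stats$var <- runif(8, 0.2, 2)
  conv$gamma$value <- runif(8, 0.5, 1.5)
  conv$beta$value <- rnorm(8)
  x <- rand_tensor(8, 6, 6, seed = 11)
  y_ref <- ns$fwd(conv, ns$tz_const(x))$value
  ns$mod_fuse(conv)
  y_fused <- ns$fwd(conv, ns$tz_const(x))$value
  expect_equal(y_fused, y_ref, tolerance = 1e-5)
  # second fusion is a no-op
  w1 <- conv$w$value
  ns$mod_fuse(conv)
  expect_identical(conv$w$value, w1)
})
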