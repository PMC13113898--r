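test_that("learned upsampling doubles spatial dims and maps channels", {
  set.seed(1)
  up <- psff_upsample(6, 4)
  x <- rand_tensor(6, 10, 10, seed = 2)
  y <- upsample_learned(up, x)
  expect_equal(dim(y), c(4L, 20L, 20L))
})

test_that("a partition-of-unity stencil keeps constant images constant", {
  up <- psff_upsample(1, 1, k = 2)
  up$w$value <- array(1, dim = c(1, 1, 2, 2))  # constant stencil, sums to 1/site
  up$bn <- FALSE; up$gamma <- NULL; up$beta <- NULL; up$stats <- NULL
  up$act <- "identity"
  x <- array(3.7, dim = c(1, 6, 6))
  y <- upsample_learned(up, x)
  expect_equal(dim(y), c(1L, 12L, 12L))
  expect_true(all(abs(y - 3.7) < 1e-12))
})

test_that("transposed convolution equals the zero-stuffing + convolution oracle", {
  set.seed(3)
  up <- psff_upsample(3, 2, k = 2)
  up$bn <- FALSE; up$gamma <- NULL; up$beta <- NULL; up$stats <- NULL
  up$act <- "identity"
  x <- rand_tensor(3, 4, 5, seed = 4)
  expect_equal(upsample_learned(up, x),
               oracle_convT(x, up$w$value, stride = 2, pad = 0), tolerance = 1e-5)
})

test_that("gate-closed and gate-open limits of the fusion node", {
  set.seed(5)
  node <- psff_fuse_node(4, 4)
  L <- rand_tensor(4, 6, 6, seed = 6)
  U <- rand_tensor(4, 6, 6, seed = 7)
  node$gate$w$value <- node$gate$w$value * 0
  node$gate$b$value <- rep(-40, 4)          # sigmoid -> 0: deep passthrough
  expect_equal(gated_fuse(node, L, U), U, tolerance = 1e-8)
  node$gate$b$value <- rep(40, 4)           # sigmoid -> 1
  zero_module(node$ca)                      # forces both CA gates to 1/2
  node$gate$w$value <- node$gate$w$value * 0
  node$gate$b$value <- rep(40, 4)
  expect_equal(gated_fuse(node, L, U), 0.25 * L + U, tolerance = 1e-8)
  expect_error(gated_fuse(node, L, rand_tensor(4, 5, 5)), "spatial mismatch")
})

test_that("fusion node matches the decided formula CA(L) * sigmoid(conv(U)) + U", {
  set.seed(8)
  node <- psff_fuse_node(4, 4)
  L <- rand_tensor(4, 6, 6, seed = 9)
  U <- rand_tensor(4, 6, 6, seed = 10)
  got <- gated_fuse(node, L, U)
  gmat <- matrix(node$gate$w$value, 4)
  Um <- matrix(U, 4)
  gate <- 1 / (1 + exp(-(gmat %*% Um + node$gate$b$value)))
  want <- array(matrix(ca_forward(node$ca, L), 4) * gate + Um, dim = dim(L))
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("neck preserves strides/channels per node and contains no concatenation", {
  set.seed(11)
  nk <- psff_neck(c(16, 16, 16), lateral_channels = c(16, 32, 64), expansion = 2)
  shapes <- list(c(16L, 16L, 16L), c(32L, 8L, 8L), c(64L, 4L, 4L))
  p <- ns$mod_profile(nk, shapes)
  expect_equal(p$out[[1]][2:3], c(16L, 16L))
  expect_equal(p$out[[2]][2:3], c(8L, 8L))
  expect_equal(p$out[[3]][2:3], c(4L, 4L))
  expect_equal(sapply(p$out, `[`, 1), c(16, 16, 16))  # constant-channel contract
  # no m_concat module anywhere among the neck's fusion plumbing
  kinds <- sapply(ns$psff_children(nk), function(m) class(m)[1])
  expect_false(any(kinds == "m_concat"))
  xs <- lapply(shapes, function(s) ns$tz_const(array(rnorm(prod(s)), s)))
  outs <- ns$fwd(nk, xs)
  expect_equal(dim(outs[[1]]$value), c(16L, 16L, 16L))
})

test_that("whole-neck FLOPs are additive over nodes and below the concat neck's", {
  set.seed(12)
  cfg <- model_config("full")
  full <- build_model(cfg)
  base <- build_model(model_config("baseline"))
  pf <- ns$profile_model(full, 640)
  pb <- ns$profile_model(base, 640)
  neck_f <- pf$table$flops[pf$table$module == "psff_neck"]
  neck_b <- sum(pb$table$flops[pb$table$module %in%
    c("up1", "cat1", "c13", "up2", "cat2", "c16", "d17", "cat3", "c19",
      "d20", "cat4", "c22")])
  expect_lt(neck_f, neck_b)
  # additivity: per-node FLOPs at their true input shapes sum to the whole
  nk <- full$neck
  wn <- nk$channels[1]
  at <- function(hw, c = wn) c(c, hw, hw)
  child_in <- list(
    up54 = at(20, 256), node4 = list(at(40, 128), at(40)), stage4 = at(40),
    up43 = at(40), node3 = list(at(80, 128), at(80)), stage3 = at(80),
    down34 = at(80), node4b = list(at(40), at(40)), stage4b = at(40),
    down45 = at(40), node5 = list(at(20, 256), at(20)), stage5 = at(20))
  kids <- ns$psff_children(nk)
  fl_sum <- sum(sapply(names(kids), function(nm)
    ns$mod_profile(kids[[nm]], child_in[[nm]])$flops))
  p <- ns$mod_profile(nk, list(at(80, 128), at(40, 128), at(20, 256)))
  expect_equal(p$flops, fl_sum)
})
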