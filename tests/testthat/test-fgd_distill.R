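box1 <- function(cx, cy, w, h, class = 0L)
  data.frame(class = class, cx = cx, cy = cy, w = w, h = h)

test_that("degenerate geometries: full-image box and empty image", {
  tf <- rand_tensor(4, 8, 8, seed = 1)
  mk <- build_focal_masks(box1(0.5, 0.5, 1, 1), c(4, 8, 8), tf)
  expect_true(all(mk$M == 1))
  expect_true(all(abs(mk$S - 1 / (8 * 8)) < 1e-12))
  mk0 <- build_focal_masks(box1(0, 0, 0, 0)[0, ], c(4, 8, 8), tf)
  expect_true(all(mk0$M == 0))
  expect_true(all(abs(mk0$S - 1 / (8 * 8)) < 1e-12))
})

test_that("uniform teacher features give flat attention masks with stated sums", {
  tf <- array(0.3, dim = c(6, 5, 7))
  mk <- build_focal_masks(box1(0.5, 0.5, 0.4, 0.4), c(6, 5, 7), tf)
  expect_true(all(abs(mk$a_s - 1) < 1e-12))
  expect_true(all(abs(mk$a_c - 1) < 1e-12))
  # sums hold for generic teachers too
  tf2 <- rand_tensor(6, 5, 7, seed = 2)
  mk2 <- build_focal_masks(box1(0.5, 0.5, 0.4, 0.4), c(6, 5, 7), tf2)
  expect_lt(abs(sum(mk2$a_s) - 5 * 7), 1e-4)
  expect_lt(abs(sum(mk2$a_c) - 6), 1e-4)
})

test_that("binary mask support equals a pixel-enumeration rasterization", {
  boxes <- rbind(box1(0.2, 0.25, 0.25, 0.3), box1(0.75, 0.7, 0.2, 0.25))
  H <- 12; W <- 16
  tf <- rand_tensor(3, H, W, seed = 3)
  mk <- build_focal_masks(boxes, c(3, H, W), tf)
  want <- matrix(0, H, W)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    cx <- (w - 0.5) / W; cy <- (h - 0.5) / H
    for (i in 1:2) {
      b <- boxes[i, ]
      if (cx >= b$cx - b$w / 2 && cx <= b$cx + b$w / 2 &&
          cy >= b$cy - b$h / 2 && cy <= b$cy + b$h / 2) want[h, w] <- 1
    }
  }
  expect_equal(mk$M, want)
})

test_that("loss vanishes at teacher equality and under zero weights", {
  tf <- rand_tensor(4, 6, 6, seed = 4)
  mk <- build_focal_masks(box1(0.4, 0.4, 0.3, 0.3), c(4, 6, 6), tf)
  l_eq <- fgd_loss(tf, tf, mk)
  expect_equal(as.numeric(l_eq$total$value), 0, tolerance = 1e-12)
  fs <- rand_tensor(4, 6, 6, seed = 5)
  l_off <- fgd_loss(tf, fs, mk, fgd_config(w_fg = 0, w_bg = 0, w_at = 0, w_gl = 0))
  expect_equal(as.numeric(l_off$total$value), 0)
  l_on <- fgd_loss(tf, fs, mk)
  expect_gt(as.numeric(l_on$total$value), 0)
})

test_that("total is linear in the loss weights", {
  tf <- rand_tensor(4, 6, 6, seed = 6)
  fs <- rand_tensor(4, 6, 6, seed = 7)
  mk <- build_focal_masks(box1(0.5, 0.5, 0.5, 0.5), c(4, 6, 6), tf)
  c1 <- fgd_config()
  c2 <- fgd_config(w_fg = 2 * c1$w_fg, w_bg = 2 * c1$w_bg,
                   w_at = 2 * c1$w_at, w_gl = 2 * c1$w_gl)
  l1 <- as.numeric(fgd_loss(tf, fs, mk, c1)$total$value)
  l2 <- as.numeric(fgd_loss(tf, fs, mk, c2)$total$value)
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
})

test_that("focal-feature terms equal an explicit loop transcription", {
  set.seed(8)
  C <- 3; H <- 5; W <- 5
  tf <- rand_tensor(C, H, W, seed = 8)
  fs <- rand_tensor(C, H, W, seed = 9)
  b <- box1(0.45, 0.5, 0.4, 0.35)
  cfg <- fgd_config()
  mk <- build_focal_masks(b, c(C, H, W), tf, cfg)
  got <- fgd_loss(tf, fs, mk, cfg)
  fg <- 0; bg <- 0
  for (c in seq_len(C)) for (h in seq_len(H)) for (w in seq_len(W)) {
    d2 <- (tf[c, h, w] - fs[c, h, w])^2
    wgt <- mk$S[h, w] * mk$a_s[h, w] * mk$a_c[c]
    if (mk$M[h, w] == 1) fg <- fg + d2 * wgt else bg <- bg + d2 * wgt
  }
  expect_equal(unname(got$components["fg"]), fg, tolerance = 1e-5)
  expect_equal(unname(got$components["bg"]), bg, tolerance = 1e-5)
  # global term: squared difference of attention-pooled context vectors
  pool <- function(f) {
    att <- exp(apply(abs(f), c(2, 3), mean) / cfg$temperature)
    att <- att / sum(att)
    v <- rep(0, C)
    for (c in seq_len(C)) v[c] <- sum(f[c, , ] * att)
    v
  }
  expect_equal(unname(got$components["gl"]), sum((pool(tf) - pool(fs))^2),
               tolerance = 1e-5)
})

test_that("distillation leaves the inference graph untouched", {
  set.seed(10)
  m <- build_model(model_config("full", width = 0.125))
  r0 <- complexity_report(m, 64)
  ds <- generate_synthetic_dataset(5, images_per_session = 1, blur_fraction = 0,
                                   seed = 1, width = 64, height = 64)
  teacher <- build_model(model_config("full", width = 0.125))
  cfg <- train_config(epochs = 1, batch = 4, imgsz = 64, augment = FALSE,
                      distill = TRUE, seed = 1)
  res <- train(m, list(images = ds$images[1:4], labels = ds$labels[1:4]),
               cfg, teacher = teacher)
  r1 <- complexity_report(m, 64)
  expect_identical(r0$params, r1$params)
  expect_identical(r0$gflops, r1$gflops)
  expect_false(any(grepl("distill", names(model_params(m)))))
})
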