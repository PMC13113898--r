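# build a minimal single-level prediction object by hand: one 4x4 grid at
# stride 8 (32 px image), nc classes, reg_max bins
toy_preds <- function(cls_logits, reg_logits) {
  list(list(cls = ns$tz_const(cls_logits), reg = ns$tz_const(reg_logits)))
}

test_that("perfect predictions drive box and DFL components to zero", {
  nc <- 3L; reg_max <- 16L; H <- 4L; W <- 4L; imgsz <- 32L
  # ground truth centered on anchor (2,2) (cell centers at 4,12,20,28):
  # center (12,12), extents 1 cell in every direction -> distances exactly 1
  truths <- data.frame(class = 1L, cx = 12 / 32, cy = 12 / 32, w = 16 / 32, h = 16 / 32)
  cls <- array(-30, dim = c(nc, H, W))
  reg <- array(0, dim = c(4L * reg_max, H, W))
  for (s in 1:4) reg[(s - 1L) * reg_max + 2L, , ] <- 30   # one-hot on bin "1"
  cls[2, 2, 2] <- 30                                      # saturated confidence
  dl <- detection_loss(toy_preds(cls, reg), truths, imgsz,
                       strides = 8L, reg_max = reg_max, nc = nc)
  expect_lt(unname(dl$components["box"]), 1e-5)
  expect_lt(unname(dl$components["dfl"]), 1e-4)
})

test_that("doubling the component weights doubles the total loss", {
  set.seed(1)
  nc <- 3L; reg_max <- 16L
  cls <- array(rnorm(nc * 4 * 4), dim = c(nc, 4, 4))
  reg <- array(rnorm(64 * 4 * 4, sd = 0.5), dim = c(64, 4, 4))
  truths <- data.frame(class = 0L, cx = 0.4, cy = 0.5, w = 0.5, h = 0.4)
  c1 <- train_config()
  c2 <- train_config(lambda_box = 2 * c1$lambda_box,
                     lambda_cls = 2 * c1$lambda_cls,
                     lambda_dfl = 2 * c1$lambda_dfl)
  l1 <- detection_loss(toy_preds(cls, reg), truths, 32, c1, 8L, reg_max, nc)
  l2 <- detection_loss(toy_preds(cls, reg), truths, 32, c2, 8L, reg_max, nc)
  expect_equal(as.numeric(l2$total$value), 2 * as.numeric(l1$total$value),
               tolerance = 1e-10)
})

test_that("single-anchor toy assignment reproduces a hand-composed loss", {
  nc <- 2L; reg_max <- 16L
  # 1x1 grid at stride 8: single anchor at (4,4); gt covers the whole cell
  truths <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 1, h = 1)
  cls <- array(c(0.3, -0.2), dim = c(nc, 1, 1))
  reg <- array(0.1, dim = c(4L * reg_max, 1, 1))
  dl <- detection_loss(toy_preds(cls, reg), truths, 8, train_config(),
                       strides = 8L, reg_max = reg_max, nc = nc)
  # by hand: uniform reg logits -> every side distance = mean(0:15) = 7.5
  # pred box = (4-60, 4-60, 4+60, 4+60); gt = (0,0,8,8)
  pb <- c(4 - 60, 4 - 60, 4 + 60, 4 + 60); gb <- c(0, 0, 8, 8)
  iou <- 64 / (120 * 120)
  p0 <- plogis(0.3)
  align <- p0^0.5 * iou^6
  score <- iou                      # normalized: single anchor hits iou_max
  # cls: BCE with target `score` on (class 1, anchor 1), 0 on the other logit
  bce <- function(x, t) max(x, 0) - x * t + log1p(exp(-abs(x)))
  cls_hand <- (bce(0.3, score) + bce(-0.2, 0)) / max(score, 1)
  expect_equal(unname(dl$components["cls"]), cls_hand, tolerance = 1e-8)
  # box: weighted mean of (1 - CIoU) with a single weight -> 1 - CIoU
  rho2 <- sum((c(4, 4) - c(4, 4))^2)
  c2 <- 120^2 + 120^2
  v <- (4 / pi^2) * (atan(8 / 8) - atan(120 / 120))^2  # both square: v = 0
  ciou <- iou - rho2 / c2 - 0
  expect_equal(unname(dl$components["box"]), 1 - ciou, tolerance = 1e-6)
  # dfl: target distances all 4/8 = 0.5 cells -> CE split between bins 0 and 1
  lsm <- log(rep(1 / reg_max, reg_max))
  dfl_hand <- -4 * (0.5 * lsm[1] + 0.5 * lsm[2]) / 4
  expect_equal(unname(dl$components["dfl"]), dfl_hand, tolerance = 1e-6)
})

test_that("SGD descends when fitting a single seeded image", {
  ds <- generate_synthetic_dataset(5, images_per_session = 1, blur_fraction = 0,
                                   seed = 5, width = 64, height = 64, zoom = 2.5)
  set.seed(5)
  model <- build_model(model_config("full", width = 0.125))
  cfg <- train_config(epochs = 40, batch = 1, imgsz = 64, augment = FALSE,
                      seed = 5, optimizer = "sgd")
  res <- train(model, list(images = ds$images[1], labels = ds$labels[1]), cfg)
  expect_lt(res$history$loss[40], 0.5 * res$history$loss[1])
  expect_lt(res$history$box[40], 0.5 * res$history$box[1])
})

test_that("identical teacher and student give a vanishing distillation component", {
  set.seed(6)
  model <- build_model(model_config("full", width = 0.125))
  x <- rand_tensor(3, 64, 64, seed = 7)
  preds <- model_forward(model, x)
  feats <- attr(preds, "neck_features")
  lab <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.4, h = 0.4)
  for (f in feats) {
    mk <- build_focal_masks(lab, dim(f$value), f$value)
    l <- fgd_loss(f$value, f$value, mk)
    expect_equal(as.numeric(l$total$value), 0, tolerance = 1e-10)
  }
})

test_that("epoch-0 loss is bitwise reproducible under a fixed seed", {
  ds <- generate_synthetic_dataset(5, images_per_session = 1, blur_fraction = 0,
                                   seed = 8, width = 64, height = 64)
  run_once <- function() {
    set.seed(9)
    model <- build_model(model_config("full", width = 0.125))
    cfg <- train_config(epochs = 1, batch = 5, imgsz = 64, augment = FALSE, seed = 9)
    train(model, list(images = ds$images[1:5], labels = ds$labels[1:5]),
          cfg)$history$loss[1]
  }
  expect_identical(run_once(), run_once())
})

test_that("augmentations keep labels inside the unit square", {
  ds <- generate_synthetic_dataset(5, images_per_session = 1, blur_fraction = 0,
                                   seed = 10, width = 64, height = 64)
  set.seed(10)
  cfg <- train_config(imgsz = 64)
  for (k in 1:10) {
    s <- ns$augment_sample(ds, sample(length(ds$images), 1), cfg)
    expect_equal(dim(s$image), c(64, 64, 3))
    if (nrow(s$labels)) {
      expect_true(all(s$labels$cx - s$labels$w / 2 >= -1e-9))
      expect_true(all(s$labels$cx + s$labels$w / 2 <= 1 + 1e-9))
      expect_true(all(s$labels$w > 0 & s$labels$h > 0))
    }
  }
})
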