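mkdet <- function(x1, y1, x2, y2, conf = 1, class = 0L, image = "i1")
  data.frame(image = image, class = class, conf = conf,
             x_min = x1, y_min = y1, x_max = x2, y_max = y2)

test_that("IoU: identity, hand-computed overlap, disjoint, degenerate", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7, tolerance = 1e-12)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("NMS keeps singles, suppresses hand-checked overlaps, matches brute force", {
  one <- mkdet(0, 0, 10, 10, 0.9)
  expect_equal(nrow(nms(one)), 1L)
  pair <- rbind(mkdet(0, 0, 10, 10, 0.9), mkdet(0, 0, 10, 8, 0.8))
  expect_equal(nrow(nms(pair, 0.7)), 1L)               # IoU 0.8 > 0.7
  expect_equal(nms(pair, 0.7)$conf, 0.9)
  other_class <- rbind(mkdet(0, 0, 10, 10, 0.9, class = 0L),
                       mkdet(0, 0, 10, 8, 0.8, class = 1L))
  expect_equal(nrow(nms(other_class, 0.7)), 2L)        # class-aware
  set.seed(1)
  rnd <- do.call(rbind, lapply(1:50, function(i) {
    x <- runif(1, 0, 80); y <- runif(1, 0, 80)
    mkdet(x, y, x + runif(1, 5, 30), y + runif(1, 5, 30),
          conf = runif(1), class = sample(0:2, 1))
  }))
  for (thr in c(0.3, 0.5, 0.7)) {
    got <- nms(rnd, thr)
    want <- oracle_nms(rnd, thr)
    expect_equal(got[order(-got$conf), ], want[order(-want$conf), ],
                 ignore_attr = TRUE)
  }
  survivors <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t) nrow(nms(rnd, t)))
  expect_true(all(diff(survivors) >= 0))     # higher threshold, never fewer kept
  expect_equal(nrow(nms(rnd[0, ])), 0L)
})

test_that("precision/recall counting follows the published percentage formulas", {
  truths <- do.call(rbind, lapply(1:9, function(i)
    mkdet(10 * i, 10, 10 * i + 8, 18, image = "a")))[, -3]
  dets <- rbind(
    do.call(rbind, lapply(1:9, function(i) mkdet(10 * i, 10, 10 * i + 8, 18, 0.9, image = "a"))),
    mkdet(500, 500, 510, 510, 0.8, image = "a"))
  pr <- pr_counts(dets, truths)
  expect_equal(pr$precision, 90)
  expect_equal(pr$recall, 100)
  pr0 <- pr_counts(dets[0, ], truths)
  expect_equal(pr0$recall, 0)
  expect_equal(pr0$precision, 0)
  expect_true(pr0$no_detections)
  expect_equal(pr$tp + pr$fn, nrow(truths))
})

test_that("greedy matching agrees with exhaustive assignment on a crafted scene", {
  truths <- rbind(mkdet(0, 0, 10, 10), mkdet(20, 0, 30, 10), mkdet(40, 0, 50, 10))[, -3]
  dets <- rbind(
    mkdet(1, 0, 11, 10, 0.95),   # good match gt1
    mkdet(0, 0, 10, 10, 0.90),   # duplicate of gt1 -> FP (gt used)
    mkdet(21, 0, 31, 10, 0.85),  # good match gt2
    mkdet(40, 2, 50, 12, 0.80),  # decent match gt3
    mkdet(60, 0, 70, 10, 0.75),  # pure FP
    mkdet(44, 0, 54, 10, 0.70))  # weak overlap with used gt3 -> FP
  pr <- pr_counts(dets, truths, iou_cut = 0.5)
  # exhaustive check over all injective det->gt assignments
  best <- 0
  combos <- expand.grid(rep(list(0:3), 6))
  for (r in seq_len(nrow(combos))) {
    asg <- as.integer(combos[r, ])
    used <- asg[asg > 0]
    if (any(duplicated(used))) next
    ok <- 0
    for (d in 1:6) if (asg[d] > 0) {
      i <- box_iou(as.numeric(dets[d, 4:7]), as.numeric(truths[asg[d], 3:6]))
      if (i >= 0.5) ok <- ok + 1
    }
    best <- max(best, ok)
  }
  expect_equal(pr$tp, best)
  expect_equal(pr$tp, 3)
})

test_that("average precision: perfect detector, hopeless detector, sweep oracle", {
  expect_equal(average_precision(rep(TRUE, 7), 7), 1.0)
  expect_equal(average_precision(rep(FALSE, 4), 7), 0.0)
  expect_true(is.na(average_precision(logical(0), 0)))
  tp <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  conf <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  expect_equal(average_precision(tp, 4), oracle_ap_sweep(tp, conf, 4),
               tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:5) {
    n <- 12
    tp <- runif(n) > 0.4
    conf <- sort(runif(n), decreasing = TRUE)
    expect_equal(average_precision(tp, 8), oracle_ap_sweep(tp, conf, 8),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone confidence rescaling", {
  set.seed(3)
  dets <- do.call(rbind, lapply(1:20, function(i) {
    x <- runif(1, 0, 90)
    mkdet(x, x, x + 8, x + 8, conf = runif(1), class = sample(0:1, 1))
  }))
  truths <- do.call(rbind, lapply(seq(5, 85, by = 10), function(x)
    mkdet(x, x, x + 8, x + 8, class = sample(0:1, 1))))[, -3]
  m1 <- map_score(dets, truths)
  dets2 <- dets; dets2$conf <- plogis(5 * dets$conf - 2)  # strictly monotone
  m2 <- map_score(dets2, truths)
  expect_equal(m1$map50, m2$map50, tolerance = 1e-12)
  expect_lte(m1$map50_95, m1$map50 + 1e-12)
})

test_that("mAP aggregates class APs by the unweighted mean", {
  # one perfectly detected class, one undetected class
  truths <- rbind(mkdet(0, 0, 10, 10, class = 0L), mkdet(30, 30, 40, 40, class = 1L))[, -3]
  dets <- mkdet(0, 0, 10, 10, 0.9, class = 0L)
  m <- map_score(dets, truths)
  expect_equal(unname(m$ap50), c(1, 0))
  expect_equal(m$map50, 0.5)  # unweighted class mean
  expect_error(map_score(dets, truths, iou_grid = numeric(0)), "empty")
})

test_that("theoretical FPS reproduces the edge-latency worked examples", {
  expect_equal(theoretical_fps(13.26), 75.41)
  expect_equal(theoretical_fps(12.40), 80.65)
  expect_equal(theoretical_fps(1000), 1.00)
  expect_error(theoretical_fps(0), "positive")
})

test_that("detections round-trip through the CSV interface", {
  d <- mkdet(1.5, 2.5, 10, 12, 0.75, 3L, "img7")
  f <- tempfile(fileext = ".csv")
  write_detections(d, f)
  back <- read_detections(f)
  expect_equal(back$conf, 0.75)
  expect_equal(back$x_min, 1.5)
  unlink(f)
})
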