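test_that("frame thinning keeps every third frame", {
  expect_length(downsample_frames(1:90), 30L)
  expect_equal(downsample_frames(7), 7)
  expect_equal(downsample_frames(1:7), c(1, 4, 7))
  expect_length(downsample_frames(integer(0)), 0L)
})

test_that("campaign arithmetic: herd size, per-session retention, blur merge", {
  man <- manifest_skeleton(494, images_per_session = 8,
                           class_counts = c(17L, 82L, 174L, 198L, 23L))
  expect_equal(nrow(man), 7904L)                       # 494 x 8 x 2
  expect_equal(length(unique(man$animal_id)), 494L)
  cls_animals <- tapply(man$animal_id, man$class, function(x) length(unique(x)))
  expect_equal(as.numeric(cls_animals), c(17, 82, 174, 198, 23))
  expect_equal(sum(cls_animals), 494)
  # merging the blurred copies with the clear set
  blurred <- man[sample(nrow(man), 2658), ]
  blurred$blurred <- TRUE
  merged <- rbind(man, blurred)
  expect_equal(nrow(merged), 10562L)
})

test_that("blur kernels are normalized lines; constants pass through", {
  for (len in c(21, 27, 32, 35)) for (ang in c(0, 37, 90, 135))
    expect_equal(sum(motion_blur_kernel(len, ang)), 1, tolerance = 1e-12)
  k <- motion_blur_kernel(21, 0)
  expect_equal(sum(k > 0), 21L)                       # 21 pixels along one row
  expect_true(all(abs(k[k > 0] - 1 / 21) < 1e-12))
  expect_equal(which(rowSums(k) > 0), 11L)
  img <- matrix(100, 60, 60)
  expect_equal(apply_motion_blur(img, 21, 33), img, tolerance = 1e-9)
  expect_error(apply_motion_blur(matrix(1, 10, 10), 21), "diagonal")
})

test_that("blur equals an explicit 2-D convolution loop with reflected borders", {
  set.seed(1)
  img <- matrix(runif(30 * 26), 30, 26)
  got <- apply_motion_blur(img, 9, 25)
  want <- oracle_filter2_reflect(img, motion_blur_kernel(9, 25))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("animal-level split honours the 8:2 rule and its rounding", {
  man <- manifest_skeleton(10, images_per_session = 2, class_counts = 10L)
  s <- animal_level_split(man, 0.8, seed = 1)
  expect_equal(length(unique(s$animal_id[s$split == "train"])), 8L)
  expect_equal(length(unique(s$animal_id[s$split == "val"])), 2L)
  man17 <- manifest_skeleton(17, images_per_session = 1, class_counts = 17L)
  s17 <- animal_level_split(man17, 0.8, seed = 2)
  expect_equal(length(unique(s17$animal_id[s17$split == "train"])), 14L)
  expect_equal(length(unique(s17$animal_id[s17$split == "val"])), 3L)
})

test_that("no animal identity leaks across the split, blurred copies included", {
  ds <- generate_synthetic_dataset(12, images_per_session = 2, seed = 3,
                                   width = 64, height = 64)
  man <- ds$manifest
  for (aid in unique(man$animal_id))
    expect_length(unique(man$split[man$animal_id == aid]), 1L)
  # deterministic under the seed
  ds2 <- generate_synthetic_dataset(12, images_per_session = 2, seed = 3,
                                    width = 64, height = 64)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images, ds2$images)
})

test_that("generator counts, label geometry and class-conditional texture", {
  ds <- generate_synthetic_dataset(5, images_per_session = 2, seed = 4,
                                   width = 96, height = 96)
  man <- ds$manifest
  expect_equal(sum(!man$blurred), 20L)                 # 5 animals x 2 x 2 sessions
  expect_gte(sum(man$blurred), 5L)                     # ~1/3 of 20, stochastic rounding
  expect_lte(sum(man$blurred), 10L)
  expect_true(all(man$cx - man$w / 2 >= 0 & man$cx + man$w / 2 <= 1))
  expect_true(all(man$cy - man$h / 2 >= 0 & man$cy + man$h / 2 <= 1))
  expect_setequal(unique(man$class), 0:4)
  # texture contrast inside the labeled box grows with the class index
  box_var <- function(i) {
    img <- ds$images[[i]]; b <- man[i, ]
    H <- dim(img)[1]; W <- dim(img)[2]
    rows <- max(1, round((b$cy - b$h / 2) * H)):min(H, round((b$cy + b$h / 2) * H))
    cols <- max(1, round((b$cx - b$w / 2) * W)):min(W, round((b$cx + b$w / 2) * W))
    stats::var(as.numeric(img[rows, cols, 1]))
  }
  clear_morning <- which(!man$blurred & man$session == "morning")
  v_by_class <- tapply(sapply(clear_morning, box_var),
                       man$class[clear_morning], mean)
  expect_true(all(diff(v_by_class) > 0))
})

test_that("label files round-trip through the YOLO text format", {
  lab <- data.frame(class = c(0L, 3L), cx = c(0.5, 0.25), cy = c(0.4, 0.6),
                    w = c(0.2, 0.1), h = c(0.15, 0.12))
  f <- tempfile(fileext = ".txt")
  write_yolo_labels(lab, f)
  back <- read_yolo_labels(f)
  expect_equal(back, lab, tolerance = 1e-6)
  writeLines(character(0), f)
  expect_equal(nrow(read_yolo_labels(f)), 0L)
  unlink(f)
})
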