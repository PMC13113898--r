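# Detection metric stack: IoU, class-aware greedy NMS, precision/recall
# counting, 101-point-interpolated average precision, mAP at IoU 0.5 and over
# the 0.5:0.05:0.95 grid, and the theoretical-FPS formula.

#' Intersection-over-union of two boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)` with min strictly below max.
#'
#' @param a,b numeric length-4 boxes
#' @return IoU in [0, 1]; 0 for disjoint boxes
#' @export
box_iou <- function(a, b) {
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4])
    stop("degenerate box")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# vectorized IoU of one box against a matrix of boxes (rows)
iou_one_many <- function(a, B) {
  if (!nrow(B)) return(numeric(0))
  iw <- pmin(a[3], B[, 3]) - pmax(a[1], B[, 1])
  ih <- pmin(a[4], B[, 4]) - pmax(a[2], B[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  inter / pmax(union, 1e-12)  # zero-area pairs score 0
}

#' Class-aware greedy non-maximum suppression
#'
#' Detections are visited in order of decreasing confidence (ties broken by
#' earlier index); a detection is suppressed when an already-kept detection
#' of the same class overlaps it with IoU above the threshold.
#'
#' @param dets data.frame with x_min, y_min, x_max, y_max, class, conf
#' @param iou_threshold suppression threshold (default 0.7, the validated
#'   inference setting)
#' @return the kept subset of `dets`, highest confidence first
#' @export
nms <- function(dets, iou_threshold = 0.7) {
  if (!nrow(dets)) return(dets)
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  B <- as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")])
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (i > 1) {
      prev <- which(keep[seq_len(i - 1)] & d$class[seq_len(i - 1)] == d$class[i])
      if (length(prev) && any(iou_one_many(B[i, ], B[prev, , drop = FALSE]) > iou_threshold)) next
    }
    keep[i] <- TRUE
  }
  d[keep, , drop = FALSE]
}

# greedy confidence-ordered matching of detections to ground truths within
# one image; returns TP flag per detection (in confidence order)
match_image <- function(dets, truths, iou_cut) {
  used <- logical(nrow(truths))
  tp <- logical(nrow(dets))
  if (!nrow(dets)) return(tp)
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  TB <- as.matrix(truths[, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE])
  for (i in ord) {
    cand <- which(!used & truths$class == dets$class[i])
    if (!length(cand)) next
    ious <- iou_one_many(as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
                         TB[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_cut) { used[cand[j]] <- TRUE; tp[i] <- TRUE }
  }
  tp  # indexed by original row order
}

#' Precision/recall counts at a fixed IoU threshold
#'
#' Matches detections to ground truths per image (greedy by confidence, best
#' IoU above the cut, same class, one truth used at most once) and reports
#' TP/FP/FN with precision and recall as percentages.
#'
#' @param dets data.frame with image, class, conf and corner columns
#' @param truths data.frame with image, class and corner columns
#' @param iou_cut matching threshold (default 0.5)
#' @return list with tp, fp, fn, precision, recall (percent) and
#'   `no_detections` flag (precision reported as 0 when nothing is predicted)
#' @export
pr_counts <- function(dets, truths, iou_cut = 0.5) {
  tp <- 0L
  for (img in unique(truths$image)) {
    di <- dets[dets$image == img, , drop = FALSE]
    ti <- truths[truths$image == img, , drop = FALSE]
    tp <- tp + sum(match_image(di, ti, iou_cut))
  }
  # detections on images without any truth are false positives too
  fp <- nrow(dets) - tp
  fn <- nrow(truths) - tp
  none <- nrow(dets) == 0L
  list(tp = tp, fp = fp, fn = fn,
       precision = if (none) 0 else 100 * tp / (tp + fp),
       recall = if (nrow(truths)) 100 * tp / (tp + fn) else NA_real_,
       no_detections = none)
}

#' Average precision of one class by 101-point interpolation
#'
#' Detections are ranked by confidence over the whole dataset; precision is
#' interpolated (running maximum from the right) and averaged over the 101
#' recall points 0, 0.01, ..., 1.
#'
#' @param tp logical vector, confidence-ordered true-positive flags
#' @param n_truth number of ground-truth boxes of the class
#' @return AP in [0, 1]
#' @export
average_precision <- function(tp, n_truth) {
  if (n_truth == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope
  penv <- rev(cummax(rev(precision)))
  pts <- seq(0, 1, by = 0.01)
  mean(vapply(pts, function(r) {
    i <- which(recall >= r)
    if (length(i)) penv[i[1]] else 0
  }, numeric(1)))
}

# dataset-level per-class AP at one IoU cut
ap_per_class <- function(dets, truths, iou_cut) {
  classes <- sort(unique(truths$class))
  sapply(classes, function(cl) {
    dc <- dets[dets$class == cl, , drop = FALSE]
    tc <- truths[truths$class == cl, , drop = FALSE]
    flags <- logical(0); confs <- numeric(0)
    for (img in unique(c(dc$image, tc$image))) {
      di <- dc[dc$image == img, , drop = FALSE]
      ti <- tc[tc$image == img, , drop = FALSE]
      if (!nrow(di)) next
      tpf <- if (nrow(ti)) match_image(di, ti, iou_cut) else logical(nrow(di))
      flags <- c(flags, tpf); confs <- c(confs, di$conf)
    }
    ord <- order(-confs)
    average_precision(flags[ord], nrow(tc))
  })
}

#' Mean average precision at IoU 0.5 and over the 0.5:0.95 grid
#'
#' @param dets data.frame with image, class, conf, x_min, y_min, x_max, y_max
#' @param truths data.frame with image, class and corner columns
#' @param iou_grid thresholds for the averaged metric (default 0.5 to 0.95
#'   in steps of 0.05)
#' @return list with per-class `ap50`, `map50`, `map50_95`
#' @export
map_score <- function(dets, truths, iou_grid = seq(0.5, 0.95, by = 0.05)) {
  if (!length(iou_grid)) stop("empty IoU grid")
  ap50 <- ap_per_class(dets, truths, 0.5)
  maps <- vapply(iou_grid, function(cut) mean(ap_per_class(dets, truths, cut),
                                              na.rm = TRUE), numeric(1))
  list(ap50 = ap50, map50 = mean(ap50, na.rm = TRUE), map50_95 = mean(maps))
}

#' Theoretical throughput from average inference latency
#'
#' @param t_latency_ms per-frame latency in milliseconds (> 0)
#' @return frames per second, 1000 / latency, rounded to 2 decimals
#' @examples
#' theoretical_fps(13.26)  # 75.41
#' @export
theoretical_fps <- function(t_latency_ms) {
  if (any(t_latency_ms <= 0)) stop("latency must be positive")
  round(1000 / t_latency_ms, 2)
}

#' Write detections to CSV
#' @param dets detection data.frame
#' @param path output file
#' @export
write_detections <- function(dets, path)
  utils::write.csv(dets[, c("image", "class", "conf", "x_min", "y_min",
                            "x_max", "y_max")], path, row.names = FALSE)

#' Read detections from CSV
#' @param path CSV written by [write_detections()]
#' @return detection data.frame
#' @export
read_detections <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
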