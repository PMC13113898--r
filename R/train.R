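# Training and evaluation: anchor-free decoding with distribution-focal box
# regression, task-aligned target assignment, the YOLO-family composite loss
# (CIoU box + BCE classification + DFL regression), SGD with momentum and
# linear learning-rate decay, the stated augmentation set, and optional
# focal+global distillation against a frozen teacher.

#' Training configuration
#'
#' Defaults are the published training settings: SGD with initial learning
#' rate 0.01, momentum 0.937, weight decay 5e-4; HSV jitter 0.015/0.7/0.4;
#' translation 0.1 and scale 0.5; horizontal flip 0.5; mosaic probability 1.0
#' throughout; 100 epochs, batch 16, input 640; NMS IoU 0.7 at validation.
#'
#' @param epochs,batch,imgsz training duration, batch size, square input size
#' @param optimizer "sgd", "adamw", or "auto" (the family rule: AdamW with a
#'   class-count-scaled learning rate when the run is shorter than 10k
#'   iterations, the stated SGD settings otherwise)
#' @param lr0,lrf,momentum,weight_decay SGD settings (linear decay to lr0*lrf)
#' @param hsv_h,hsv_s,hsv_v,translate,scale,fliplr,mosaic augmentation gains
#' @param nms_iou NMS threshold used at validation
#' @param seed RNG seed
#' @param distill enable feature distillation
#' @param distill_cfg an [fgd_config()]
#' @param lambda_box,lambda_cls,lambda_dfl loss component weights
#' @param augment master switch for the augmentation pipeline
#' @return list of class `train_config`
#' @export
train_config <- function(epochs = 100L, batch = 16L, imgsz = 640L,
                         optimizer = "auto",
                         lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                         weight_decay = 5e-4,
                         hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                         translate = 0.1, scale = 0.5, fliplr = 0.5,
                         mosaic = 1.0, nms_iou = 0.7, seed = 0L,
                         distill = FALSE, distill_cfg = fgd_config(),
                         lambda_box = 7.5, lambda_cls = 0.5, lambda_dfl = 1.5,
                         augment = TRUE) {
  stopifnot(lr0 > 0, all(c(hsv_h, hsv_s, hsv_v, fliplr, mosaic) >= 0),
            all(c(fliplr, mosaic) <= 1))
  structure(as.list(environment()), class = "train_config")
}

# anchor centers (pixels) for one level
anchor_centers <- function(H, W, stride) {
  list(cx = rep((seq_len(W) - 0.5) * stride, each = H),
       cy = rep((seq_len(H) - 0.5) * stride, times = W))
}

# numeric softmax-expectation decode of a reg map (4*reg_max, H, W) -> n x 4
# distances (l, t, r, b) in stride units; anchors flattened h-fastest
decode_distances <- function(reg, reg_max) {
  d <- dim(reg); H <- d[2]; W <- d[3]
  out <- matrix(0, H * W, 4)
  bins <- 0:(reg_max - 1)
  rm <- matrix(reg, nrow = 4L * reg_max)  # channels x anchors
  for (s in 1:4) {
    lo <- rm[((s - 1) * reg_max + 1):(s * reg_max), , drop = FALSE]
    lo <- exp(sweep(lo, 2, apply(lo, 2, max)))
    lo <- sweep(lo, 2, colSums(lo), "/")
    out[, s] <- colSums(lo * bins)
  }
  out
}

#' Decode raw predictions into pixel-space detections
#'
#' @param preds per-level list with cls/reg tensors (from [model_forward()])
#' @param strides per-level strides (default 8/16/32)
#' @param reg_max distribution-focal bins
#' @param conf_thresh minimum class confidence
#' @param image_id identifier stored in the `image` column
#' @return detection data.frame (image, class, conf, corners)
#' @export
decode_predictions <- function(preds, strides = c(8L, 16L, 32L), reg_max = 16L,
                               conf_thresh = 0.25, image_id = "img") {
  rows <- list()
  for (li in seq_along(preds)) {
    cls <- preds[[li]]$cls$value
    reg <- preds[[li]]$reg$value
    d <- dim(cls); nc <- d[1]; H <- d[2]; W <- d[3]
    p <- 1 / (1 + exp(-matrix(cls, nrow = nc)))   # nc x anchors
    conf <- apply(p, 2, max)
    cl <- max.col(t(p)) - 1L
    keep <- which(conf >= conf_thresh)
    if (!length(keep)) next
    dist <- decode_distances(reg, reg_max)
    pos_area <- (dist[keep, 1] + dist[keep, 3]) > 1e-6 &
                (dist[keep, 2] + dist[keep, 4]) > 1e-6
    keep <- keep[pos_area]
    if (!length(keep)) next
    an <- anchor_centers(H, W, strides[li])
    s <- strides[li]
    rows[[length(rows) + 1L]] <- data.frame(
      image = image_id, class = cl[keep], conf = conf[keep],
      x_min = an$cx[keep] - dist[keep, 1] * s,
      y_min = an$cy[keep] - dist[keep, 2] * s,
      x_max = an$cx[keep] + dist[keep, 3] * s,
      y_max = an$cy[keep] + dist[keep, 4] * s)
  }
  if (!length(rows))
    return(data.frame(image = character(), class = integer(), conf = numeric(),
                      x_min = numeric(), y_min = numeric(), x_max = numeric(),
                      y_max = numeric()))
  do.call(rbind, rows)
}

# task-aligned assignment. truths_px: data.frame class, x_min..y_max (pixels).
# Returns per-anchor assignment over the flattened multi-level anchor list.
assign_targets <- function(preds, truths_px, strides, reg_max, nc,
                           topk = 10L, alpha = 0.5, beta = 6.0) {
  cxs <- numeric(0); cys <- numeric(0); sts <- numeric(0); level <- integer(0)
  pmat <- NULL; boxes <- NULL
  for (li in seq_along(preds)) {
    cls <- preds[[li]]$cls$value
    d <- dim(cls); H <- d[2]; W <- d[3]
    an <- anchor_centers(H, W, strides[li])
    cxs <- c(cxs, an$cx); cys <- c(cys, an$cy)
    sts <- c(sts, rep(strides[li], H * W)); level <- c(level, rep(li, H * W))
    p <- 1 / (1 + exp(-matrix(cls, nrow = d[1])))
    pmat <- cbind(pmat, p)
    dist <- decode_distances(preds[[li]]$reg$value, reg_max)
    boxes <- rbind(boxes, cbind(an$cx - dist[, 1] * strides[li],
                                an$cy - dist[, 2] * strides[li],
                                an$cx + dist[, 3] * strides[li],
                                an$cy + dist[, 4] * strides[li]))
  }
  n_anchor <- length(cxs)
  gt_of <- integer(n_anchor)           # 0 = background
  align_of <- numeric(n_anchor)
  iou_of <- numeric(n_anchor)
  if (nrow(truths_px)) {
    align_mat <- matrix(0, n_anchor, nrow(truths_px))
    iou_mat <- matrix(0, n_anchor, nrow(truths_px))
    for (g in seq_len(nrow(truths_px))) {
      tb <- as.numeric(truths_px[g, c("x_min", "y_min", "x_max", "y_max")])
      inside <- cxs > tb[1] & cxs < tb[3] & cys > tb[2] & cys < tb[4]
      cand <- which(inside)
      if (!length(cand)) {  # box smaller than a cell: nearest anchor per level
        d2 <- (cxs - mean(tb[c(1, 3)]))^2 + (cys - mean(tb[c(2, 4)]))^2
        cand <- vapply(split(seq_along(d2), level),
                       function(ix) ix[which.min(d2[ix])], integer(1))
      }
      ious <- iou_one_many(tb, boxes[cand, , drop = FALSE])
      sc <- pmat[truths_px$class[g] + 1L, cand]
      al <- sc^alpha * pmax(ious, 0)^beta
      keep <- cand[order(-al)][seq_len(min(topk, length(cand)))]
      align_mat[keep, g] <- al[match(keep, cand)]
      iou_mat[keep, g] <- pmax(ious[match(keep, cand)], 0)
    }
    for (a in which(rowSums(align_mat > 0) > 0)) {
      g <- which.max(align_mat[a, ])
      gt_of[a] <- g; align_of[a] <- align_mat[a, g]; iou_of[a] <- iou_mat[a, g]
    }
    # normalize: per gt, scaled so the best anchor's target equals its IoU
    for (g in seq_len(nrow(truths_px))) {
      sel <- which(gt_of == g)
      if (!length(sel)) next
      amax <- max(align_of[sel]); imax <- max(iou_of[sel])
      align_of[sel] <- if (amax > 0) align_of[sel] / amax * imax else imax
      if (all(align_of[sel] == 0)) align_of[sel] <- 1e-3  # cold start
    }
  }
  list(gt = gt_of, score = align_of, cx = cxs, cy = cys, stride = sts,
       level = level)
}

# CIoU between predicted box tensors (vectors) and constant gt boxes
ciou_loss_terms <- function(x1, y1, x2, y2, gt) {
  g1 <- tz_const(gt[, 1]); g2 <- tz_const(gt[, 2])
  g3 <- tz_const(gt[, 3]); g4 <- tz_const(gt[, 4])
  zero <- tz_const(rep(0, length(gt[, 1])))
  iw <- op_pmax(op_sub(op_pmin(x2, g3), op_pmax(x1, g1)), zero)
  ih <- op_pmax(op_sub(op_pmin(y2, g4), op_pmax(y1, g2)), zero)
  inter <- op_mul(iw, ih)
  area_p <- op_mul(op_sub(x2, x1), op_sub(y2, y1))
  area_g <- (gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2])
  union <- op_sub(op_add(area_p, tz_const(area_g)), inter)
  iou <- op_div(inter, op_shift(union, 1e-9))
  # enclosing box diagonal
  cw <- op_sub(op_pmax(x2, g3), op_pmin(x1, g1))
  chh <- op_sub(op_pmax(y2, g4), op_pmin(y1, g2))
  c2 <- op_shift(op_add(op_square(cw), op_square(chh)), 1e-9)
  rho2 <- op_add(
    op_square(op_scale(op_sub(op_add(x1, x2), tz_const(gt[, 1] + gt[, 3])), 0.5)),
    op_square(op_scale(op_sub(op_add(y1, y2), tz_const(gt[, 2] + gt[, 4])), 0.5)))
  wg <- gt[, 3] - gt[, 1]; hg <- gt[, 4] - gt[, 2]
  vterm <- op_square(op_scale(op_sub(tz_const(atan(wg / hg)),
                                     op_atan(op_div(op_sub(x2, x1),
                                                    op_shift(op_sub(y2, y1), 1e-9)))),
                              2 / pi))
  avals <- as.numeric(vterm$value) /
    (1 - as.numeric(iou$value) + as.numeric(vterm$value) + 1e-9)
  ciou <- op_sub(iou, op_add(op_div(rho2, c2), op_mul(vterm, tz_const(avals))))
  op_sub(tz_const(rep(1, length(avals))), ciou)  # 1 - CIoU
}

#' Composite detection loss (CIoU + BCE + DFL with task-aligned assignment)
#'
#' @param preds per-level predictions from [model_forward()] (training mode)
#' @param truths data.frame of normalized labels (class, cx, cy, w, h)
#' @param imgsz input image size in pixels
#' @param cfg a [train_config()] (component weights)
#' @param strides per-level strides
#' @param reg_max,nc head geometry
#' @return list with tz_tensor `total` and numeric `components`
#' @export
detection_loss <- function(preds, truths, imgsz, cfg = train_config(),
                           strides = c(8L, 16L, 32L), reg_max = 16L, nc = 5L) {
  truths_px <- if (nrow(truths)) data.frame(
    class = truths$class,
    x_min = (truths$cx - truths$w / 2) * imgsz,
    y_min = (truths$cy - truths$h / 2) * imgsz,
    x_max = (truths$cx + truths$w / 2) * imgsz,
    y_max = (truths$cy + truths$h / 2) * imgsz)
  else data.frame(class = integer(), x_min = numeric(), y_min = numeric(),
                  x_max = numeric(), y_max = numeric())
  asg <- assign_targets(preds, truths_px, strides, reg_max, nc)
  # classification BCE over every anchor and class
  targ_list <- list(); off <- 0L
  per_level_n <- integer(length(preds))
  for (li in seq_along(preds)) {
    d <- dim(preds[[li]]$cls$value); per_level_n[li] <- d[2] * d[3]
  }
  targets <- matrix(0, nc, sum(per_level_n))
  pos <- which(asg$gt > 0)
  for (a in pos) targets[truths_px$class[asg$gt[a]] + 1L, a] <- asg$score[a]
  cls_flat <- op_cat(lapply(preds, function(l)
    op_reshape(l$cls, c(dim(l$cls$value)[1], dim(l$cls$value)[2] * dim(l$cls$value)[3], 1L))), 2L)
  cls_loss <- op_bce_logits(cls_flat,
                            array(targets, dim = c(nc, sum(per_level_n), 1L)))
  denom <- max(sum(asg$score), 1)
  cls_loss <- op_scale(cls_loss, 1 / denom)
  comp <- c(box = 0, cls = as.numeric(cls_loss$value), dfl = 0)
  total <- op_scale(cls_loss, cfg$lambda_cls)
  if (length(pos)) {
    # gather the 4*reg_max regression logits of every positive anchor
    level_off <- c(0L, cumsum(per_level_n))
    by_level <- split(pos, asg$level[pos])
    reg_cols <- list(); ord_pos <- integer(0)
    for (lv in names(by_level)) {
      li <- as.integer(lv)
      d <- dim(preds[[li]]$reg$value); K <- d[1]; H <- d[2]
      aidx <- by_level[[lv]] - level_off[li]          # anchor index within level
      flat <- outer(seq_len(K), (aidx - 1L) * K, `+`) # K x n flat indices
      reg_cols[[lv]] <- op_reshape(op_gather(preds[[li]]$reg, as.integer(flat)),
                                   c(K, length(aidx), 1L))
      ord_pos <- c(ord_pos, by_level[[lv]])
    }
    regs <- if (length(reg_cols) > 1L) op_cat(reg_cols, 2L) else reg_cols[[1]]
    n_pos <- length(ord_pos)
    gt <- as.matrix(truths_px[asg$gt[ord_pos], c("x_min", "y_min", "x_max", "y_max")])
    # box/DFL terms use the weights as a weighted mean so the localization
    # gradient keeps its scale even while the alignment scores are still small
    wts <- asg$score[ord_pos] / max(sum(asg$score[ord_pos]), 1e-9)
    denom <- 1
    st <- asg$stride[ord_pos]; acx <- asg$cx[ord_pos]; acy <- asg$cy[ord_pos]
    bins <- matrix(0:(reg_max - 1), nrow = 1)
    sides <- vector("list", 4)
    lsm_sides <- vector("list", 4)
    for (s in 1:4) {
      lo <- op_reshape(op_narrow(regs, 1L, (s - 1L) * reg_max + 1L, reg_max),
                       c(reg_max, n_pos))
      lsm_sides[[s]] <- op_logsoftmax(lo, margin = 1)
      sm <- op_softmax(lo, margin = 1)
      sides[[s]] <- op_reshape(op_matmul(tz_const(bins), sm), n_pos)  # distances
    }
    x1 <- op_sub(tz_const(acx), op_mul(sides[[1]], tz_const(st)))
    y1 <- op_sub(tz_const(acy), op_mul(sides[[2]], tz_const(st)))
    x2 <- op_add(tz_const(acx), op_mul(sides[[3]], tz_const(st)))
    y2 <- op_add(tz_const(acy), op_mul(sides[[4]], tz_const(st)))
    box_l <- op_scale(op_sum(op_mul(ciou_loss_terms(x1, y1, x2, y2, gt),
                                    tz_const(wts))), 1 / denom)
    # distribution-focal loss toward the two integer bins around each target
    tgt_d <- cbind((acx - gt[, 1]) / st, (acy - gt[, 2]) / st,
                   (gt[, 3] - acx) / st, (gt[, 4] - acy) / st)
    tgt_d <- pmin(pmax(tgt_d, 0), reg_max - 1 - 1e-3)
    dfl_l <- NULL
    for (s in 1:4) {
      t <- tgt_d[, s]; lo_bin <- floor(t); wl <- lo_bin + 1 - t; wr <- t - lo_bin
      wmat <- matrix(0, reg_max, n_pos)
      wmat[cbind(lo_bin + 1L, seq_len(n_pos))] <- wl
      wmat[cbind(pmin(lo_bin + 2L, reg_max), seq_len(n_pos))] <-
        wmat[cbind(pmin(lo_bin + 2L, reg_max), seq_len(n_pos))] + wr
      wmat <- sweep(wmat, 2, wts, "*")
      term <- op_neg(op_sum(op_mul(lsm_sides[[s]], tz_const(wmat))))
      dfl_l <- if (is.null(dfl_l)) term else op_add(dfl_l, term)
    }
    dfl_l <- op_scale(dfl_l, 1 / (4 * denom))
    comp["box"] <- as.numeric(box_l$value)
    comp["dfl"] <- as.numeric(dfl_l$value)
    total <- op_add(total, op_add(op_scale(box_l, cfg$lambda_box),
                                  op_scale(dfl_l, cfg$lambda_dfl)))
  }
  list(total = total, components = comp)
}

# -- augmentations -----------------------------------------------------------

hsv_jitter <- function(image, hsv_h, hsv_s, hsv_v) {
  gains <- 1 + stats::runif(3, -1, 1) * c(hsv_h, hsv_s, hsv_v)
  d <- dim(image)
  m <- t(matrix(image, ncol = 3))          # 3 x N, rows R,G,B
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] * gains[1]) %% 1
  hsv[2, ] <- pmin(hsv[2, ] * gains[2], 1)
  hsv[3, ] <- pmin(hsv[3, ] * gains[3], 1)
  rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
  array(t(rgb), dim = d)
}

flip_horizontal <- function(image, labels) {
  image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  labels$cx <- 1 - labels$cx
  list(image = image, labels = labels)
}

translate_scale <- function(image, labels, translate, scale) {
  d <- dim(image)
  sc <- 1 + stats::runif(1, -scale, scale)
  tx <- stats::runif(1, -translate, translate)
  ty <- stats::runif(1, -translate, translate)
  out <- array(0.447, dim = d)   # canvas gray
  nh <- max(2L, round(d[1] * sc)); nw <- max(2L, round(d[2] * sc))
  rs <- resize_image(image, nh, nw)
  oy <- round(ty * d[1]); ox <- round(tx * d[2])
  sy <- max(1L, 1L - oy); sx <- max(1L, 1L - ox)
  dy <- max(1L, 1L + oy); dx <- max(1L, 1L + ox)
  len_y <- min(nh - sy, d[1] - dy) + 1L; len_x <- min(nw - sx, d[2] - dx) + 1L
  if (len_y > 0 && len_x > 0)
    out[dy:(dy + len_y - 1L), dx:(dx + len_x - 1L), ] <-
      rs[sy:(sy + len_y - 1L), sx:(sx + len_x - 1L), , drop = FALSE]
  labels$cx <- labels$cx * sc * d[2] / d[2] + ox / d[2]
  labels$cy <- labels$cy * sc + oy / d[1]
  labels$w <- labels$w * sc; labels$h <- labels$h * sc
  # clip boxes to the canvas, drop those mostly outside
  x1 <- pmax(labels$cx - labels$w / 2, 0); x2 <- pmin(labels$cx + labels$w / 2, 1)
  y1 <- pmax(labels$cy - labels$h / 2, 0); y2 <- pmin(labels$cy + labels$h / 2, 1)
  keep <- (x2 - x1) > 0.01 & (y2 - y1) > 0.01
  labels <- data.frame(class = labels$class, cx = (x1 + x2) / 2,
                       cy = (y1 + y2) / 2, w = x2 - x1, h = y2 - y1)[keep, ]
  list(image = out, labels = labels)
}

mosaic_compose <- function(samples, imgsz) {
  # four images in quadrants of one canvas
  out <- array(0.447, dim = c(imgsz, imgsz, 3))
  half <- imgsz %/% 2L
  lab <- list()
  for (q in 1:4) {
    s <- samples[[q]]
    im <- resize_image(s$image, half, half)
    ro <- if (q %in% c(1, 2)) 0L else half
    co <- if (q %in% c(1, 3)) 0L else half
    out[(ro + 1):(ro + half), (co + 1):(co + half), ] <- im
    l <- s$labels
    if (nrow(l)) {
      l$cx <- (l$cx * half + co) / imgsz
      l$cy <- (l$cy * half + ro) / imgsz
      l$w <- l$w / 2; l$h <- l$h / 2
      lab[[length(lab) + 1]] <- l
    }
  }
  list(image = out,
       labels = if (length(lab)) do.call(rbind, lab)
                else data.frame(class = integer(), cx = numeric(), cy = numeric(),
                                w = numeric(), h = numeric()))
}

augment_sample <- function(dataset, idx, cfg) {
  # letterbox-free square resize; normalized labels are unchanged by it
  get1 <- function(i) list(image = resize_image(dataset$images[[i]], cfg$imgsz, cfg$imgsz),
                           labels = dataset$labels[[i]])
  s <- if (cfg$augment && stats::runif(1) < cfg$mosaic) {
    others <- sample(seq_along(dataset$images), 3, replace = TRUE)
    mosaic_compose(lapply(c(idx, others), get1), cfg$imgsz)
  } else get1(idx)
  if (cfg$augment) {
    s2 <- translate_scale(s$image, s$labels, cfg$translate, cfg$scale)
    if (nrow(s2$labels)) s <- s2   # keep at least one target when possible
    if (stats::runif(1) < cfg$fliplr) s <- flip_horizontal(s$image, s$labels)
    if (cfg$hsv_h + cfg$hsv_s + cfg$hsv_v > 0)
      s$image <- hsv_jitter(s$image, cfg$hsv_h, cfg$hsv_s, cfg$hsv_v)
  }
  s
}

# -- optimizer ---------------------------------------------------------------

clip_scale <- function(params, clip_norm = 100) {
  # global gradient-norm clipping keeps the first noisy updates bounded
  if (!is.finite(clip_norm)) return(1)
  gn <- sqrt(sum(vapply(params, function(p)
    if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
  if (gn > clip_norm) clip_norm / gn else 1
}

decay_of <- function(p, weight_decay) {
  # decay only multi-dimensional weights, not biases/normalization affines
  if (is.null(dim(p$value)) || length(dim(p$value)) < 2L) 0 else weight_decay
}

sgd_step <- function(params, state, lr, momentum, weight_decay) {
  scale <- clip_scale(params)
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * scale + decay_of(p, weight_decay) * p$value
    v <- state[[nm]] %||% 0
    v <- momentum * v - lr * g
    state[[nm]] <- v
    p$value <- p$value + v
  }
  invisible(state)
}

adamw_step <- function(params, state, lr, momentum, weight_decay,
                       beta2 = 0.999, eps = 1e-8) {
  scale <- clip_scale(params)
  state$t <- (state$t %||% 0) + 1
  t <- state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    m <- state[[paste0(nm, ".m")]] %||% 0
    v <- state[[paste0(nm, ".v")]] %||% 0
    m <- momentum * m + (1 - momentum) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[paste0(nm, ".m")]] <- m
    state[[paste0(nm, ".v")]] <- v
    mh <- m / (1 - momentum^t)
    vh <- v / (1 - beta2^t)
    p$value <- p$value - lr * (mh / (sqrt(vh) + eps) +
                               decay_of(p, weight_decay) * p$value)
  }
  invisible(state)
}

# -- evaluation --------------------------------------------------------------

#' Evaluate a model on a labeled image set
#'
#' Runs inference on every image, decodes at a low confidence floor, applies
#' class-aware NMS and scores the result against the ground truth.
#'
#' @param model an `edgebcs_model`
#' @param images list of H x W x 3 arrays
#' @param labels list of normalized label data.frames (class, cx, cy, w, h)
#' @param cfg a [train_config()] (NMS threshold)
#' @param conf_thresh decode confidence floor (low for AP computation)
#' @param use_batch_stats normalize BN by each input's own spatial moments
#'   instead of the running statistics; this is the mode a net trained at
#'   batch size one was fit under, and what the training loop's internal
#'   validation uses
#' @return list with `map50`, `map50_95`, `precision`, `recall`, `dets`
#' @export
evaluate_model <- function(model, images, labels, cfg = train_config(),
                           conf_thresh = 0.001, use_batch_stats = FALSE) {
  if (use_batch_stats)
    return(with_batch_stats(evaluate_model(model, images, labels, cfg,
                                           conf_thresh, FALSE)))
  dets <- list(); truths <- list()
  for (i in seq_along(images)) {
    img <- resize_image(images[[i]], cfg$imgsz, cfg$imgsz)
    H <- dim(img)[1]; W <- dim(img)[2]
    preds <- model_forward(model, image_to_tensor(img), train = FALSE)
    di <- decode_predictions(preds, model$strides, model$cfg$reg_max,
                             conf_thresh, image_id = sprintf("img%04d", i))
    di <- nms(di, cfg$nms_iou)
    if (nrow(di) > 300L) di <- di[seq_len(300L), ]
    dets[[i]] <- di
    l <- labels[[i]]
    truths[[i]] <- data.frame(image = sprintf("img%04d", i), class = l$class,
                              x_min = (l$cx - l$w / 2) * W,
                              y_min = (l$cy - l$h / 2) * H,
                              x_max = (l$cx + l$w / 2) * W,
                              y_max = (l$cy + l$h / 2) * H)
  }
  dets <- do.call(rbind, dets); truths <- do.call(rbind, truths)
  ms <- map_score(dets, truths)
  pr <- pr_counts(dets[dets$conf >= 0.25, , drop = FALSE], truths)
  list(map50 = ms$map50, map50_95 = ms$map50_95, ap50 = ms$ap50,
       precision = pr$precision, recall = pr$recall, dets = dets)
}

# -- training loop -----------------------------------------------------------

#' Train a detector
#'
#' SGD with momentum, weight decay and linear learning-rate decay; per-epoch
#' loss logging and periodic validation; optional focal+global distillation
#' from a frozen teacher on the three neck levels (masks recomputed per
#' level). Fully reproducible under `cfg$seed`.
#'
#' @param model an `edgebcs_model` (modified in place)
#' @param dataset list with `images` and `labels` (e.g. from
#'   [generate_synthetic_dataset()]), used for training
#' @param cfg a [train_config()]
#' @param val optional list with `images`/`labels` for validation (defaults
#'   to the training set, matching a no-independent-test-set protocol)
#' @param teacher optional frozen `edgebcs_model` used when `cfg$distill`
#' @param eval_every validate every k epochs (0 = only at the end)
#' @param checkpoint_path optional path; best-mAP weights are saved there
#' @param verbose print per-epoch lines
#' @param stop_at_map optional mAP@50 level at which training stops early
#' @return list with `history` (per-epoch data.frame) and `best_map50`
#' @export
train <- function(model, dataset, cfg = train_config(), val = NULL,
                  teacher = NULL, eval_every = 0L, checkpoint_path = NULL,
                  verbose = FALSE, stop_at_map = NULL) {
  if (!length(dataset$images)) stop("empty training split")
  set.seed(cfg$seed)
  val <- val %||% dataset
  params <- model_params(model)
  state <- new.env(parent = emptyenv())
  opt_state <- list()
  history <- list()
  best <- -Inf
  n <- length(dataset$images)
  adapters <- NULL
  # calibrate BN running moments on a data sample before the first update:
  # training normalizes with the running statistics, which start at (0, 1)
  # and would otherwise let activation scales collapse through the depth
  calib_idx <- sample(n, min(n, 16L))
  for (k in seq_along(calib_idx)) {
    .tz$bn_calib <- k
    invisible(model_forward(model,
      image_to_tensor(resize_image(dataset$images[[calib_idx[k]]],
                                   cfg$imgsz, cfg$imgsz)), train = TRUE))
  }
  .tz$bn_calib <- NULL
  for (p in params) p$requires_grad <- TRUE
  # optimizer: the family's auto rule picks AdamW (class-count-scaled lr) for
  # short runs and the stated SGD settings for full-scale ones
  iters <- cfg$epochs * ceiling(n / cfg$batch)
  opt_kind <- cfg$optimizer
  if (opt_kind == "auto") opt_kind <- if (iters < 10000) "adamw" else "sgd"
  if (opt_kind == "adamw" && cfg$optimizer == "auto") {
    lr_base <- round(0.002 * 5 / (4 + model$cfg$nc), 6)
    mom <- 0.9
  } else {
    lr_base <- cfg$lr0
    mom <- cfg$momentum
  }
  warmup <- min(3, cfg$epochs %/% 10)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_base * (1 - (epoch - 1) / max(cfg$epochs, 1) * (1 - cfg$lrf))
    if (epoch <= warmup) lr <- lr * epoch / (warmup + 1)  # linear warmup
    idx <- sample(n)
    ep_loss <- 0; ep_comp <- c(box = 0, cls = 0, dfl = 0, distill = 0)
    nb <- 0
    for (start in seq(1, n, by = cfg$batch)) {
      bidx <- idx[start:min(start + cfg$batch - 1, n)]
      tz_zero_grad(params)
      bloss <- 0
      for (i in bidx) {
        s <- augment_sample(dataset, i, cfg)
        x <- image_to_tensor(s$image)
        preds <- model_forward(model, x, train = TRUE)
        dl <- detection_loss(preds, s$labels, dim(s$image)[1], cfg,
                             model$strides, model$cfg$reg_max, model$cfg$nc)
        loss <- dl$total
        if (cfg$distill && !is.null(teacher)) {
          tp <- model_forward(teacher, x, train = FALSE)
          sn <- attr(preds, "neck_features")
          tn <- attr(tp, "neck_features")
          for (li in seq_along(sn)) {
            ds <- dim(sn[[li]]$value); dt <- dim(tn[[li]]$value)
            f_s <- sn[[li]]
            if (ds[1] != dt[1]) {  # trainable 1x1 adapter on the student side
              if (is.null(adapters)) adapters <- vector("list", length(sn))
              if (is.null(adapters[[li]])) {
                adapters[[li]] <- m_conv(ds[1], dt[1], 1, act = "identity", bn = FALSE, bias = TRUE)
                ap <- mod_params(adapters[[li]])
                names(ap) <- paste0("distill_adapter", li, ".", names(ap))
                for (p in ap) p$requires_grad <- TRUE
                params <- c(params, ap)
              }
              f_s <- fwd(adapters[[li]], f_s, train = TRUE)
            }
            mk <- build_focal_masks(s$labels, dim(tn[[li]]$value),
                                    tn[[li]]$value, cfg$distill_cfg)
            fl <- fgd_loss(tn[[li]]$value, f_s, mk, cfg$distill_cfg)
            loss <- op_add(loss, fl$total)
            ep_comp["distill"] <- ep_comp["distill"] +
              sum(fl$components * c(cfg$distill_cfg$w_fg, cfg$distill_cfg$w_bg,
                                    cfg$distill_cfg$w_at, cfg$distill_cfg$w_gl))
          }
        }
        loss <- op_scale(loss, 1 / length(bidx))
        tz_backward(loss)
        bloss <- bloss + as.numeric(loss$value)
        ep_comp[c("box", "cls", "dfl")] <- ep_comp[c("box", "cls", "dfl")] +
          dl$components / length(bidx)
      }
      opt_state <- if (opt_kind == "adamw")
        adamw_step(params, opt_state, lr, mom, cfg$weight_decay)
      else sgd_step(params, opt_state, lr, mom, cfg$weight_decay)
      ep_loss <- ep_loss + bloss; nb <- nb + 1
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / nb,
                      box = ep_comp["box"] / nb, cls = ep_comp["cls"] / nb,
                      dfl = ep_comp["dfl"] / nb,
                      distill = ep_comp["distill"] / nb,
                      map50 = NA_real_)
    do_eval <- (eval_every > 0L && epoch %% eval_every == 0L) || epoch == cfg$epochs
    if (do_eval) {
      ev <- evaluate_model(model, val$images, val$labels, cfg,
                           use_batch_stats = TRUE)
      row$map50 <- ev$map50
      if (ev$map50 > best) {
        best <- ev$map50
        if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
      }
    }
    history[[epoch]] <- row
    if (!is.null(stop_at_map) && !is.na(row$map50) && best >= stop_at_map) {
      if (verbose) cat(sprintf("epoch %3d  mAP50 %.3f >= %.2f, stopping\n",
                               epoch, best, stop_at_map))
      history <- history[seq_len(epoch)]
      break
    }
    if (verbose)
      cat(sprintf("epoch %3d  lr %.5f  loss %.4f  box %.3f cls %.3f dfl %.3f%s\n",
                  epoch, lr, row$loss, row$box, row$cls, row$dfl,
                  if (!is.na(row$map50)) sprintf("  mAP50 %.3f", row$map50) else ""))
  }
  for (p in params) p$requires_grad <- FALSE
  list(history = do.call(rbind, history), best_map50 = best)
}
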