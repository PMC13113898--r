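# Focal and global feature distillation between a large teacher detector and
# the lightweight student, applied to the neck feature maps during training
# only. The focal branch separates foreground (inside ground-truth boxes)
# from background with a binary mask, weights pixels inversely to the area
# they belong to (scale mask), and emphasizes informative positions/channels
# with tempered-softmax attention masks derived from the teacher; an
# attention-transfer term pulls the student's attention toward the teacher's.
# The global branch matches attention-pooled global context vectors. The
# exact loss algebra follows the cited focal+global distillation method; all
# weights and the temperature are exposed in the configuration.

#' Distillation loss configuration
#'
#' @param w_fg,w_bg foreground/background focal-feature weights
#' @param w_at attention-transfer weight
#' @param w_gl global-context weight
#' @param temperature tempered-softmax temperature for the attention masks
#' @return list of class `fgd_config`
#' @export
fgd_config <- function(w_fg = 1.6e-3, w_bg = 8e-4, w_at = 8e-4,
                       w_gl = 8e-6, temperature = 0.5) {
  if (any(c(w_fg, w_bg, w_at, w_gl) < 0)) stop("loss weights must be >= 0")
  structure(list(w_fg = w_fg, w_bg = w_bg, w_at = w_at, w_gl = w_gl,
                 temperature = temperature), class = "fgd_config")
}

# tempered softmax of a plain numeric vector
tsoftmax <- function(v, temperature) {
  z <- v / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Build the focal-distillation masks for one feature level
#'
#' @param boxes data.frame of normalized boxes (cx, cy, w, h in [0, 1]); may
#'   have zero rows (empty image)
#' @param feature_shape c(C, H, W) of the level
#' @param teacher_feature array c(C, H, W), the teacher's map at this level
#' @param cfg an [fgd_config()]
#' @return list of class `fgd_masks`: binary M (H x W), scale S (H x W),
#'   spatial attention `a_s` (H x W, sums to H*W), channel attention `a_c`
#'   (length C, sums to C)
#' @export
build_focal_masks <- function(boxes, feature_shape, teacher_feature, cfg = fgd_config()) {
  C <- feature_shape[1]; H <- feature_shape[2]; W <- feature_shape[3]
  M <- matrix(0, H, W)
  S <- matrix(0, H, W)
  if (nrow(boxes)) {
    area_of <- matrix(Inf, H, W)  # smallest covering box area per cell
    cxs <- (col(M) - 0.5) / W
    cys <- (row(M) - 0.5) / H
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      inside <- cxs >= b$cx - b$w / 2 & cxs <= b$cx + b$w / 2 &
                cys >= b$cy - b$h / 2 & cys <= b$cy + b$h / 2
      M[inside] <- 1
      area_cells <- max(b$w * W * b$h * H, 1)
      area_of[inside] <- pmin(area_of[inside], area_cells)
    }
    S[M == 1] <- 1 / area_of[M == 1]
  }
  n_bg <- sum(M == 0)
  if (n_bg > 0) S[M == 0] <- 1 / n_bg
  absmean_sp <- apply(abs(teacher_feature), c(2, 3), mean)    # H x W
  absmean_ch <- apply(abs(teacher_feature), 1, mean)          # C
  a_s <- matrix(H * W * tsoftmax(as.numeric(absmean_sp), cfg$temperature), H, W)
  a_c <- C * tsoftmax(absmean_ch, cfg$temperature)
  structure(list(M = M, S = S, a_s = a_s, a_c = a_c), class = "fgd_masks")
}

# attention-pooled global context vector (length-C tensor); parameter-free
global_context <- function(f, temperature) {
  d <- dim(f$value)
  att <- tsoftmax(as.numeric(apply(abs(f$value), c(2, 3), mean)), temperature)
  fm <- op_reshape(f, c(d[1], d[2] * d[3]))
  op_matmul(fm, tz_const(matrix(att, ncol = 1)))
}

#' Focal + global distillation loss between teacher and student features
#'
#' Both maps must share one shape (bridge student channels with a 1x1 adapter
#' beforehand if they differ). The teacher is treated as a constant; the
#' student may be a tz_tensor carrying gradients.
#'
#' @param f_t teacher feature, array or tz_tensor c(C, H, W)
#' @param f_s student feature, array or tz_tensor of the same shape
#' @param masks an `fgd_masks` object from [build_focal_masks()]
#' @param cfg an [fgd_config()]
#' @return list with tz_tensor `total` and numeric `components`
#'   (fg, bg, at, gl)
#' @export
fgd_loss <- function(f_t, f_s, masks, cfg = fgd_config()) {
  if (!inherits(f_t, "tz_tensor")) f_t <- tz_const(f_t)
  if (!inherits(f_s, "tz_tensor")) f_s <- tz_const(f_s)
  d <- dim(f_t$value)
  if (!identical(d, dim(f_s$value)))
    stop("teacher/student shape mismatch; add a 1x1 adapter on the student")
  C <- d[1]; H <- d[2]; W <- d[3]
  wmap <- function(hw) tz_const(array(rep(as.numeric(hw), each = C), dim = d))
  a_c3 <- tz_const(array(masks$a_c, dim = d))
  diff2 <- op_square(op_sub(f_t, f_s))
  att <- op_mul(wmap(masks$a_s), a_c3)
  fg <- op_sum(op_mul(diff2, op_mul(wmap(masks$M * masks$S), att)))
  bg <- op_sum(op_mul(diff2, op_mul(wmap((1 - masks$M) * masks$S), att)))
  # attention transfer: L1 between teacher and student attention maps
  t_tmp <- cfg$temperature
  s_sp <- op_softmax(op_scale(op_reshape(op_mean_dim(op_abs(f_s), 1L), c(H * W, 1L)),
                              1 / t_tmp), margin = 1)
  s_ch <- op_softmax(op_scale(op_reshape(
    op_mean_dim(op_mean_dim(op_abs(f_s), 3L), 2L), c(C, 1L)), 1 / t_tmp), margin = 1)
  at_sp <- op_sum(op_abs(op_sub(op_scale(s_sp, H * W),
                                tz_const(matrix(as.numeric(masks$a_s), ncol = 1)))))
  at_ch <- op_sum(op_abs(op_sub(op_scale(s_ch, C),
                                tz_const(matrix(masks$a_c, ncol = 1)))))
  at <- op_add(at_sp, at_ch)
  gl <- op_sum(op_square(op_sub(global_context(f_t, t_tmp),
                                global_context(f_s, t_tmp))))
  total <- op_add(op_add(op_scale(fg, cfg$w_fg), op_scale(bg, cfg$w_bg)),
                  op_add(op_scale(at, cfg$w_at), op_scale(gl, cfg$w_gl)))
  list(total = total,
       components = c(fg = as.numeric(fg$value), bg = as.numeric(bg$value),
                      at = as.numeric(at$value), gl = as.numeric(gl$value)))
}
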