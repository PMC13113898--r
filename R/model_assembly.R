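# Assembly of the detector variants and the complexity profiler.
#
# The baseline reconstructs the published YOLO11 nano topology (C3k2 stages,
# SPPF, C2PSA, concatenation PAN neck, decoupled head). The ablation ladder
# swaps in, cumulatively: the PSFF gated-fusion neck, TASM star stages in
# place of every C3k2 stage, and the grouped EGDH head.

make_div <- function(x, d = 8L) max(d, as.integer(round(x / d) * d))

#' Model configuration
#'
#' @param variant one of "baseline", "psff", "psff-tasm", "full"
#' @param nc class count (default 5: BCS classes 3-7)
#' @param width width multiplier (nano = 0.25)
#' @param depth depth multiplier (nano = 0.5; stage repeats scale with it)
#' @param max_channels channel cap before width scaling (1024)
#' @param reg_max distribution-focal bins per box side
#' @param expansion star-block expansion ratio (calibrated default, see
#'   [calibrate_widths()])
#' @param up_kernel PSFF transposed-conv kernel size
#' @return a list of class `edgebcs_config`
#' @export
model_config <- function(variant = c("full", "baseline", "psff", "psff-tasm"),
                         nc = 5L, width = 0.25, depth = 0.5,
                         max_channels = 1024L, reg_max = 16L,
                         expansion = 3.25, expansion_deep = 1, up_kernel = 2L,
                         neck_width = NULL, neck_repeats = c(2L, 1L, 1L, 1L)) {
  variant <- match.arg(variant)
  structure(list(variant = variant, nc = as.integer(nc), width = width,
                 depth = depth, max_channels = as.integer(max_channels),
                 reg_max = as.integer(reg_max), expansion = expansion,
                 expansion_deep = expansion_deep %||% expansion,
                 up_kernel = as.integer(up_kernel), neck_width = neck_width,
                 neck_repeats = as.integer(neck_repeats)),
            class = "edgebcs_config")
}

#' Build a detector
#'
#' @param cfg an [model_config()] object (or a variant name)
#' @return a model object (class `edgebcs_model`)
#' @export
build_model <- function(cfg = model_config()) {
  if (is.character(cfg)) cfg <- model_config(cfg)
  w <- cfg$width
  ch <- function(c) make_div(min(c, cfg$max_channels) * w)
  nrep <- function(n) max(1L, as.integer(round(n * cfg$depth)))
  use_tasm <- cfg$variant %in% c("psff-tasm", "full")
  use_psff <- cfg$variant %in% c("psff", "psff-tasm", "full")
  use_egdh <- cfg$variant == "full"
  stage <- function(c1, c2, n, c3k) {
    # deep (c3k) stages carry most parameters at little compute; their star
    # branch width is calibrated separately
    if (use_tasm) tasm_module(c1, c2, n = n, expansion =
                                if (c3k) cfg$expansion_deep else cfg$expansion)
    else m_c3k2(c1, c2, n = n, c3k = c3k)
  }
  c64 <- ch(64); c128 <- ch(128); c256 <- ch(256); c512 <- ch(512); c1024 <- ch(1024)
  backbone <- list(
    b0 = m_conv(3L, c64, 3, s = 2),
    b1 = m_conv(c64, c128, 3, s = 2),
    b2 = stage(c128, c256, nrep(2), FALSE),
    b3 = m_conv(c256, c256, 3, s = 2),
    b4 = stage(c256, c512, nrep(2), FALSE),
    b5 = m_conv(c512, c512, 3, s = 2),
    b6 = stage(c512, c512, nrep(2), TRUE),
    b7 = m_conv(c512, c1024, 3, s = 2),
    b8 = stage(c1024, c1024, nrep(2), TRUE),
    b9 = m_sppf(c1024, c1024),
    b10 = m_c2psa(c1024, n = nrep(2)))
  # stage-2/4 hidden split uses e = 0.25 in the published topology
  if (!use_tasm) {
    backbone$b2 <- m_c3k2(c128, c256, nrep(2), FALSE, e = 0.25)
    backbone$b4 <- m_c3k2(c256, c512, nrep(2), FALSE, e = 0.25)
  } else {
    backbone$b2 <- tasm_module(c128, c256, nrep(2), e = 0.25, expansion = cfg$expansion)
    backbone$b4 <- tasm_module(c256, c512, nrep(2), e = 0.25, expansion = cfg$expansion)
  }
  cfg$laterals <- c(c512, c512, c1024)  # backbone P3/P4/P5 channels
  if (use_psff) {
    wn <- cfg$neck_width %||% c256  # constant neck width across levels
    neck <- psff_neck_variant(rep(wn, 3L), cfg, use_tasm)
    head_ch <- rep(wn, 3L)
  } else {
    neck <- list(
      up1 = m_upsample(), cat1 = m_concat(),
      c13 = m_c3k2(c1024 + c512, c512, nrep(2), FALSE),
      up2 = m_upsample(), cat2 = m_concat(),
      c16 = m_c3k2(c512 + c512, c256, nrep(2), FALSE),
      d17 = m_conv(c256, c256, 3, s = 2), cat3 = m_concat(),
      c19 = m_c3k2(c256 + c512, c512, nrep(2), FALSE),
      d20 = m_conv(c512, c512, 3, s = 2), cat4 = m_concat(),
      c22 = m_c3k2(c512 + c1024, c1024, nrep(2), TRUE))
    head_ch <- c(c256, c512, c1024)
  }
  head <- if (use_egdh) egdh_head(head_ch, cfg$nc, cfg$reg_max)
          else m_detect_v11(cfg$nc, head_ch, cfg$reg_max)
  structure(list(cfg = cfg, backbone = backbone, neck = neck, head = head,
                 strides = c(8L, 16L, 32L), head_ch = head_ch),
            class = "edgebcs_model")
}

# PSFF neck whose post-fusion stages are TASM or C3k2 depending on the variant
psff_neck_variant <- function(channels, cfg, use_tasm) {
  nk <- psff_neck(channels, lateral_channels = cfg$laterals,
                  expansion = cfg$expansion, up_kernel = cfg$up_kernel,
                  repeats = cfg$neck_repeats)
  if (!use_tasm) {
    r <- cfg$neck_repeats
    nk$stage3 <- m_c3k2(channels[1], channels[1], r[1], FALSE)
    nk$stage4 <- m_c3k2(channels[2], channels[2], r[2], FALSE)
    nk$stage4b <- m_c3k2(channels[2], channels[2], r[3], FALSE)
    nk$stage5 <- m_c3k2(channels[3], channels[3], r[4], FALSE)
  }
  nk
}

#' Forward pass of a detector on one image
#'
#' @param model an `edgebcs_model`
#' @param image numeric array c(3, H, W), values in `[0, 1]`
#' @param train logical; BN in batch-statistics mode and gradients tracked
#' @return list of three levels, each with `cls` and `reg` tensors
#' @export
model_forward <- function(model, image, train = FALSE) {
  x <- if (inherits(image, "tz_tensor")) image else tz_const(image)
  b <- model$backbone
  x0 <- fwd(b$b0, x, train); x1 <- fwd(b$b1, x0, train)
  x2 <- fwd(b$b2, x1, train); x3 <- fwd(b$b3, x2, train)
  x4 <- fwd(b$b4, x3, train); x5 <- fwd(b$b5, x4, train)
  x6 <- fwd(b$b6, x5, train); x7 <- fwd(b$b7, x6, train)
  x8 <- fwd(b$b8, x7, train); x9 <- fwd(b$b9, x8, train)
  x10 <- fwd(b$b10, x9, train)
  if (inherits(model$neck, "m_psff_neck")) {
    feats <- fwd(model$neck, list(x4, x6, x10), train)
  } else {
    nk <- model$neck
    u1 <- fwd(nk$up1, x10, train)
    c13 <- fwd(nk$c13, fwd(nk$cat1, list(u1, x6), train), train)
    u2 <- fwd(nk$up2, c13, train)
    c16 <- fwd(nk$c16, fwd(nk$cat2, list(u2, x4), train), train)
    d17 <- fwd(nk$d17, c16, train)
    c19 <- fwd(nk$c19, fwd(nk$cat3, list(d17, c13), train), train)
    d20 <- fwd(nk$d20, c19, train)
    c22 <- fwd(nk$c22, fwd(nk$cat4, list(d20, x10), train), train)
    feats <- list(c16, c19, c22)
  }
  preds <- fwd(model$head, feats, train)
  attr(preds, "neck_features") <- feats
  preds
}

# profile backbone+neck+head at a given input size; returns totals and table
profile_model <- function(model, input_size = 640L) {
  s <- c(3L, input_size, input_size)
  rows <- list()
  acc <- function(name, p) {
    force(p)  # force nested profiles before appending, preserving row order
    rows[[length(rows) + 1L]] <<- data.frame(module = name, flops = p$flops,
                                             params = p$params, concats = p$concats)
    p$out
  }
  b <- model$backbone
  shapes <- list()
  for (nm in names(b)) { s <- acc(nm, mod_profile(b[[nm]], s)); shapes[[nm]] <- s }
  s4 <- shapes$b4; s6 <- shapes$b6; s10 <- shapes$b10
  if (inherits(model$neck, "m_psff_neck")) {
    outs <- acc("psff_neck", mod_profile(model$neck, list(s4, s6, s10)))
  } else {
    nk <- model$neck
    u1 <- acc("up1", mod_profile(nk$up1, s10))
    c13 <- acc("c13", mod_profile(nk$c13, acc("cat1", mod_profile(nk$cat1, list(u1, s6)))))
    u2 <- acc("up2", mod_profile(nk$up2, c13))
    c16 <- acc("c16", mod_profile(nk$c16, acc("cat2", mod_profile(nk$cat2, list(u2, s4)))))
    d17 <- acc("d17", mod_profile(nk$d17, c16))
    c19 <- acc("c19", mod_profile(nk$c19, acc("cat3", mod_profile(nk$cat3, list(d17, c13)))))
    d20 <- acc("d20", mod_profile(nk$d20, c19))
    c22 <- acc("c22", mod_profile(nk$c22, acc("cat4", mod_profile(nk$cat4, list(d20, s10)))))
    outs <- list(c16, c19, c22)
  }
  acc("head", mod_profile(model$head, outs))
  tab <- do.call(rbind, rows)
  list(table = tab, flops = sum(tab$flops), params = sum(tab$params),
       concats = sum(tab$concats))
}

#' Layerwise complexity report
#'
#' FLOPs are multiply-accumulates x 2 on the conv/BN-fused inference graph
#' (explicit elementwise fusion ops counted once; activations and pooling
#' free); parameters are counted on the training graph (BN affine parameters
#' included, matching what a checkpoint stores).
#'
#' @param model an `edgebcs_model`
#' @param input_size square input resolution (default 640)
#' @return list with `params`, `gflops`, `fp16_size_mb` and a per-module table
#' @export
complexity_report <- function(model, input_size = 640L) {
  p <- profile_model(model, input_size)
  list(params = p$params, gflops = p$flops / 1e9,
       fp16_size_mb = p$params * 2 / 1e6, table = p$table)
}

#' All trainable parameters of a model, flat named list
#' @param model an `edgebcs_model`
#' @return named list of tensors
#' @export
model_params <- function(model) {
  out <- collect_params(model$backbone)
  nk <- if (inherits(model$neck, "edgebcs_module")) list(neck = model$neck) else model$neck
  out <- c(out, collect_params(nk), collect_params(list(head = model$head)))
  out
}

#' Fold all batch-norm layers into their convolutions (inference graph)
#' @param model an `edgebcs_model`
#' @return the model, modified in place
#' @export
fuse_model <- function(model) {
  for (m in model$backbone) mod_fuse(m)
  if (inherits(model$neck, "edgebcs_module")) mod_fuse(model$neck)
  else for (m in model$neck) mod_fuse(m)
  mod_fuse(model$head)
  invisible(model)
}

# -- checkpoints -------------------------------------------------------------

#' Save model weights as a flat FP16 checkpoint
#'
#' Every learnable parameter is serialized at 16-bit floating precision under
#' its flat name, together with its dims and the model configuration.
#'
#' @param model an `edgebcs_model`
#' @param path output file
#' @return invisibly, the file size in MB
#' @export
save_checkpoint <- function(model, path) {
  ps <- model_params(model)
  payload <- lapply(ps, function(p)
    list(dim = dim(p$value) %||% length(p$value), fp16 = cpp_fp16_pack(as.numeric(p$value))))
  saveRDS(list(config = unclass(model$cfg), tensors = payload), path,
          compress = FALSE)  # flat container: 2 bytes/param + header
  invisible(file.size(path) / 1e6)
}

#' Load weights from an FP16 checkpoint into a model
#' @param model an `edgebcs_model` with matching architecture
#' @param path checkpoint file
#' @return the model, modified in place
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  ps <- model_params(model)
  for (nm in names(ps)) {
    t <- ck$tensors[[nm]]
    if (is.null(t)) stop("checkpoint missing tensor: ", nm)
    v <- cpp_fp16_unpack(t$fp16)
    ps[[nm]]$value <- if (length(t$dim) > 1L) array(v, dim = t$dim) else v
  }
  invisible(model)
}

#' Serialized FP16 model size in megabytes
#'
#' Writes the checkpoint to a temporary file and measures it (parameter count
#' x 2 bytes plus container overhead).
#'
#' @param model an `edgebcs_model`
#' @return size in MB
#' @export
checkpoint_size <- function(model) {
  f <- tempfile(fileext = ".ckpt")
  on.exit(unlink(f))
  as.numeric(save_checkpoint(model, f))
}

#' @export
print.edgebcs_model <- function(x, ...) {
  p <- complexity_report(x)
  cat(sprintf("edgebcs detector [%s]  nc=%d  params=%s  GFLOPs(640)=%.2f  fp16=%.1f MB\n",
              x$cfg$variant, x$cfg$nc, format(p$params, big.mark = ","),
              p$gflops, p$fp16_size_mb))
  invisible(x)
}
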