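#!/usr/bin/env Rscript
# Calibration of the architecture's free widths (star expansion ratios, neck
# width, neck stage repeats) against the published complexity budget of the
# full model: 4.7 GFLOPs at 640 and 3.3 MB at FP16. Run once; the chosen
# configuration is frozen into model_config()'s defaults.
#
# Usage: Rscript scripts/calibrate.R

suppressPackageStartupMessages(library(edgebcs))

target_gf <- 4.7
target_mb <- 3.3

res <- list()
for (ex in seq(1.25, 3.5, by = 0.25)) for (exd in c(1, 1.5, 2))
  for (n3 in 1:3) for (n4 in 1:2) for (n5 in 1:2) {
    cfg <- model_config("full", expansion = ex, expansion_deep = exd,
                        neck_repeats = c(n3, n4, n4, n5))
    r <- complexity_report(build_model(cfg))
    mb <- r$params * 2 / 1e6
    sc <- abs(r$gflops - target_gf) / target_gf + abs(mb - target_mb) / target_mb
    res[[length(res) + 1]] <- data.frame(expansion = ex, expansion_deep = exd,
      n3 = n3, n4 = n4, n5 = n5, params = r$params, gflops = r$gflops,
      fp16_mb = mb, score = sc)
  }
d <- do.call(rbind, res)
d <- d[order(d$score), ]
cat("best configurations (relative deviation from the published budget):\n")
print(head(d, 10), row.names = FALSE)
best <- d[1, ]
cat(sprintf("\nfrozen: expansion %.2f / deep %.2f, neck repeats (%d,%d,%d,%d) -> %.3f GFLOPs, %.2f MB\n",
            best$expansion, best$expansion_deep, best$n3, best$n4, best$n4,
            best$n5, best$gflops, best$fp16_mb))
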