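#!/usr/bin/env Rscript
# Stage 5: baseline-calibrated bias correction.
#
# Learns a mapping from high-proximity (lavalier, headset) amplitude/f0 to
# the studio baseline, evaluated only on held-out participants, and
# compares the tree-ensemble correction with a linear per-feature
# calibration.

library(voicebias)

features <- read.csv("results/features.csv")
paired <- pair_devices(features, high = c("lavalier", "headset"),
                       reference = "baseline")
cat(sprintf("paired %d high-proximity recordings with their baseline twins\n",
            nrow(paired)))

reports <- lapply(c("tree", "linear"), function(kind) {
  fit <- fit_correction(paired, kind, n_folds = 5, seed = 99L)
  print(fit)
  r <- fit$report
  data.frame(model = kind, r2_amp = r$r_squared[["amp"]],
             r2_f0 = r$r_squared[["f0"]],
             bias_before = r$mean_bias_before, bias_after = r$mean_bias_after,
             ks_before = r$ks_before, ks_after = r$ks_after)
})
out <- do.call(rbind, reports)
write.csv(out, "results/correction_report.csv", row.names = FALSE)

fit <- fit_correction(paired, "tree", n_folds = 5, seed = 99L)
write.csv(cbind(paired, corrected_amp = fit$corrected$amp,
                corrected_f0 = fit$corrected$f0),
          "results/corrected_pairs.csv", row.names = FALSE)
cat("wrote results/correction_report.csv and results/corrected_pairs.csv\n")
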