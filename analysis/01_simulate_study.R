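#!/usr/bin/env Rscript
# Stage 1: generate the synthetic device study.
#
# Recreates the lab design (30 participants x 5 devices x 3 emotions x
# 2 phrases x 2 headset conditions = 1,800 recordings) and samples a
# feature table from the calibrated generative model. Everything downstream
# (02-05) reads results/features.csv.

library(voicebias)

seed <- 20260924L
dir.create("results", showWarnings = FALSE)

design <- generate_design(n_participants = 30, seed = seed)
cat(sprintf("design: %d recordings, %d per participant, %d per sex\n",
            nrow(design), nrow(design) / 30L,
            sum(design$sex == "female")))

model <- default_effect_model()
features <- sample_features(design, model, seed = seed + 1L)
write.csv(features, "results/features.csv", row.names = FALSE)

dev_means <- sort(tapply(features$mean_amp_db, features$device, mean),
                  decreasing = TRUE)
cat("device mean amplitude (dB), high-proximity inflation on top:\n")
print(round(dev_means, 2))
cat("wrote results/features.csv\n")
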