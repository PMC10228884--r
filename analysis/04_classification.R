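#!/usr/bin/env Rscript
# Stage 4: device-wise prediction tasks.
#
# How much does the recording device change what a model can read off the
# voice? Emotion (random forest) and biological sex (logit) classification
# per device, under five-fold subject-wise cross-validation.

library(voicebias)

features <- read.csv("results/features.csv")
seed <- 2024L

rows <- lapply(sort(unique(features$device)), function(dv) {
  em <- classify_emotion(features, dv, n_folds = 5, seed = seed)
  sx <- classify_sex(features, dv, n_folds = 5, seed = seed)
  data.frame(device = dv,
             emotion_accuracy = em$accuracy_mean,
             emotion_accuracy_sd = em$accuracy_sd,
             sex_accuracy = sx$accuracy_mean,
             sex_accuracy_sd = sx$accuracy_sd)
})
cv <- do.call(rbind, rows)
cv <- cv[order(-cv$emotion_accuracy), ]
print(cv, digits = 3, row.names = FALSE)
cat(sprintf("\nchance level for emotion: %.3f; for sex: 0.5\n", 1 / 3))
write.csv(cv, "results/classification.csv", row.names = FALSE)
cat("wrote results/classification.csv\n")
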