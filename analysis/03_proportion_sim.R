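#!/usr/bin/env Rscript
# Stage 3: the device-mixture oversampling experiment.
#
# Varies the share of lavalier (high-proximity) recordings across synthetic
# samples of 480 participants and shows how the detectable emotion effect
# on amplitude shrinks as the share grows, even though the emotion
# manipulation never changes.

library(voicebias)

sim <- run_proportion_sim(default_effect_model(), n_participants = 480,
                          proportions = c(0, 0.5, 1), n_seeds = 20,
                          base_seed = 42)
print(sim)
cat("\naverage |Cohen's d| over the three emotion contrasts:\n")
with(sim$summary, cat(sprintf("  %3.0f%% lavalier: d = %.2f\n",
                              100 * proportion, avg_d)))
cat("=> oversampling the amplitude-inflating device attenuates the",
    "detectable emotion effect\n")

write.csv(sim$per_seed, "results/proportion_sim_per_seed.csv",
          row.names = FALSE)
write.csv(sim$summary, "results/proportion_sim_summary.csv",
          row.names = FALSE)
cat("wrote results/proportion_sim_{per_seed,summary}.csv\n")
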