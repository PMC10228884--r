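#' Device-mixture oversampling simulation
#'
#' Quantifies how oversampling high-proximity (lavalier) recordings
#' attenuates detectable emotion effects on amplitude. For each mixture
#' proportion `pi`, each synthetic participant is assigned a single device
#' (lavalier with weight `pi`, the remaining weight split equally among the
#' other four devices) and contributes one amplitude draw per emotion from
#' `Normal(mu(device, emotion) + sex_offset(device, sex), sigma(device))`,
#' with sexes balanced. The three emotion groups (3n observations) are then
#' compared with a one-way independent-groups ANOVA - observations are
#' deliberately treated as independent, which is what yields
#' `df2 = 3n - 3` (1,437 at n = 480) - followed by Tukey HSD contrasts and
#' the average absolute Cohen's d over the three pairwise emotion
#' contrasts. Results are averaged over seeds.
#'
#' @param model An [default_effect_model()] calibration (its amplitude cell
#'   means, sex offsets and per-device within-SDs drive the draws).
#' @param n_participants Participants per synthetic dataset (default 480).
#' @param proportions Lavalier mixture proportions (default 0, 0.5, 1).
#' @param n_seeds Number of independent replicate datasets per proportion.
#' @param base_seed Integer seed from which replicate seeds are derived.
#' @return An object of class `prop_sim`: `per_seed` (one row per
#'   proportion x seed with emotion means, F, df, p, Tukey-adjusted pairwise
#'   p-values and `avg_d`) and `summary` (seed-averaged means and `avg_d`
#'   per proportion).
#' @export
run_proportion_sim <- function(model = default_effect_model(),
                               n_participants = 480L,
                               proportions = c(0, 0.5, 1),
                               n_seeds = 20L, base_seed = 1L) {
  stopifnot(inherits(model, "effect_model"))
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (n_participants < 2L) stop("n_participants must be at least 2")
  others <- setdiff(model$devices, "lavalier")
  seeds <- derive_seeds(base_seed, n_seeds)
  emo <- model$emotions
  pairs <- utils::combn(emo, 2L)

  rows <- list()
  for (p in proportions) {
    w <- c(stats::setNames(p, "lavalier"),
           stats::setNames(rep((1 - p) / length(others), length(others)),
                           others))
    if (abs(sum(w) - 1) > 1e-12) stop("device weights must sum to 1")
    for (si in seq_len(n_seeds)) {
      res <- with_seed(seeds[si], {
        dev <- sample(names(w), n_participants, replace = TRUE, prob = w)
        sex <- rep(model$sexes, length.out = n_participants)
        mu <- model$amp_mean[dev, , drop = FALSE] +
          model$amp_sex_offset[cbind(dev, sex)]
        amp <- mu + matrix(stats::rnorm(n_participants * length(emo), 0,
                                        model$sigma_amp_within[dev]),
                           n_participants, length(emo))
        values <- as.numeric(amp)
        groups <- factor(rep(emo, each = n_participants), levels = emo)
        an <- oneway_anova(values, groups)
        tk <- tukey_contrasts(an)
        ds <- apply(pairs, 2L, function(pr) {
          va <- values[groups == pr[1L]]; vb <- values[groups == pr[2L]]
          # degenerate zero-dispersion draws with equal means carry no effect
          if (stats::var(va) + stats::var(vb) == 0 && mean(va) == mean(vb))
            return(0)
          abs(cohens_d(va, vb))
        })
        row <- data.frame(proportion = p, seed = seeds[si],
                          F = an$F, df1 = an$df1, df2 = an$df2, p_value = an$p,
                          partial_eta_sq = an$partial_eta_sq,
                          avg_d = mean(ds))
        for (e in emo) row[[paste0("mean_", e)]] <- an$means[[e]]
        for (j in seq_len(ncol(pairs)))
          row[[paste0("p_adj_", pairs[1L, j], "_", pairs[2L, j])]] <-
            tk$p_adj[tk$level_a == pairs[1L, j] & tk$level_b == pairs[2L, j]]
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_seed <- do.call(rbind, rows)
  num <- setdiff(names(per_seed), c("proportion", "seed"))
  summary <- stats::aggregate(per_seed[num], per_seed["proportion"], mean)
  structure(list(per_seed = per_seed, summary = summary,
                 n_participants = n_participants, n_seeds = n_seeds),
            class = "prop_sim")
}

#' @export
print.prop_sim <- function(x, ...) {
  cat(sprintf("Device-mixture simulation: %d participants, %d seeds\n",
              x$n_participants, x$n_seeds))
  cols <- c("proportion", grep("^mean_", names(x$summary), value = TRUE),
            "F", "avg_d")
  print(round(x$summary[cols], 3))
  invisible(x)
}
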