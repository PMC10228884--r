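#' Run the full study pipeline
#'
#' End-to-end orchestration of the synthetic study: design generation and
#' feature sampling, the device-bias analyses for amplitude and f0, the
#' device-mixture simulation, device-wise emotion/sex classification, and
#' the bias correction. Each stage writes CSV/JSON outputs under `out_dir`
#' and a `manifest.json` records the configuration, seeds and produced
#' files, so a rerun with the same configuration is byte-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param n_participants Participants in the simulated study (default 30).
#' @param seed Master seed; stage seeds are derived from it.
#' @param model Generative calibration, see [default_effect_model()].
#' @param stages Stages to run, in order.
#' @param sim_seeds Seeds for the device-mixture simulation stage.
#' @param quiet Suppress per-stage messages.
#' @return The manifest (named list), invisibly.
#' @export
run_study <- function(out_dir, n_participants = 30L, seed = 1L,
                      model = default_effect_model(),
                      stages = c("simulate", "analyze", "prop_sim",
                                 "classify", "correct"),
                      sim_seeds = 10L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- derive_seeds(seed, 5L)
  files <- character(0)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  t0 <- proc.time()[["elapsed"]]
  features <- NULL
  get_features <- function() {
    if (is.null(features)) {
      design <- generate_design(n_participants, stage_seeds[1L])
      features <<- sample_features(design, model, stage_seeds[2L])
    }
    features
  }

  for (stage in stages) {
    ts <- proc.time()[["elapsed"]]
    switch(stage,
      simulate = {
        emit(get_features(), "features.csv")
      },
      analyze = {
        tabs <- lapply(c("mean_amp_db", "mean_f0_hz"), function(ft) {
          rep <- analyze_devices(get_features(), ft)
          effects <- c(list(device = rep$device_anova), rep$sex_model,
                       rep$emotion_model, rep$threeway)
          data.frame(feature = ft, effect = names(effects),
                     F = vapply(effects, `[[`, 0, "F"),
                     df1 = vapply(effects, `[[`, 0L, "df1"),
                     df2 = vapply(effects, `[[`, 0L, "df2"),
                     p = vapply(effects, `[[`, 0, "p"),
                     partial_eta_sq = vapply(effects, `[[`, 0,
                                             "partial_eta_sq"),
                     row.names = NULL)
        })
        emit(do.call(rbind, tabs), "anova_effects.csv")
        rep_amp <- analyze_devices(get_features(), "mean_amp_db")
        emit(rep_amp$device_contrasts, "amplitude_device_contrasts.csv")
        emit(rep_amp$cell_means_emotion, "amplitude_cell_means.csv")
      },
      prop_sim = {
        sim <- run_proportion_sim(model, n_seeds = sim_seeds,
                                  base_seed = stage_seeds[3L])
        emit(sim$per_seed, "proportion_sim_per_seed.csv")
        emit(sim$summary, "proportion_sim_summary.csv")
      },
      classify = {
        tab <- get_features()
        rows <- lapply(unique(tab$device), function(dv) {
          em <- classify_emotion(tab, dv, seed = stage_seeds[4L])
          sx <- classify_sex(tab, dv, seed = stage_seeds[4L])
          data.frame(device = dv,
                     emotion_accuracy = em$accuracy_mean,
                     emotion_accuracy_sd = em$accuracy_sd,
                     sex_accuracy = sx$accuracy_mean,
                     sex_accuracy_sd = sx$accuracy_sd)
        })
        emit(do.call(rbind, rows), "classification.csv")
      },
      correct = {
        paired <- pair_devices(get_features())
        fit <- fit_correction(paired, "tree", seed = stage_seeds[5L])
        rep <- fit$report
        emit(data.frame(model = rep$model_kind,
                        r2_amp = rep$r_squared[["amp"]],
                        r2_f0 = rep$r_squared[["f0"]],
                        bias_before = rep$mean_bias_before,
                        bias_after = rep$mean_bias_after,
                        ks_before = rep$ks_before, ks_after = rep$ks_after),
             "correction_report.csv")
        emit(cbind(paired, corrected_amp = fit$corrected$amp,
                   corrected_f0 = fit$corrected$f0), "corrected_pairs.csv")
      },
      stop("unknown stage: ", stage))
    say("stage %-9s done in %.1f s", stage, proc.time()[["elapsed"]] - ts)
  }

  manifest <- list(
    package = "voicebias",
    version = as.character(utils::packageVersion("voicebias")),
    seed = seed, stage_seeds = stage_seeds,
    n_participants = n_participants, stages = stages, files = files,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
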