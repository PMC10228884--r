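#' Pair high-proximity recordings with their reference-device counterparts
#'
#' Matches each lavalier/headset recording to the baseline (studio)
#' recording of the same (participant, emotion, phrase, headset condition)
#' cell, producing the paired table that [fit_correction()] learns from.
#'
#' @param table A feature table (see [sample_features()]).
#' @param high Devices to correct (default lavalier and headset).
#' @param reference Reference device (default `"baseline"`).
#' @return A data.frame with `participant_id`, `device`, predictors
#'   `amp_high`, `f0_high` and targets `amp_ref`, `f0_ref`.
#' @export
pair_devices <- function(table, high = c("lavalier", "headset"),
                         reference = "baseline") {
  key <- function(d) paste(d$participant_id, d$emotion, d$phrase,
                           d$headset_worn, sep = "|")
  ref <- table[table$device == reference, , drop = FALSE]
  hi <- table[table$device %in% high, , drop = FALSE]
  if (nrow(ref) == 0L || nrow(hi) == 0L)
    stop("pairing error: reference or high-proximity rows are absent")
  idx <- match(key(hi), key(ref))
  if (anyNA(idx))
    stop("pairing error: some high-proximity recordings have no reference counterpart")
  data.frame(participant_id = hi$participant_id, device = hi$device,
             amp_high = hi$mean_amp_db, f0_high = hi$mean_f0_hz,
             amp_ref = ref$mean_amp_db[idx], f0_ref = ref$mean_f0_hz[idx])
}

#' Baseline-calibrated device bias correction
#'
#' Learns a mapping from high-proximity device features (mean amplitude and
#' mean f0) to the values the reference device would have captured, either
#' with a random-forest regression or a per-feature linear calibration, and
#' evaluates it with subject-wise cross-validation so correction quality is
#' always measured on held-out participants. The report contains held-out
#' R-squared per feature, the mean amplitude bias before and after
#' correction, and the two-sample Kolmogorov-Smirnov distance between the
#' (corrected) high-proximity and reference amplitude distributions.
#'
#' @param paired A paired table from [pair_devices()].
#' @param model_kind `"tree"` (random forest) or `"linear"`.
#' @param n_folds Subject-wise folds (default 5).
#' @param seed Integer seed.
#' @param num_trees Trees for the forest.
#' @return An object of class `correction_fit`: final `models` (fit on all
#'   pairs), a `report` list, and the held-out predictions.
#' @export
fit_correction <- function(paired, model_kind = c("tree", "linear"),
                           n_folds = 5L, seed = 1L, num_trees = 500L) {
  model_kind <- match.arg(model_kind)
  if (length(unique(paired$participant_id)) < 2L)
    stop("need at least 2 participants for subject-wise validation")
  preds <- c("amp_high", "f0_high")
  if (length(unique(paired$device)) > 1L) {
    paired$device <- factor(paired$device)
    preds <- c(preds, "device")
  }
  targets <- c(amp = "amp_ref", f0 = "f0_ref")

  fit_one <- function(target, data) {
    fml <- stats::reformulate(preds, target)
    if (model_kind == "tree")
      ranger::ranger(fml, data = data, num.trees = num_trees, seed = seed,
                     num.threads = 1L)
    else stats::lm(fml, data = data)
  }
  predict_one <- function(fit, data) {
    if (model_kind == "tree")
      stats::predict(fit, data, num.threads = 1L)$predictions
    else as.numeric(stats::predict(fit, data))
  }

  ids <- unique(paired$participant_id)
  folds <- subjectwise_folds(ids, n_folds, seed)
  oof <- matrix(NA_real_, nrow(paired), length(targets),
                dimnames = list(NULL, names(targets)))
  for (f in seq_len(n_folds)) {
    test <- folds[paired$participant_id] == f
    for (tg in names(targets))
      oof[test, tg] <- predict_one(
        fit_one(targets[[tg]], paired[!test, , drop = FALSE]),
        paired[test, , drop = FALSE])
  }
  r2 <- vapply(names(targets), function(tg) {
    obs <- paired[[targets[[tg]]]]
    1 - sum((obs - oof[, tg])^2) / sum((obs - mean(obs))^2)
  }, 0)
  ks_stat <- function(a, b)
    as.numeric(suppressWarnings(stats::ks.test(a, b))$statistic)
  report <- list(
    model_kind = model_kind,
    r_squared = r2,
    mean_bias_before = mean(paired$amp_high - paired$amp_ref),
    mean_bias_after = mean(oof[, "amp"] - paired$amp_ref),
    ks_before = ks_stat(paired$amp_high, paired$amp_ref),
    ks_after = ks_stat(oof[, "amp"], paired$amp_ref))
  models <- lapply(targets, fit_one, data = paired)
  structure(list(models = models, model_kind = model_kind,
                 predictors = preds, report = report,
                 corrected = as.data.frame(oof)),
            class = "correction_fit")
}

#' Apply a fitted bias correction to new high-proximity features
#'
#' @param fit A `correction_fit` from [fit_correction()].
#' @param newdata Data with the predictor columns (`amp_high`, `f0_high`,
#'   and `device` when the fit used it).
#' @return A data.frame with corrected `amp` and `f0` columns.
#' @export
apply_correction <- function(fit, newdata) {
  stopifnot(inherits(fit, "correction_fit"))
  out <- lapply(fit$models, function(mod) {
    if (fit$model_kind == "tree")
      stats::predict(mod, newdata, num.threads = 1L)$predictions
    else as.numeric(stats::predict(mod, newdata))
  })
  data.frame(amp = out$amp, f0 = out$f0)
}

#' @export
print.correction_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("Bias correction (%s): held-out R^2 amp = %.3f, f0 = %.3f\n",
              r$model_kind, r$r_squared[["amp"]], r$r_squared[["f0"]]))
  cat(sprintf("  mean amplitude bias %.2f -> %.2f dB; KS D %.3f -> %.3f\n",
              r$mean_bias_before, r$mean_bias_after, r$ks_before, r$ks_after))
  invisible(x)
}
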