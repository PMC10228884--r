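#' Device-bias analysis of a feature table
#'
#' Runs the lab-study analysis battery for one feature: recordings are
#' first aggregated to participant x condition means (the raw design has
#' 12 recordings per participant x device cell; the repeated-measures
#' error term is defined across participants), then
#'
#' * a one-way repeated-measures ANOVA over devices with Tukey HSD
#'   contrasts,
#' * a mixed ANOVA with biological sex as the between-subjects factor,
#' * a two-within ANOVA over device x emotion,
#' * the three-way device x emotion x sex model,
#' * cross-device correlations with the Farrar-Glauber chi-square, and
#' * cell-mean tables with 95% confidence intervals across participants.
#'
#' @param table A feature table from [sample_features()] (or read from CSV
#'   with the same columns).
#' @param feature `"mean_amp_db"` or `"mean_f0_hz"`.
#' @return An object of class `analysis_report`.
#' @export
analyze_devices <- function(table, feature = c("mean_amp_db", "mean_f0_hz")) {
  feature <- match.arg(feature)
  if (length(unique(table$device)) < 2L)
    stop("degenerate design: need at least 2 device levels")

  agg <- function(cols) {
    out <- stats::aggregate(table[[feature]], table[cols], mean)
    names(out)[ncol(out)] <- feature
    out
  }

  pd <- agg(c("participant_id", "device"))
  wide <- tapply(pd[[feature]], list(pd$participant_id, pd$device), mean)
  if (anyNA(wide)) stop("incomplete design: every participant needs every device")
  device_anova <- rm_anova_oneway(wide)
  device_contrasts <- tukey_contrasts(device_anova)

  pds <- agg(c("participant_id", "sex", "device"))
  sex_model <- mixed_anova(pds, feature, "participant_id", "device", "sex")
  pde <- agg(c("participant_id", "device", "emotion"))
  emotion_model <- mixed_anova(pde, feature, "participant_id",
                               c("device", "emotion"))
  pdes <- agg(c("participant_id", "sex", "device", "emotion"))
  threeway <- mixed_anova(pdes, feature, "participant_id",
                          c("device", "emotion"), "sex")

  # device contrasts conditional on sex, against the device x subject
  # within-sex error stratum
  ms_dev <- sex_model$device$ms_err
  df_dev <- sex_model$device$df2
  contrasts_by_sex <- lapply(split(pds, pds$sex), function(d) {
    mns <- tapply(d[[feature]], d$device, mean)
    cell_contrasts(mns, length(unique(d$participant_id)), ms_dev, df_dev)
  })

  ci_table <- function(d, cols) {
    sp <- split(d[[feature]], d[cols])
    keys <- do.call(rbind, strsplit(names(sp), "\\."))
    mns <- vapply(sp, mean, 0)
    ses <- vapply(sp, function(v) stats::sd(v) / sqrt(length(v)), 0)
    tq <- stats::qt(0.975, vapply(sp, length, 0L) - 1L)
    out <- data.frame(keys, mean = mns, ci_lo = mns - tq * ses,
                      ci_hi = mns + tq * ses, row.names = NULL)
    names(out)[seq_along(cols)] <- cols
    out
  }

  structure(list(
    feature = feature,
    device_anova = device_anova,
    device_contrasts = device_contrasts,
    sex_model = sex_model,
    emotion_model = emotion_model,
    threeway = threeway,
    contrasts_by_sex = contrasts_by_sex,
    cell_means = ci_table(pd, "device"),
    cell_means_sex = ci_table(pds, c("device", "sex")),
    cell_means_emotion = ci_table(pde, c("device", "emotion")),
    correlations = device_correlations(table, feature)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Device-bias analysis of %s\n", x$feature))
  print(x$device_anova)
  cat(sprintf("  device x sex: F(%d, %d) = %.2f, p = %.3g\n",
              x$sex_model[[2L]]$df1, x$sex_model[[2L]]$df2,
              x$sex_model[["device:sex"]]$F, x$sex_model[["device:sex"]]$p))
  cat(sprintf("  device x emotion: F(%d, %d) = %.2f, p = %.3g\n",
              x$emotion_model[["device:emotion"]]$df1,
              x$emotion_model[["device:emotion"]]$df2,
              x$emotion_model[["device:emotion"]]$F,
              x$emotion_model[["device:emotion"]]$p))
  cat(sprintf("  mean cross-device r = %.2f, Farrar chi-square = %.1f\n",
              mean(x$correlations$r[lower.tri(x$correlations$r)]),
              x$correlations$farrar$chisq))
  invisible(x)
}
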