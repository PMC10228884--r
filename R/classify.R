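#' Subject-wise cross-validation folds
#'
#' Partitions participants (not recordings) into folds so that no
#' individual contributes to both training and test data. Optionally
#' stratifies by a participant-level label (sex by default in the
#' classifiers) to avoid degenerate folds.
#'
#' @param participants Vector of unique participant identifiers.
#' @param n_folds Number of folds (>= 2; default 5).
#' @param seed Integer seed.
#' @param strata Optional vector of participant-level labels, parallel to
#'   `participants`.
#' @return Named integer vector: fold index per participant; fold sizes
#'   differ by at most one participant.
#' @export
subjectwise_folds <- function(participants, n_folds = 5L, seed = 1L,
                              strata = NULL) {
  participants <- as.character(participants)
  if (anyDuplicated(participants)) stop("participant ids must be unique")
  if (n_folds < 2L) stop("need at least 2 folds")
  if (length(participants) < n_folds)
    stop("need at least as many participants as folds")
  if (is.null(strata)) strata <- rep("all", length(participants))
  # canonical order first, so the assignment depends only on the set of
  # participants and the seed, never on input row order
  canon <- order(participants)
  participants <- participants[canon]
  strata <- strata[canon]
  with_seed(seed, {
    # shuffle within stratum, concatenate, deal cyclically: global fold
    # sizes differ by <= 1 and strata spread as evenly as possible
    ord <- unlist(lapply(split(seq_along(participants), strata), sample),
                  use.names = FALSE)
    folds <- integer(length(participants))
    folds[ord] <- rep_len(seq_len(n_folds), length(participants))
    stats::setNames(folds, participants)
  })
}

cv_result <- function(device, task, per_fold) {
  structure(list(device = device, task = task,
                 accuracy_mean = mean(per_fold),
                 accuracy_sd = stats::sd(per_fold),
                 per_fold = per_fold), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s classification [%s]: accuracy %.1f%% (SD %.1f%%, %d folds)\n",
              x$task, x$device, 100 * x$accuracy_mean, 100 * x$accuracy_sd,
              length(x$per_fold)))
  invisible(x)
}

participant_strata <- function(d) {
  tapply(d$sex, d$participant_id, function(v) v[1L])
}

#' Device-wise emotion classification
#'
#' Trains a random forest (500 trees, majority vote) to predict the
#' expressed emotion from a device's recordings, using mean amplitude,
#' mean f0, the amplitude and f0 perturbation covariates and biological
#' sex, under subject-wise cross-validation.
#'
#' @param table A feature table (see [sample_features()]).
#' @param device Device level to classify within.
#' @param n_folds Number of subject-wise folds (default 5).
#' @param seed Integer seed (folds and forest).
#' @param features Predictor columns.
#' @param num_trees Trees in the ensemble.
#' @return A `cv_result` with mean, SD and per-fold held-out accuracy.
#' @export
classify_emotion <- function(table, device, n_folds = 5L, seed = 1L,
                             features = c("mean_amp_db", "mean_f0_hz",
                                          "sd_amp_db", "sd_f0_hz", "sex"),
                             num_trees = 500L) {
  d <- table[table$device == device, , drop = FALSE]
  if (nrow(d) == 0L) stop("no recordings for device: ", device)
  d$emotion <- factor(d$emotion)
  d$sex <- factor(d$sex)
  strat <- participant_strata(d)
  folds <- subjectwise_folds(names(strat), n_folds, seed, strat)
  per_fold <- vapply(seq_len(n_folds), function(f) {
    test <- folds[d$participant_id] == f
    train <- d[!test, c(features, "emotion")]
    if (nlevels(droplevels(train$emotion)) < nlevels(d$emotion))
      warning("fold ", f, " training data is missing an emotion class; fold retained")
    fit <- ranger::ranger(emotion ~ ., data = train, num.trees = num_trees,
                          seed = seed + f, num.threads = 1L)
    pred <- stats::predict(fit, d[test, features, drop = FALSE],
                           num.threads = 1L)$predictions
    mean(pred == d$emotion[test])
  }, 0)
  cv_result(device, "emotion", per_fold)
}

#' Device-wise biological-sex classification
#'
#' Logistic regression predicting biological sex from a device's vocal
#' features (the emotion-classification feature set minus sex), under
#' subject-wise cross-validation. Convergence warnings from quasi-separated
#' fits (expected when f0 separates the sexes almost perfectly) are
#' suppressed.
#'
#' @inheritParams classify_emotion
#' @return A `cv_result`.
#' @export
classify_sex <- function(table, device, n_folds = 5L, seed = 1L,
                         features = c("mean_amp_db", "mean_f0_hz",
                                      "sd_amp_db", "sd_f0_hz")) {
  d <- table[table$device == device, , drop = FALSE]
  if (nrow(d) == 0L) stop("no recordings for device: ", device)
  if (length(unique(d$sex)) < 2L) stop("both sexes must be present")
  d$sex <- factor(d$sex)
  strat <- participant_strata(d)
  folds <- subjectwise_folds(names(strat), n_folds, seed, strat)
  per_fold <- vapply(seq_len(n_folds), function(f) {
    test <- folds[d$participant_id] == f
    fit <- suppressWarnings(
      stats::glm(sex ~ ., data = d[!test, c(features, "sex")],
                 family = stats::binomial()))
    prob <- suppressWarnings(
      stats::predict(fit, d[test, features, drop = FALSE], type = "response"))
    pred <- levels(d$sex)[1L + (prob > 0.5)]
    mean(pred == as.character(d$sex[test]))
  }, 0)
  cv_result(device, "sex", per_fold)
}
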