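anova_result <- function(effect, ss_effect, df1, ss_error, df2, means = NULL,
                         n_per_mean = NULL) {
  ms_eff <- ss_effect / df1
  ms_err <- ss_error / df2
  f <- if (ms_err > 0) ms_eff / ms_err else if (ms_eff == 0) 0 else Inf
  structure(list(
    effect = effect, F = f, df1 = df1, df2 = df2,
    p = stats::pf(f, df1, df2, lower.tail = FALSE),
    partial_eta_sq = if (ss_effect + ss_error > 0)
      ss_effect / (ss_effect + ss_error) else 0,
    ss_effect = ss_effect, ss_error = ss_error, ms_err = ms_err,
    means = means, n_per_mean = n_per_mean), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.2f\n",
              x$effect, x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Sums-of-squares decomposition for a complete subject x condition matrix:
#' `SS_cond = n * sum_j (ybar_j - ybar)^2`, `SS_subj = k * sum_s (ybar_s -
#' ybar)^2`, `SS_err = SS_tot - SS_cond - SS_subj`, with
#' `F = MS_cond / MS_err` on `(k - 1, (n - 1)(k - 1))` degrees of freedom.
#' No sphericity correction is applied (uncorrected degrees of freedom are
#' reported throughout).
#'
#' @param y Numeric matrix, one row per subject, one column per condition;
#'   no missing cells.
#' @return An `anova_result` with `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`, plus the condition means and error mean square used
#'   by [tukey_contrasts()].
#' @export
rm_anova_oneway <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("unbalanced design: missing cells are not allowed")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  m <- mean(y)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  ss_tot <- sum((y - m)^2)
  ss_cond <- n * sum((cond_means - m)^2)
  ss_subj <- k * sum((subj_means - m)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  if (is.null(colnames(y))) colnames(y) <- paste0("c", seq_len(k))
  anova_result("condition", ss_cond, k - 1L, ss_err, (n - 1L) * (k - 1L),
               means = stats::setNames(cond_means, colnames(y)),
               n_per_mean = n)
}

#' One-way independent-groups ANOVA
#'
#' Between-subjects counterpart of [rm_anova_oneway()], used by the
#' device-mixture simulation where each observation is treated as
#' independent: `df = (k - 1, N - k)`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, one per value.
#' @return An `anova_result` (group means and error mean square attached).
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  m <- mean(values)
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  ss_b <- sum(ng * (gm - m)^2)
  ss_w <- sum((values - gm[as.integer(groups)])^2)
  k <- nlevels(groups)
  res <- anova_result("group", ss_b, k - 1L, ss_w, length(values) - k,
                      means = stats::setNames(as.numeric(gm), levels(groups)),
                      n_per_mean = if (length(unique(ng)) == 1L) ng[1L] else NA)
  res
}

# Balanced multistratum sums of squares for up to two within factors and an
# optional between factor; subjects are the blocking stratum.
#' Mixed-design (repeated-measures) ANOVA
#'
#' Balanced ANOVA with one or two within-subject factors and an optional
#' between-subjects factor, each effect tested against its own
#' subject-interaction error stratum: a between factor `B` against subjects
#' within groups (`df = n - g`), a within factor `A` and `A:B` against
#' `A x subjects` within groups (`df = (n - g)(a - 1)`), and `A:C` (+ `B`)
#' against `A x C x subjects` within groups. Exactly one observation per
#' subject x within-cell is required (aggregate replicates first).
#'
#' @param data A data.frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of one or two within-subject factor names.
#' @param between Optional name of a between-subjects factor.
#' @return A named list of `anova_result`, one per effect (e.g. `device`,
#'   `device:sex`, `device:emotion`).
#' @export
mixed_anova <- function(data, dv, subject, within, between = NULL) {
  stopifnot(length(within) %in% 1:2)
  y <- data[[dv]]
  S <- factor(data[[subject]])
  A <- factor(data[[within[1L]]])
  C <- if (length(within) == 2L) factor(data[[within[2L]]]) else
    factor(rep("all", nrow(data)))
  B <- if (!is.null(between)) factor(data[[between]]) else
    factor(rep("all", nrow(data)))
  n <- nlevels(S); a <- nlevels(A); cc <- nlevels(C); g <- nlevels(B)

  counts <- table(S, A, C)
  if (any(counts != 1L))
    stop("unbalanced design: need exactly one observation per subject x within-factor cell (aggregate replicates first)")
  grp_of <- tapply(as.integer(B), S, function(v) {
    u <- unique(v)
    if (length(u) != 1L) stop("between factor must be constant within subject")
    u
  })
  if (g > 1L && length(unique(tabulate(grp_of, g))) != 1L)
    stop("unbalanced design: between-subject groups must be equal-sized")

  m <- mean(y)
  M_s <- tapply(y, S, mean); M_a <- tapply(y, A, mean); M_c <- tapply(y, C, mean)
  M_g <- tapply(y, B, mean)
  M_sa <- tapply(y, list(S, A), mean); M_sc <- tapply(y, list(S, C), mean)
  M_ga <- tapply(y, list(B, A), mean); M_gc <- tapply(y, list(B, C), mean)
  M_ac <- tapply(y, list(A, C), mean)
  M_gac <- tapply(y, list(B, A, C), mean)
  gs <- grp_of[levels(S)] # group index per subject level

  out <- list()
  add <- function(name, ss, df1, ss_err, df2, means = NULL, nper = NULL) {
    out[[name]] <<- anova_result(name, ss, df1, ss_err, df2, means, nper)
  }

  if (g > 1L) {
    ss_b <- a * cc * (n / g) * sum((M_g - m)^2)
    ss_swb <- a * cc * sum((M_s - M_g[gs])^2)
    add(between, ss_b, g - 1L, ss_swb, n - g,
        means = stats::setNames(as.numeric(M_g), levels(B)),
        nper = (n / g) * a * cc)
  }

  # within factor A stratum
  resid_a <- M_sa - matrix(M_s, n, a) - M_ga[gs, , drop = FALSE] +
    matrix(M_g[gs], n, a)
  ss_aswb <- cc * sum(resid_a^2)
  df_aswb <- (n - g) * (a - 1L)
  ss_a <- n * cc * sum((M_a - m)^2)
  add(within[1L], ss_a, a - 1L, ss_aswb, df_aswb,
      means = stats::setNames(as.numeric(M_a), levels(A)), nper = n * cc)
  if (g > 1L) {
    dev_ga <- sweep(sweep(M_ga, 1L, M_g), 2L, M_a) + m
    ss_ab <- cc * (n / g) * sum(dev_ga^2)
    add(paste(within[1L], between, sep = ":"), ss_ab, (g - 1L) * (a - 1L),
        ss_aswb, df_aswb)
  }

  if (cc > 1L) {
    resid_c <- M_sc - matrix(M_s, n, cc) - M_gc[gs, , drop = FALSE] +
      matrix(M_g[gs], n, cc)
    ss_cswb <- a * sum(resid_c^2)
    df_cswb <- (n - g) * (cc - 1L)
    ss_c <- n * a * sum((M_c - m)^2)
    add(within[2L], ss_c, cc - 1L, ss_cswb, df_cswb,
        means = stats::setNames(as.numeric(M_c), levels(C)), nper = n * a)
    if (g > 1L) {
      dev_gc <- sweep(sweep(M_gc, 1L, M_g), 2L, M_c) + m
      add(paste(within[2L], between, sep = ":"),
          a * (n / g) * sum(dev_gc^2), (g - 1L) * (cc - 1L),
          ss_cswb, df_cswb)
    }

    dev_ac <- sweep(sweep(M_ac, 1L, M_a), 2L, M_c) + m
    ss_ac <- n * sum(dev_ac^2)
    # A x C x S within B residual stratum
    yarr <- tapply(y, list(S, A, C), mean)
    resid3 <- yarr
    for (si in seq_len(n)) for (ai in seq_len(a)) for (ci in seq_len(cc)) {
      gi <- gs[si]
      resid3[si, ai, ci] <- yarr[si, ai, ci] - M_sa[si, ai] - M_sc[si, ci] -
        M_gac[gi, ai, ci] + M_s[si] + M_ga[gi, ai] + M_gc[gi, ci] - M_g[gi]
    }
    ss_acswb <- sum(resid3^2)
    df_acswb <- (n - g) * (a - 1L) * (cc - 1L)
    add(paste(within, collapse = ":"), ss_ac, (a - 1L) * (cc - 1L),
        ss_acswb, df_acswb)
    if (g > 1L) {
      dev3 <- M_gac
      for (gi in seq_len(g)) for (ai in seq_len(a)) for (ci in seq_len(cc))
        dev3[gi, ai, ci] <- M_gac[gi, ai, ci] - M_ga[gi, ai] -
          M_gc[gi, ci] - M_ac[ai, ci] + M_g[gi] + M_a[ai] + M_c[ci] - m
      add(paste(c(within, between), collapse = ":"),
          (n / g) * sum(dev3^2), (g - 1L) * (a - 1L) * (cc - 1L),
          ss_acswb, df_acswb)
    }
  }
  out
}

#' Tukey HSD pairwise contrasts
#'
#' Pairwise contrasts between the condition means of an omnibus ANOVA,
#' using the omnibus error mean square:
#' `t = (m_a - m_b) / sqrt(2 * MS_err / n)` with the familywise-adjusted
#' p-value `P(Q_{k, df2} >= |t| * sqrt(2))` from the studentized range
#' distribution.
#'
#' @param anova An `anova_result` from [rm_anova_oneway()],
#'   [oneway_anova()] or a [mixed_anova()] effect that carries condition
#'   means.
#' @return A data.frame with columns `level_a`, `level_b`, `estimate`, `t`,
#'   `p_adj`.
#' @export
tukey_contrasts <- function(anova) {
  stopifnot(inherits(anova, "anova_result"))
  if (is.null(anova$means) || length(anova$means) < 2L)
    stop("ANOVA result carries fewer than 2 condition means")
  if (is.na(anova$n_per_mean))
    stop("Tukey contrasts require equal cell sizes")
  cell_contrasts(anova$means, anova$n_per_mean, anova$ms_err, anova$df2)
}

# Tukey-adjusted contrasts among a family of equally replicated means.
cell_contrasts <- function(means, n_per, ms_err, df_err) {
  k <- length(means)
  labs <- names(means)
  pairs <- utils::combn(k, 2L)
  est <- means[pairs[1L, ]] - means[pairs[2L, ]]
  se <- sqrt(2 * ms_err / n_per)
  t <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  p_adj <- stats::ptukey(abs(t) * sqrt(2), k, df_err, lower.tail = FALSE)
  data.frame(level_a = labs[pairs[1L, ]], level_b = labs[pairs[2L, ]],
             estimate = as.numeric(est), t = as.numeric(t),
             p_adj = as.numeric(p_adj), row.names = NULL)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled standard deviation.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return The standardized difference (numeric scalar); its sign matches
#'   the sign of the raw mean difference.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("undefined effect size: zero pooled standard deviation")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Farrar-Glauber collinearity chi-square
#'
#' `chisq = -(n - 1 - (2p + 5)/6) * ln(det(R))` for a `p x p` correlation
#' matrix estimated from `n` observations, on `p(p-1)/2` degrees of freedom.
#'
#' @param R Correlation matrix.
#' @param n Number of observations behind `R`.
#' @return A list with `chisq`, `df`, `p`.
#' @export
farrar_glauber <- function(R, n) {
  p <- ncol(R)
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(det(R))
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Cross-device feature correlations
#'
#' Pairs recordings across devices by (participant, emotion, phrase,
#' headset condition), computes the Pearson correlation matrix of the
#' chosen feature across devices, and the Farrar-Glauber collinearity
#' chi-square for the whole set.
#'
#' @param table A feature table (see [sample_features()]).
#' @param feature Feature column name, e.g. `"mean_f0_hz"`.
#' @return A list with the correlation matrix `r`, `n` paired observations,
#'   and `farrar` (see [farrar_glauber()]).
#' @export
device_correlations <- function(table, feature = "mean_f0_hz") {
  key <- interaction(table$participant_id, table$emotion, table$phrase,
                     table$headset_worn, drop = TRUE)
  wide <- tapply(table[[feature]], list(key, table$device), mean)
  if (anyNA(wide))
    stop("unpairable rows: each (participant, emotion, phrase, headset) cell must appear on every device")
  R <- stats::cor(wide)
  list(r = R, n = nrow(wide), farrar = farrar_glauber(R, nrow(wide)))
}
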