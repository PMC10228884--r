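test_that("repeated-measures F matches an independent linear-model decomposition", {
  for (dims in list(c(3L, 3L), c(30L, 5L), c(12L, 4L))) {
    y <- withr::with_seed(sum(dims), matrix(
      stats::rnorm(prod(dims), sd = 3) + rep(1:dims[2], each = dims[1]),
      dims[1], dims[2]))
    res <- rm_anova_oneway(y)
    long <- data.frame(val = as.numeric(y),
                       subj = factor(rep(seq_len(dims[1]), dims[2])),
                       cond = factor(rep(seq_len(dims[2]), each = dims[1])))
    tab <- stats::anova(stats::lm(val ~ subj + cond, long))
    f_oracle <- tab["cond", "Mean Sq"] / tab["Residuals", "Mean Sq"]
    expect_lt(abs(res$F - f_oracle) / f_oracle, 1e-10)
    expect_identical(c(res$df1, res$df2),
                     c(dims[2] - 1L, (dims[1] - 1L) * (dims[2] - 1L)))
    # partition identity
    total <- sum((y - mean(y))^2)
    parts <- res$ss_effect + res$ss_error +
      dims[2] * sum((rowMeans(y) - mean(y))^2)
    expect_lt(abs(total - parts) / total, 1e-9)
  }
})

test_that("degrees of freedom reproduce the study's design bookkeeping", {
  ft <- make_table(30, seed = 21)
  agg <- aggregate(mean_amp_db ~ participant_id + sex + device + emotion,
                   ft, mean)
  pd <- aggregate(mean_amp_db ~ participant_id + device, agg, mean)
  wide <- tapply(pd$mean_amp_db, list(pd$participant_id, pd$device), mean)
  one <- rm_anova_oneway(wide)
  expect_identical(c(one$df1, one$df2), c(4L, 116L))

  pds <- aggregate(mean_amp_db ~ participant_id + sex + device, agg, mean)
  ms <- mixed_anova(pds, "mean_amp_db", "participant_id", "device", "sex")
  expect_identical(c(ms[["device:sex"]]$df1, ms[["device:sex"]]$df2),
                   c(4L, 112L))

  me <- mixed_anova(agg, "mean_amp_db", "participant_id",
                    c("device", "emotion"))
  expect_identical(c(me[["device:emotion"]]$df1, me[["device:emotion"]]$df2),
                   c(8L, 232L))

  m3 <- mixed_anova(agg, "mean_amp_db", "participant_id",
                    c("device", "emotion"), "sex")
  expect_identical(
    c(m3[["device:emotion:sex"]]$df1, m3[["device:emotion:sex"]]$df2),
    c(8L, 224L))
})

test_that("mixed-design strata agree with aov on every effect", {
  ft <- make_table(10, seed = 22)
  agg <- aggregate(mean_f0_hz ~ participant_id + sex + device + emotion,
                   ft, mean)
  mine <- mixed_anova(agg, "mean_f0_hz", "participant_id",
                      c("device", "emotion"), "sex")
  oracle <- summary(stats::aov(
    mean_f0_hz ~ sex * device * emotion +
      Error(participant_id / (device * emotion)), agg))
  pick <- function(stratum, term) {
    tab <- oracle[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(mine$sex$F, pick("Error: participant_id", "sex"), tolerance = 1e-10)
  expect_equal(mine$device$F, pick("Error: participant_id:device", "device"),
               tolerance = 1e-10)
  expect_equal(mine[["device:sex"]]$F,
               pick("Error: participant_id:device", "sex:device"),
               tolerance = 1e-10)
  expect_equal(mine$emotion$F, pick("Error: participant_id:emotion", "emotion"),
               tolerance = 1e-10)
  expect_equal(mine[["device:emotion"]]$F,
               pick("Error: participant_id:device:emotion", "device:emotion"),
               tolerance = 1e-10)
  expect_equal(mine[["device:emotion:sex"]]$F,
               pick("Error: participant_id:device:emotion", "sex:device:emotion"),
               tolerance = 1e-10)
})

test_that("rm_anova_oneway equals mixed_anova without a between factor", {
  y <- withr::with_seed(9, matrix(stats::rnorm(60), 12, 5))
  long <- data.frame(val = as.numeric(y), s = rep(1:12, 5),
                     cond = rep(letters[1:5], each = 12))
  a <- rm_anova_oneway(y)
  b <- mixed_anova(long, "val", "s", "cond")$cond
  expect_equal(a$F, b$F, tolerance = 1e-12)
  expect_equal(a$partial_eta_sq, b$partial_eta_sq, tolerance = 1e-12)
})

test_that("no condition variance means F = 0; missing cells are an error", {
  y <- matrix(rep(stats::rnorm(8, sd = 2), 3), 8, 3)
  res <- rm_anova_oneway(y)
  expect_equal(res$F, 0)
  expect_equal(res$partial_eta_sq, 0)
  y[2, 3] <- NA
  expect_error(rm_anova_oneway(y), "unbalanced")
  long <- data.frame(val = stats::rnorm(9), s = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                     w = c(1, 2, 3, 1, 2, 3, 1, 2, 2))
  expect_error(mixed_anova(long, "val", "s", "w"), "unbalanced")
})

test_that("Tukey contrasts reduce to the paired t-test when k = 2", {
  y <- withr::with_seed(13, matrix(stats::rnorm(40, mean = rep(c(0, 0.6),
                                                               each = 20)),
                                   20, 2))
  an <- rm_anova_oneway(y)
  tk <- tukey_contrasts(an)
  t_stat <- tk$t[1]
  expect_equal(tk$p_adj[1],
               2 * stats::pt(abs(t_stat), an$df2, lower.tail = FALSE),
               tolerance = 1e-9)

  same <- cbind(a = y[, 1], b = y[, 1])
  tk0 <- tukey_contrasts(rm_anova_oneway(same))
  expect_equal(tk0$t, 0)
  expect_equal(tk0$p_adj, 1)
})

test_that("Tukey t-values and adjusted p-values match emmeans", {
  skip_if_not_installed("emmeans")
  y <- withr::with_seed(14, matrix(stats::rnorm(150) +
                                     rep(c(0, 0.3, 0.5, 0.5, 1), each = 30),
                                   30, 5, dimnames = list(NULL, letters[1:5])))
  an <- rm_anova_oneway(y)
  tk <- tukey_contrasts(an)
  long <- data.frame(val = as.numeric(y), subj = factor(rep(1:30, 5)),
                     cond = factor(rep(letters[1:5], each = 30)))
  em <- summary(emmeans::emmeans(stats::lm(val ~ subj + cond, long),
                                 pairwise ~ cond, adjust = "tukey")$contrasts)
  expect_equal(tk$estimate, em$estimate, tolerance = 1e-8)
  expect_equal(tk$t, em$t.ratio, tolerance = 1e-8)
  expect_equal(tk$p_adj, em$p.value, tolerance = 1e-6)
})

test_that("Tukey familywise error under the null is controlled at 5%", {
  n_rep <- 4000L
  hits <- withr::with_seed(99, vapply(seq_len(n_rep), function(i) {
    y <- matrix(stats::rnorm(150), 30, 5)
    any(tukey_contrasts(rm_anova_oneway(y))$p_adj < 0.05)
  }, NA))
  expect_lt(abs(mean(hits) - 0.05), 0.01)
})

test_that("Cohen's d behaves as a standardized difference", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(a, a), 0)
  expect_equal(cohens_d(a + stats::sd(a), a), 1)
  big <- withr::with_seed(5, list(stats::rnorm(1e5, 1), stats::rnorm(1e5, 0)))
  expect_equal(cohens_d(big[[1]], big[[2]]), 1, tolerance = 0.02)
  expect_error(cohens_d(c(1, 1, 1), c(1, 1)), "zero pooled")
  expect_error(cohens_d(1, 2), "at least 2")
})

test_that("Farrar-Glauber chi-square matches its closed form", {
  expect_equal(farrar_glauber(diag(4), 50)$chisq, 0)
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(farrar_glauber(R, 100)$chisq, -97.5 * log(0.19),
               tolerance = 1e-10)
  expect_equal(farrar_glauber(R, 100)$chisq, 161.9, tolerance = 0.1)
})

test_that("device pairing for correlations requires complete cells", {
  ft <- make_table(6, seed = 31)
  expect_silent(device_correlations(ft, "mean_amp_db"))
  expect_error(device_correlations(ft[-1, ], "mean_amp_db"), "unpairable")
})

test_that("independent-groups ANOVA matches aov and reports group means", {
  vals <- withr::with_seed(17, stats::rnorm(90, rep(c(0, 0.5, 1), each = 30)))
  grp <- rep(c("a", "b", "c"), each = 30)
  res <- oneway_anova(vals, grp)
  oracle <- summary(stats::aov(vals ~ grp))[[1]]
  expect_equal(res$F, oracle["grp", "F value"], tolerance = 1e-10)
  expect_identical(c(res$df1, res$df2), c(2L, 87L))
})
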