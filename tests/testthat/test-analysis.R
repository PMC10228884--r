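test_that("Tukey contrasts recover the configured device amplitude ordering", {
  m <- default_effect_model(sigma_amp_within = 1, sigma_f0_within = 2,
                            sigma_amp_participant = 0.5,
                            sigma_f0_participant = 1)
  ft <- make_table(30, seed = 41, model = m)
  rep <- analyze_devices(ft, "mean_amp_db")
  ord <- rep$cell_means$device[order(-rep$cell_means$mean)]
  expect_identical(ord, c("lavalier", "headset", "baseline", "smartphone",
                          "laptop"))
  expect_true(all(rep$device_contrasts$p_adj < 0.001))
  expect_identical(c(rep$device_anova$df1, rep$device_anova$df2), c(4L, 116L))
})

test_that("report tables have the design's dimensions", {
  ft <- make_table(8, seed = 42)
  rep <- analyze_devices(ft, "mean_amp_db")
  expect_identical(nrow(rep$cell_means), 5L)
  expect_identical(nrow(rep$cell_means_emotion), 15L)
  expect_identical(nrow(rep$cell_means_sex), 10L)
  expect_true(all(rep$cell_means$ci_lo < rep$cell_means$mean &
                    rep$cell_means$mean < rep$cell_means$ci_hi))
  expect_error(analyze_devices(ft[ft$device == "laptop", ], "mean_amp_db"),
               "degenerate")
})

test_that("estimated device means cover the calibration at the nominal CI rate", {
  m <- default_effect_model()
  target <- rowMeans(m$amp_mean) + rowMeans(m$amp_sex_offset)
  n_seeds <- 200L
  covered <- 0L
  checks <- 0L
  detected <- 0L
  for (s in seq_len(n_seeds)) {
    ft <- make_table(30, seed = 1000L + s)
    pd <- aggregate(mean_amp_db ~ participant_id + device, ft, mean)
    wide <- tapply(pd$mean_amp_db, list(pd$participant_id, pd$device), mean)
    mns <- colMeans(wide)
    hw <- stats::qt(0.975, nrow(wide) - 1L) *
      apply(wide, 2, stats::sd) / sqrt(nrow(wide))
    ok <- abs(mns - target[colnames(wide)]) <= hw
    covered <- covered + sum(ok)
    checks <- checks + length(ok)
    detected <- detected + (rm_anova_oneway(wide)$p < 0.001)
  }
  expect_gte(covered / checks, 0.93)
  # the device effect on amplitude is essentially always detected
  expect_gte(detected / n_seeds, 0.99)
})

test_that("device p-values are null-calibrated when device means are equal", {
  m <- default_effect_model()
  amp <- m$amp_mean
  amp[] <- mean(amp)
  flat <- default_effect_model(amp_mean = amp)
  pvals <- vapply(1:80, function(s) {
    ft <- make_table(10, seed = 3000L + s, model = flat)
    pd <- aggregate(mean_amp_db ~ participant_id + device, ft, mean)
    wide <- tapply(pd$mean_amp_db, list(pd$participant_id, pd$device), mean)
    rm_anova_oneway(wide)$p
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("the smartphone f0 elevation for males is detected", {
  ft <- make_table(30, seed = 44)
  rep <- analyze_devices(ft, "mean_f0_hz")
  male <- rep$contrasts_by_sex$male
  sm <- male[male$level_a == "smartphone" | male$level_b == "smartphone", ]
  est <- ifelse(sm$level_a == "smartphone", sm$estimate, -sm$estimate)
  expect_true(all(est > 0))
  expect_true(all(sm$p_adj < 0.05))
})

test_that("two devices separated by 2 sigma recover a standardized difference near 2", {
  m <- default_effect_model()
  amp <- m$amp_mean
  amp["lavalier", ] <- amp["baseline", ] + 2 * 4.5
  off <- m$amp_sex_offset; off[] <- 0
  m2 <- default_effect_model(amp_mean = amp, sigma_amp_within = 4.5,
                             sigma_amp_participant = 0, amp_sex_offset = off)
  ft <- make_table(60, seed = 45, model = m2)
  keep <- ft$device %in% c("baseline", "lavalier")
  d <- cohens_d(ft$mean_amp_db[keep & ft$device == "lavalier"],
                ft$mean_amp_db[keep & ft$device == "baseline"])
  expect_equal(d, 2, tolerance = 0.1)
})
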