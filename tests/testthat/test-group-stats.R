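test_that("compare_to_null matches closed forms", {
  tbl <- tibble::tibble(observed_mean_r = c(0.1, 0.2, 0.15, 0.12),
                        null_mean_r = c(0.1, 0.2, 0.15, 0.12) - 0.1 +
                          c(0, 1e-6, -1e-6, 0))
  out <- compare_to_null(tbl)
  d <- tbl$observed_mean_r - tbl$null_mean_r
  expect_equal(out$cohens_d, mean(d) / sd(d))
  expect_equal(out$t_statistic, out$cohens_d * sqrt(4), tolerance = 1e-9)
  expect_equal(out$dof, 3)
  # identical columns: undefined statistic
  same <- tibble::tibble(observed_mean_r = 1:4 / 10, null_mean_r = 1:4 / 10)
  expect_error(compare_to_null(same), "zero variance")
})

test_that("mismatched-pairing null never scores an epoch against itself", {
  eps <- tiny_epochs(6, snr = 2, seed = 70)
  eps$subject_id <- 1L
  eps$stimulus_id <- 1:6
  eps$epoch_index <- 1L
  out <- nested_loo_decode(eps, t_min = -0.1, t_max = 0.25, lambda_grid = 1)
  nt <- null_distribution(out, n_permutations = 40, seed = 71)
  expect_equal(nrow(nt), 1)
  # the matched decode beats its own mismatched null
  expect_gt(nt$observed_mean_r, nt$null_mean_r)
  # epochs sharing envelope content (same stimulus+epoch) cannot be paired:
  # two distinct stimuli can swap, two copies of one stimulus cannot
  dup <- out
  dup$stimulus_id <- rep(1:2, each = 3)
  dup$epoch_index <- rep(1L, 6)
  expect_error(null_distribution(dup[c(1, 4), ], 5, 1), NA)
  expect_error(null_distribution(dup[c(1, 2), ], 5, 1), "mismatched")
})

test_that("pure-noise reconstructions give a null centred at zero", {
  set.seed(72)
  fake <- tibble::tibble(
    subject_id = rep(1:8, each = 6),
    stimulus_id = rep(1:6, 8),
    epoch_index = 1L,
    envelope = replicate(48, simulate_envelope(5, 64, sample.int(1e6, 1)),
                         simplify = FALSE),
    reconstruction = replicate(48, rnorm(320), simplify = FALSE))
  fake$accuracy <- purrr::map2_dbl(fake$reconstruction, fake$envelope, cor)
  nt <- null_distribution(fake, n_permutations = 50, seed = 73)
  se <- sd(nt$null_mean_r) / sqrt(nrow(nt))
  expect_lt(abs(mean(nt$null_mean_r)), 2 * se + 0.02)
})

test_that("the mixed model recovers absent random variation", {
  r <- simulate_accuracy_records(20, subject_sd = 0, stimulus_sd = 0,
                                 resid_sd = 0.05, seed = 80)
  f <- suppressWarnings(fit_lmm(code_indicators(r),
                                Reconstruction ~ Familiarity))
  vc <- f$random_variances
  expect_lt(vc$variance[vc$group == "Subject"], 1e-6)
  expect_lt(vc$variance[vc$group == "Stimulus"], 1e-6)
  expect_equal(f$r2_conditional, f$r2_marginal, tolerance = 1e-6)
})

test_that("an intercept-only fit returns the grand mean and ordered R2", {
  r <- code_indicators(simulate_accuracy_records(12, seed = 81))
  f <- fit_lmm(r, Reconstruction ~ 1)
  expect_equal(f$coefficients$estimate[1], mean(r$accuracy), tolerance = 0.01)
  expect_gte(f$r2_conditional, f$r2_marginal)
  expect_gte(f$r2_marginal, 0)
  expect_lte(f$r2_conditional, 1)
})

test_that("standardized familiarity effect is recovered within its CI", {
  # planted standardized effect: beta / sd(y) with half/half coding
  r <- code_indicators(simulate_accuracy_records(
    30, effect_high = 0.04, effect_low = 0.04, subject_sd = 0.02,
    stimulus_sd = 0.01, resid_sd = 0.07, seed = 82))
  f <- fit_lmm(r, Reconstruction ~ Familiarity)
  row <- f$coefficients[f$coefficients$term == "FamiliarityHigh", ]
  expect_lt(abs(row$estimate - 0.04), 0.02)
  implied_std <- 0.04 / sd(r$accuracy)
  expect_gt(implied_std, row$std_conf_low)
  expect_lt(implied_std, row$std_conf_high)
  # CI ordering invariant
  expect_true(all(f$coefficients$conf_low <= f$coefficients$estimate &
                    f$coefficients$estimate <= f$coefficients$conf_high))
})

test_that("tidy and glance expose the fit in broom style", {
  r <- code_indicators(simulate_accuracy_records(10, seed = 83))
  f <- fit_lmm(r, Reconstruction ~ Familiarity + Repetition)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std_error", "df", "t_value",
                    "p_value", "conf_low", "conf_high", "std_beta")
                  %in% names(td)))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("r2_marginal", "r2_conditional", "aic", "nobs")
                  %in% names(gl)))
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("likelihood-ratio test behaves at its boundaries and under signal", {
  r <- code_indicators(simulate_accuracy_records(
    20, effect_high = 0.06, effect_low = 0.06, seed = 84))
  full <- fit_lmm(r, Reconstruction ~ Familiarity)
  null <- fit_lmm(r, Reconstruction ~ 1)
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chisq, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1)
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p_value, 0.001)
  expect_error(likelihood_ratio_test(null, full), "nested")
})

test_that("stepwise keeps everything at alpha_fixed = 1 and is reproducible", {
  r <- code_indicators(simulate_accuracy_records(12, seed = 85))
  sw <- suppressWarnings(
    stepwise_backward(r, alpha_fixed = 1 + 1e-9, alpha_random = 1e-12))
  expect_setequal(retained_fixed_terms(sw),
                  c("Familiarity", "MindWandering", "Repetition",
                    "Familiarity:MindWandering", "Familiarity:Repetition",
                    "MindWandering:Repetition",
                    "Familiarity:MindWandering:Repetition"))
  sw1 <- suppressWarnings(stepwise_backward(r))
  sw2 <- suppressWarnings(stepwise_backward(r))
  expect_identical(sw1$elimination, sw2$elimination)
  expect_equal(deparse(sw1$reduced_formula), deparse(sw2$reduced_formula))
})

test_that("stepwise agrees with the packaged backward-elimination routine", {
  r <- code_indicators(simulate_accuracy_records(
    24, effect_high = 0.06, effect_low = 0.06,
    subject_sd = 0.035, stimulus_sd = 0.03, seed = 86))
  sw <- stepwise_backward(r)
  fr <- lmm_frame(r)
  m <- lmerTest::lmer(
    Reconstruction ~ Familiarity * MindWandering * Repetition +
      (1 | Subject) + (1 | Stimulus), data = fr, REML = TRUE)
  st <- lmerTest::step(m)
  kept <- attr(terms(lme4::nobars(formula(lmerTest::get_model(st)))),
               "term.labels")
  expect_setequal(retained_fixed_terms(sw), kept)
})

test_that("follow-up fits split the data and flag empty levels", {
  r <- code_indicators(simulate_accuracy_records(
    16, effect_high = 0.08, effect_low = 0, subject_sd = 0.02,
    stimulus_sd = 0.02, seed = 87))
  fu <- follow_up_by_level(r)
  expect_setequal(names(fu$fits), c("Low", "High"))
  s <- fu$summary[fu$summary$term == "FamiliarityHigh", ]
  expect_lt(s$p_value[s$level == "High"], 0.05)
  # identical subsets give identical fits
  r_same <- r
  r_same$coded_mw_group <- factor("High", levels = c("Low", "High"))
  r_low <- r
  r_low$coded_mw_group <- factor("Low", levels = c("Low", "High"))
  fit_hi <- follow_up_by_level(r_same)$fits$High
  fit_lo <- follow_up_by_level(r_low)$fits$Low
  expect_equal(fit_hi$coefficients$estimate, fit_lo$coefficients$estimate)
})
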