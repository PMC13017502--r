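# Synthetic cohorts, strategy-parameter recovery and the statistics stage.

test_that("cohort simulation honours extreme profiles", {
  prof <- cohort_profiles(
    data.frame(group = c("perfect", "lapser"),
               p_ic = c(1, 0), p_iw = c(1, 0), lapse = c(0, 1)),
    n_per_group = 5)
  tab <- simulate_cohort(prof, n_train = 30, n_test = 30, seed = 3)
  s <- cohort_summary(tab)
  perf <- s[s$group == "perfect", ]
  expect_true(all(perf$acc_ic_test == 1) && all(perf$acc_iw_test == 1))
  lap <- s[s$group == "lapser", ]
  expect_lt(abs(mean(c(lap$acc_ic_test, lap$acc_iw_test, lap$acc_train)) - 0.1),
            0.04)
  # every participant contributes every block kind
  expect_equal(nrow(dplyr::distinct(tab, participant_id, block_kind)), 10 * 4)
  expect_error(simulate_cohort(prof[0, ]), class = "zipflearn_argument_error")
})

test_that("generative strategy probabilities are recovered within 0.05", {
  prof <- cohort_profiles(
    data.frame(group = c("g1", "g2"), p_ic = c(0.8, 0.3),
               p_iw = c(0.25, 0.7), lapse = c(0.05, 0.05)),
    n_per_group = 30)
  tab <- simulate_cohort(prof, n_train = 150, n_test = 30, seed = 11)
  rec <- recover_profiles(tab, lapse = 0.05)
  rec <- dplyr::left_join(rec, prof[, c("participant_id", "p_ic", "p_iw")],
                          by = "participant_id")
  grp <- rec |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(d_ic = abs(mean(p_ic_hat) - mean(p_ic)),
                     d_iw = abs(mean(p_iw_hat) - mean(p_iw)))
  expect_true(all(grp$d_ic < 0.05))
  expect_true(all(grp$d_iw < 0.05))
})

test_that("Bayes factors match the closed form with interpretation bands", {
  expect_equal(as.numeric(bayes_factor(10, 10)), 1)
  expect_equal(as.numeric(bayes_factor(2 * log(100), 0)), 100, tolerance = 1e-12)
  bf <- bayes_factor(0, 2 * log(10))
  expect_equal(as.numeric(bf), 0.1, tolerance = 1e-12)
  expect_match(attr(bf, "category"), "strong evidence for absence")
  expect_match(bf_category(150), "decisive evidence for effect")
  expect_match(bf_category(1.5), "anecdotal")
})

test_that("Bonferroni adjusts and caps p values in order", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(0.004, m = 3), 0.012)
  expect_equal(bonferroni(c(0.02, 0.001), m = 5), c(0.1, 0.005))
  expect_error(bonferroni(1.2), class = "zipflearn_argument_error")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), class = "zipflearn_argument_error")
})

test_that("group contrasts detect strong effects and stay quiet under the null", {
  strong <- cohort_profiles(
    data.frame(group = c(0, 1), p_ic = c(0.8, 0.2), p_iw = c(0.5, 0.5)),
    n_per_group = 30)
  tab <- simulate_cohort(strong, n_train = 30, n_test = 30, seed = 21)
  fit <- fit_group_contrast(tab, "ic_test", family = "logistic")
  expect_lt(fit$p_value, 0.05)
  expect_gt(fit$bf, 100)
  expect_lt(fit$beta, 0)   # accuracy drops from group 0 to group 1
  # BF consistency with the reported BICs
  expect_equal(fit$bf, as.numeric(bayes_factor(fit$bic_null, fit$bic)))
  td <- tidy(fit); gl <- glance(fit)
  expect_equal(td$estimate, fit$beta)
  expect_equal(gl$bayes_factor, fit$bf)

  null_prof <- cohort_profiles(
    data.frame(group = c(0, 1), p_ic = c(0.5, 0.5), p_iw = c(0.5, 0.5)),
    n_per_group = 30)
  ntab <- simulate_cohort(null_prof, n_train = 30, n_test = 30, seed = 22)
  nfit <- fit_group_contrast(ntab, "ic_test")
  expect_lt(abs(nfit$beta), 0.5)
  expect_false(nfit$separation)
})

test_that("the linear family models participant-level double learning", {
  prof <- cohort_profiles(
    data.frame(group = c(0, 1), p_ic = c(0.9, 0.9), p_iw = c(0.2, 0.8)),
    n_per_group = 30)
  tab <- simulate_cohort(prof, n_train = 30, n_test = 30, seed = 31)
  fit <- fit_group_contrast(tab, family = "linear", outcome = "dli")
  expect_gt(fit$beta, 0)   # the double-learning group scores higher
  expect_lt(fit$p_value, 0.01)
})

test_that("perfect separation is flagged and handled by penalisation", {
  prof <- cohort_profiles(
    data.frame(group = c(0, 1), p_ic = c(0.0001, 0.9999), p_iw = c(0.5, 0.5)),
    n_per_group = 15)
  tab <- simulate_cohort(prof, n_train = 10, n_test = 30, seed = 41)
  fit <- fit_group_contrast(tab, "ic_test")
  expect_true(fit$separation)
  expect_true(is.finite(fit$beta) && is.finite(fit$se))
})

test_that("the random-intercept mode agrees in direction with the robust fit", {
  skip_if_not_installed("lme4")
  prof <- cohort_profiles(
    data.frame(group = c(0, 1), p_ic = c(0.8, 0.3), p_iw = c(0.5, 0.5)),
    n_per_group = 20)
  tab <- simulate_cohort(prof, n_train = 10, n_test = 30, seed = 51)
  f_glm <- fit_group_contrast(tab, "ic_test", method = "glm")
  f_mix <- fit_group_contrast(tab, "ic_test", method = "glmer")
  expect_identical(sign(f_glm$beta), sign(f_mix$beta))
  expect_lt(f_mix$p_value, 0.05)
})

test_that("cohort tables round-trip through CSV", {
  prof <- cohort_profiles(data.frame(group = c(0, 1), p_ic = c(0.5, 0.5),
                                     p_iw = c(0.5, 0.5)), n_per_group = 2)
  tab <- simulate_cohort(prof, n_train = 5, n_test = 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back[, c("participant_id", "block_kind", "trial_index",
                                      "correct", "response_type")]),
               as.data.frame(tab[, c("participant_id", "block_kind", "trial_index",
                                     "correct", "response_type")]))
})

test_that("contrast fits export to JSON", {
  prof <- cohort_profiles(data.frame(group = c(0, 1), p_ic = c(0.8, 0.2),
                                     p_iw = c(0.5, 0.5)), n_per_group = 10)
  tab <- simulate_cohort(prof, n_train = 5, n_test = 30, seed = 61)
  fit <- fit_group_contrast(tab, "ic_test")
  path <- withr::local_tempfile(fileext = ".json")
  write_contrast_json(fit, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$beta, fit$beta, tolerance = 1e-12)
  expect_true(!is.null(obj$bf_category))
})
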