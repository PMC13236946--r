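test_that("cohort generation is a pure function of (params, seed)", {
  p <- cohort_params(n_subjects = 20)
  c1 <- generate_cohort(p, seed = 11)
  c2 <- generate_cohort(p, seed = 11)
  c3 <- generate_cohort(p, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1$severity, c3$severity))
  # the generator leaves the caller's RNG stream alone
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(generate_cohort(p, seed = 11)); after <- runif(5)
  expect_identical(before, after)
})

test_that("generated assessments always satisfy the model invariants", {
  p <- cohort_params(n_subjects = 400, localization_prob = 0.3)
  cohort <- generate_cohort(p, seed = 21)
  for (a in cohort$assessments) {
    expect_identical(validate_assessment(a), character(0))
  }
})

test_that("expert labels correlate positively with DENTALE totals", {
  cohort <- generate_cohort(cohort_params(), seed = 22)
  totals <- score_cohort(cohort$assessments)$final_total
  expect_gt(cor(totals, as.numeric(cohort$expert_label)), 0.3)
  expect_gt(cor(totals, cohort$severity), 0.5)
})

test_that("degenerate severity limits hit the analytic extremes", {
  # pathology probabilities driven to zero -> every total is 0
  quiet <- cohort_params(n_subjects = 15,
                         item_intercepts = setNames(rep(-30, 9),
                                                    names(cohort_params()$item_intercepts)))
  c0 <- generate_cohort(quiet, seed = 31)
  expect_true(all(score_cohort(c0$assessments)$base_total == 0))

  # severity pinned at 1 with near-certain items -> the all-missing worst
  # case, base 158 (wear unscorable)
  loud <- cohort_params(n_subjects = 15, mix_weight_high = 1,
                        sev_high_shape = c(1e6, 1),
                        item_intercepts = setNames(rep(30, 9),
                                                   names(cohort_params()$item_intercepts)),
                        localization_prob = 0)
  c1 <- generate_cohort(loud, seed = 32)
  expect_true(all(score_cohort(c1$assessments)$base_total == 158))
})

test_that("localized subjects confine pathology to one sextant", {
  p <- cohort_params(n_subjects = 120, localization_prob = 1,
                     mix_weight_high = 1)
  cohort <- generate_cohort(p, seed = 33)
  expect_true(all(cohort$localized))
  chart <- tooth_chart()
  n_affected_sextants <- vapply(cohort$assessments, function(a) {
    tooth_abn <- a$teeth$status == "missing" |
      Reduce(`|`, a$teeth[c("crown_abnormal", "root_abnormal",
                            "crown_root_ratio_abnormal",
                            "eruption_not_age_appropriate")])
    sx <- unique(c(chart$sextant[tooth_abn],
                   a$sextants$sextant[a$sextants$alveolar_reduced |
                                        a$sextants$tooth_wear]))
    length(sx)
  }, integer(1))
  bony_quiet <- vapply(cohort$assessments, function(a) !any(a$bony),
                       logical(1))
  expect_true(all(n_affected_sextants <= 1L))
  expect_true(all(bony_quiet))
})

test_that("mean total is monotone in forced severity", {
  mean_total_at <- function(s) {
    # pin severity at s via a near-degenerate Beta
    eps <- 1e6
    p <- cohort_params(n_subjects = 60, mix_weight_high = 1,
                       sev_high_shape = c(max(s, 1e-9) * eps,
                                          max(1 - s, 1e-9) * eps),
                       localization_prob = 0)
    mean(score_cohort(generate_cohort(p, seed = 34)$assessments)$base_total)
  }
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), mean_total_at, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rater simulation honours its contract", {
  truth <- generate_cohort(cohort_params(n_subjects = 1), seed = 41)$assessments[[1]]
  copies <- simulate_raters(truth, rater_noise(flip_prob = 0), k = 3,
                            seed = 42)
  for (cp in copies) {
    expect_identical(cp$teeth, truth$teeth)
    expect_identical(cp$sextants, truth$sextants)
    expect_identical(unname(cp$bony), unname(truth$bony))
  }
  noisy <- simulate_raters(truth, rater_noise(flip_prob = 0.2), k = 4,
                           seed = 43)
  for (cp in noisy) expect_identical(validate_assessment(cp), character(0))
  expect_false(identical(noisy[[1]]$teeth$status, noisy[[2]]$teeth$status))

  expect_error(simulate_raters(truth, rater_noise(0.1), k = 1), "k = 2")
  expect_error(rater_noise(flip_prob = 0.5), "0.5")
  expect_error(rater_noise(flip_prob = -0.1), "0.5")
  expect_error(simulate_raters(truth, rater_noise(0.1, bias = c(0, 0.1)),
                               k = 3), "per rater")
})

test_that("noise-free raters on a varied cohort give ICC 1", {
  cohort <- generate_cohort(cohort_params(n_subjects = 10), seed = 44)
  mats <- sapply(cohort$assessments, function(truth) {
    copies <- simulate_raters(truth, rater_noise(0), k = 3, seed = 45)
    score_cohort(copies)$final_total
  })
  m <- t(mats)   # subjects x raters
  expect_equal(icc_two_way(m)$estimate, 1)
})

test_that("rater bias inflates aspect findings", {
  truth <- new_assessment("T")   # all normal: only bias can add findings
  copies <- simulate_raters(truth, rater_noise(flip_prob = 0,
                                               bias = c(0, 0.4)),
                            k = 2, seed = 46)
  n_flags <- vapply(copies, function(a)
    sum(unlist(a$teeth[c("crown_abnormal", "root_abnormal",
                         "crown_root_ratio_abnormal",
                         "eruption_not_age_appropriate")])), numeric(1))
  expect_equal(n_flags[1], 0)
  expect_gt(n_flags[2], 0)
})

test_that("recovery experiment returns one row per usable replicate", {
  expect_equal(nrow(recovery_experiment(cohort_params(n_subjects = 20),
                                        reps = 0)), 0L)
  res <- recovery_experiment(cohort_params(n_subjects = 40), reps = 5,
                             seed = 47)
  expect_equal(nrow(res) + attr(res, "n_skipped"), 5L)
  expect_true(all(res$selected_threshold %in% c(14, 16, 18, 20, NA)))
  res2 <- recovery_experiment(cohort_params(n_subjects = 40), reps = 5,
                              seed = 47)
  expect_identical(res, res2)
})
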