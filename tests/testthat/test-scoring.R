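test_that("the analytic extremes score 0 and 158", {
  s0 <- score_assessment(new_assessment("normal"))
  expect_equal(s0$base_total, 0)
  expect_equal(s0$final_total, 0)
  expect_false(s0$refer)

  s158 <- score_assessment(worst_case_assessment())
  expect_equal(s158$base_total, 158)
  expect_equal(s158$presence_points, 144)
  expect_equal(s158$condyle_points, 6)
  expect_equal(s158$ramus_points, 2)
  expect_equal(s158$alveolar_points, 6)
  expect_equal(s158$wear_points, 0)   # wear unscorable without teeth
  expect_true(s158$refer)
})

test_that("single-item deltas equal the published weights", {
  base <- new_assessment("S")
  delta <- function(a) score_assessment(a)$base_total
  expect_equal(delta(set_tooth(base, 13, status = "missing")), 8)  # canine
  expect_equal(delta(set_tooth(base, 41, status = "missing")), 6)  # incisor
  expect_equal(delta(set_tooth(base, 15, status = "missing")), 4)  # premolar
  expect_equal(delta(set_tooth(base, 37, status = "missing")), 4)  # molar
  expect_equal(delta(set_bony(base, condyle_left_abnormal = TRUE)), 3)
  expect_equal(delta(set_bony(base, ramus_right_abnormal = TRUE)), 1)
  expect_equal(delta(set_sextant(base, 3, alveolar_reduced = TRUE)), 1)
  expect_equal(delta(set_sextant(base, 2, tooth_wear = TRUE)), 1)
  expect_equal(delta(set_tooth(base, 21, crown_abnormal = TRUE,
                               root_abnormal = TRUE)), 2)
})

test_that("a lone missing canine gives 8 points in sextant 2, no referral", {
  s <- score_assessment(set_tooth(new_assessment("S"), 13,
                                  status = "missing"))
  expect_equal(s$base_total, 8)
  expect_equal(unname(s$per_sextant_totals["s2"]), 8)
  expect_equal(s$adjustment_points, 0)
  expect_equal(s$final_total, 8)
  expect_false(s$refer)
})

test_that("the >10-in-one-sextant rule adds 5 once, strictly", {
  # 8 + 6 = 14 points in sextant 2
  a <- set_tooth(new_assessment("S"), c(13, 11), status = "missing")
  s <- score_assessment(a)
  expect_equal(s$base_total, 14)
  expect_equal(unname(s$per_sextant_totals["s2"]), 14)
  expect_equal(s$adjustment_points, 5)
  expect_equal(s$final_total, 19)
  expect_true(s$refer)

  # exactly 10 in sextant 2: missing canine + two crown flags -> no bonus
  a10 <- set_tooth(new_assessment("S"), 13, status = "missing")
  a10 <- set_tooth(a10, c(12, 11), crown_abnormal = TRUE)
  s10 <- score_assessment(a10)
  expect_equal(unname(s10$per_sextant_totals["s2"]), 10)
  expect_equal(s10$adjustment_points, 0)
  expect_equal(s10$final_total, 10)

  # two qualifying sextants still add 5 under the default rule ...
  a2 <- set_tooth(new_assessment("S"), c(13, 11, 33, 31),
                  status = "missing")
  s2 <- score_assessment(a2)
  expect_equal(s2$adjustment_points, 5)
  # ... and 10 under the per-sextant sensitivity switch
  s2b <- score_assessment(a2, default_weights(adjustment_per_sextant = TRUE))
  expect_equal(s2b$adjustment_points, 10)

  # condyle/ramus points are attributed to no sextant
  abony <- set_bony(set_tooth(new_assessment("S"), 13, status = "missing"),
                    condyle_left_abnormal = TRUE,
                    condyle_right_abnormal = TRUE)
  sb <- score_assessment(abony)
  expect_equal(unname(sb$per_sextant_totals["s2"]), 8)
  expect_equal(sb$adjustment_points, 0)
})

test_that("referral decision is inclusive at the threshold", {
  expect_true(referral_decision(16))
  expect_false(referral_decision(15))
  expect_false(referral_decision(0))
  expect_equal(referral_decision(c(15, 16, 20)), c(FALSE, TRUE, TRUE))
  expect_true(referral_decision(14, default_weights(referral_threshold = 14)))
  expect_error(referral_decision(-1), "total")
})

test_that("excluded teeth contribute nothing anywhere", {
  a <- set_tooth(new_assessment("S"), 13, status = "missing",
                 exclusion_note = "orthodontic extraction")
  s <- score_assessment(a)
  expect_equal(s$base_total, 0)
  expect_equal(unname(s$per_sextant_totals["s2"]), 0)
  # a present-but-excluded tooth also scores no aspects
  b <- set_tooth(new_assessment("S"), 21, crown_abnormal = TRUE)
  b$teeth$exclusion_note[b$teeth$fdi == 21] <- "pre-treatment restoration"
  expect_equal(score_assessment(b)$base_total, 0)
})

test_that("score_cohort preserves order and reports bad records by index", {
  expect_equal(nrow(score_cohort(list())), 0L)
  res <- score_cohort(list(new_assessment("a"), worst_case_assessment()))
  expect_equal(res$base_total, c(0, 158))
  expect_equal(res$subject_id, c("a", "worst"))

  bad <- new_assessment("b"); bad$teeth <- bad$teeth[-1, ]
  expect_error(score_cohort(list(new_assessment("a"), bad)),
               "assessment 2")
})

test_that("invalid assessments are rejected with all violations listed", {
  a <- new_assessment("S")
  a$teeth$status[1] <- "missing"; a$teeth$crown_abnormal[1] <- TRUE
  a$age_at_opg_years <- -1
  err <- tryCatch(score_assessment(a), error = conditionMessage)
  expect_match(err, "unscorable")
  expect_match(err, "age")
})

test_that("scorer agrees with the brute-force oracle on random cases", {
  set.seed(401)
  for (i in 1:500) {
    a <- random_assessment(paste0("S", i), p_missing = runif(1, 0, 0.5),
                           p_flag = runif(1, 0, 0.5))
    s <- score_assessment(a)
    o <- oracle_score(a)
    expect_identical(s$base_total, o$base_total)
    expect_identical(s$final_total, o$final_total)
    expect_identical(unname(s$per_sextant_totals), o$per_sextant)
    expect_identical(s$refer, o$refer)
  }
})

test_that("flipping any single finding never decreases the final total", {
  set.seed(402)
  for (i in 1:60) {
    a <- random_assessment(paste0("S", i))
    s0 <- score_assessment(a)$final_total
    # candidate flips: one per item family, normal -> abnormal
    present <- a$teeth$fdi[a$teeth$status == "present" &
                             is.na(a$teeth$exclusion_note)]
    if (length(present)) {
      t <- sample(present, 1)
      expect_gte(score_assessment(set_tooth(a, t, status = "missing"))$final_total, s0)
      expect_gte(score_assessment(set_tooth(a, t, root_abnormal = TRUE))$final_total, s0)
    }
    sx <- sample(1:6, 1)
    expect_gte(score_assessment(set_sextant(a, sx, alveolar_reduced = TRUE))$final_total, s0)
    expect_gte(score_assessment(set_bony(a, condyle_right_abnormal = TRUE))$final_total, s0)
  }
})

test_that("base totals stay inside [0, max_base_score] on random cases", {
  set.seed(403)
  hi <- max_base_score()
  for (i in 1:200) {
    s <- score_assessment(random_assessment(paste0("S", i),
                                            p_missing = runif(1),
                                            p_flag = runif(1)))
    expect_gte(s$base_total, 0)
    expect_lte(s$base_total, hi)
    # missing/aspect exclusivity: totals decompose exactly
    expect_equal(s$base_total,
                 s$presence_points + s$aspect_points + s$alveolar_points +
                   s$wear_points + s$condyle_points + s$ramus_points)
  }
})
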