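test_that("generation is seeded, reproducible, and respects n", {
  expect_equal(nrow(generate_cohort(0, seed = 1)), 0)
  a <- generate_cohort(20, seed = 5, items = TRUE)
  b <- generate_cohort(20, seed = 5, items = TRUE)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_cohort(20, seed = 6)
  expect_false(identical(tibble::as_tibble(a)[names(c)], tibble::as_tibble(c)))
  expect_equal(sum(a$timepoint == "baseline"), 20)
  expect_error(generate_cohort(10, seed = NULL), "seed")
})

test_that("adding a variable does not disturb the draws of existing ones", {
  a <- generate_cohort(15, seed = 44)
  spec2 <- cohort_spec(variables = list(
    steps = list(mean = 7000, sd = 2500, change_mean = 500, change_sd = 1500,
                 min = 0, max = 40000, grain = 1)))
  b <- generate_cohort(15, spec2, seed = 44)
  expect_equal(a$diet_score, b$diet_score)
  expect_equal(a$sleep_hours, b$sleep_hours)
  expect_true("steps" %in% names(b))
})

test_that("completion counts sit in the binomial band around (1 - dropout) * n", {
  completers <- vapply(1:40, function(s) {
    coh <- generate_cohort(30, cohort_spec(dropout = 0.2), seed = 100 + s)
    sum(coh$timepoint == "followup")
  }, numeric(1))
  # binomial(30, 0.8): mean 24, sd 2.19; the mean of 40 cohorts should sit
  # well inside +/- 3 SE of 24 and every draw inside the support
  expect_true(all(completers >= 0 & completers <= 30))
  expect_lt(abs(mean(completers) - 24), 3 * 2.19 / sqrt(40))
})

test_that("generated values respect instrument ranges and grains", {
  coh <- generate_cohort(200, seed = 21, items = TRUE)
  expect_true(all(coh$diet_score >= 0 & coh$diet_score <= 14))
  expect_true(all(coh$diet_score == round(coh$diet_score)))
  expect_true(all(coh$positive_mood >= 10 & coh$positive_mood <= 50))
  expect_true(all(coh$life_satisfaction >= 5 & coh$life_satisfaction <= 35))
  expect_true(all(coh$stress >= 0 & coh$stress <= 40))
  expect_true(all(coh$sleep_hours >= 3 & coh$sleep_hours <= 12))
  expect_true(all(coh$age >= 30 & coh$age <= 60))
  mood_items <- as.matrix(coh[grep("^(pos|neg)_mood_item_", names(coh))])
  expect_true(all(mood_items >= 1 & mood_items <= 5))
  diet_items <- as.matrix(coh[grep("^diet_item_", names(coh))])
  expect_true(all(diet_items %in% c(0, 1)))
  # back-filled items reproduce the target scores exactly
  expect_equal(unname(rowSums(diet_items)), coh$diet_score)
  stress_items <- as.matrix(coh[grep("^stress_item_", names(coh))])
  rev_idx <- c(4, 5, 7, 8)
  coded <- stress_items; coded[, rev_idx] <- 4 - coded[, rev_idx]
  expect_equal(unname(rowSums(coded)), coh$stress)
})

test_that("a baseline mean outside the legal range is rejected", {
  expect_error(cohort_spec(variables = list(
    diet_score = list(mean = 20, sd = 1, change_mean = 0, change_sd = 1,
                      min = 0, max = 14, grain = 1))), "legal range")
})

test_that("power simulation is calibrated at the null and monotone in effect size", {
  null <- simulate_power(n = 18, delta = 0, sd = 0.75, reps = 10000, seed = 17)
  expect_lt(abs(null$power - 0.05), 0.01)
  small <- simulate_power(n = 24, delta = 0.25, sd = 0.75, reps = 4000, seed = 18)
  large <- simulate_power(n = 24, delta = 0.5, sd = 0.75, reps = 4000, seed = 18)
  expect_gt(large$power, small$power)
  expect_equal(large$se, sqrt(large$power * (1 - large$power) / 4000))
})

test_that("simulated power agrees with the analytic noncentral-t power", {
  est <- simulate_power(n = 24, delta = 0.5, sd = 0.75, reps = 10000, seed = 19)
  analytic <- stats::power.t.test(n = 24, delta = 0.5, sd = 0.75,
                                  sig.level = 0.05, type = "paired")$power
  expect_lt(abs(est$power - analytic), 4 * est$se)
})

test_that("the generator and the estimator recover a known diet change", {
  spec <- cohort_spec(dropout = 0)
  est <- vapply(1:300, function(s) {
    coh <- generate_cohort(18, spec, seed = 2000 + s)
    base <- dplyr::filter(coh, timepoint == "baseline")
    fu <- dplyr::filter(coh, timepoint == "followup")
    mean(fu$diet_score[match(base$id, fu$id)] - base$diet_score)
  }, numeric(1))
  # default diet change is +1.4 (SD 1.5): the grand mean over 300 cohorts of
  # 18 has SE 1.5/sqrt(300*18) = 0.020
  expect_lt(abs(mean(est) - 1.4), 3 * 1.5 / sqrt(300 * 18))
})
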