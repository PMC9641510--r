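test_that("paired t test matches the closed form and defines degenerate cases", {
  # d = (1,2,3,4): mean 2.5, sd 1.2910, t = 3.873, p = 0.0305
  res <- paired_t_test(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(res$estimate, 2.5)
  expect_equal(res$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(res$p.value, 0.03046629, tolerance = 1e-6)
  expect_true(res$significant)

  same <- paired_t_test(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  shifted <- paired_t_test(c(1, 1, 1), c(2, 2, 2)) # zero variance, nonzero mean
  expect_equal(shifted$p.value, 0)

  neg <- paired_t_test(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(neg$statistic, -res$statistic)
  expect_equal(neg$p.value, res$p.value)
  expect_error(paired_t_test(1, 2), ">= 2")
})

test_that("paired t p-value is invariant to adding a constant to both arms", {
  set.seed(5)
  pre <- rnorm(12); post <- pre + rnorm(12, 0.3)
  a <- paired_t_test(pre, post)
  b <- paired_t_test(pre + 100, post + 100)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, b$statistic)
})

test_that("paired t agrees with stats::t.test", {
  set.seed(6)
  for (i in 1:10) {
    pre <- rnorm(15); post <- pre + rnorm(15, 0.4)
    ours <- paired_t_test(pre, post)
    ref <- stats::t.test(post, pre, paired = TRUE)
    expect_equal(ours$p.value, ref$p.value)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("exact Wilcoxon p comes from the sign-assignment distribution", {
  # all five differences positive: only the two all-same-sign assignments
  # are as extreme, p = 2/32
  res <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(res$statistic, 15)
  expect_equal(res$p.value, 2 / 32)
  expect_equal(res$method, "wilcoxon_exact")

  zeros <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(zeros$p.value, 1)

  expect_error(wilcoxon_signed_rank(numeric(0), numeric(0)), "at least one")
})

test_that("exact Wilcoxon equals brute-force enumeration, with ties and zeros", {
  set.seed(7)
  for (i in 1:40) {
    m <- sample(3:10, 1)
    # half-integer grid forces ties; some exact zeros get dropped
    pre <- round(rnorm(m) * 2) / 2
    post <- round(rnorm(m, 0.3) * 2) / 2
    if (all(post - pre == 0)) next
    ours <- wilcoxon_signed_rank(pre, post, mode = "exact")
    expect_equal(ours$p.value, wilcoxon_enumeration_p(pre, post), info = i)
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test when there are no ties", {
  set.seed(8)
  for (i in 1:10) {
    pre <- rnorm(10); post <- pre + rnorm(10, 0.5)
    ours <- wilcoxon_signed_rank(pre, post, mode = "exact")
    ref <- stats::wilcox.test(post, pre, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("normal approximation tracks the exact p-value at m = 12", {
  set.seed(9)
  for (i in 1:20) {
    pre <- rnorm(12); post <- pre + rnorm(12, 0.4)
    pe <- wilcoxon_signed_rank(pre, post, mode = "exact")$p.value
    pa <- wilcoxon_signed_rank(pre, post, mode = "approximate")$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("sample size reproduces the published design and scales correctly", {
  planned <- required_sample_size(0.5, 0.75, alpha = 0.05, power = 0.90, dropout = 0.20)
  expect_identical(planned$n_enroll, 30L)
  expect_identical(planned$n_complete, 24L)
  expect_identical(required_sample_size(0.5, 0.75, dropout = 0)$n_enroll, 24L)

  # monotonicity: non-increasing in delta and alpha, non-decreasing in
  # sd, power, dropout
  base <- required_sample_size(0.5, 0.75)$n_enroll
  expect_lte(required_sample_size(1.0, 0.75)$n_enroll, base)
  expect_lte(required_sample_size(0.5, 0.75, alpha = 0.10)$n_enroll, base)
  expect_gte(required_sample_size(0.5, 1.5)$n_enroll, base)
  expect_gte(required_sample_size(0.5, 0.75, power = 0.95)$n_enroll, base)
  expect_gte(required_sample_size(0.5, 0.75, dropout = 0.4)$n_enroll, base)
  # halving sd quarters the pre-dropout n up to ceiling effects
  expect_equal(required_sample_size(0.5, 0.375)$n_complete, 6L)
  expect_error(required_sample_size(0, 0.75), "nonzero")
  expect_error(required_sample_size(0.5, -1), "> 0")
})

test_that("cohort summaries render integer percentages and labelled spreads", {
  coh <- neutral_cohort(16)
  coh$sex <- c(rep("female", 10), rep("male", 6))
  coh$smoking <- c(rep("never", 12), rep("ex", 4))
  s <- summarize_cohort(coh)
  expect_equal(s$baseline[s$variable == "sex:female"], "10 (63%)")
  expect_equal(s$baseline[s$variable == "smoking:never"], "12 (75%)")
  expect_equal(s$baseline[s$variable == "sex:male"], "6 (38%)")
  # nonparametric rows display both the full range and the IQR, labelled
  expect_match(s$baseline[s$variable == "sleep_hours"], "range .*IQR")
  # parametric rows display mean (SD)
  expect_equal(s$kind[s$variable == "diet_score"], "mean (SD)")
  expect_equal(nrow(summarize_cohort(neutral_cohort(0))), 0)
})

test_that("evaluation uses the fixed variable-test assignment on complete cases", {
  coh <- generate_cohort(27, seed = 12)
  ev <- evaluate_pre_post(coh)
  td <- tidy(ev)
  expect_equal(td$method[td$variable == "diet_score"], "paired_t")
  expect_equal(td$method[td$variable == "life_satisfaction"], "paired_t")
  expect_equal(td$method[td$variable == "combined_mood"], "paired_t")
  for (v in c("delta", "bmi", "weight_kg", "met_hours", "stress", "sleep_hours")) {
    expect_match(td$method[td$variable == v], "^wilcoxon", info = v)
  }
  expect_true(all(td$n == ev$n_completers))
  expect_identical(td$significant, td$p.value <= 0.05)
  gl <- glance(ev)
  expect_equal(gl$n_enrolled, 27)
  expect_equal(gl$n_completers, ev$n_completers)
})

test_that("evaluation handles no follow-ups and identical pre/post", {
  base_only <- neutral_cohort(5)
  ev <- evaluate_pre_post(base_only)
  expect_equal(ev$n_enrolled, 5)
  expect_equal(ev$n_completers, 0)
  expect_equal(nrow(ev$tests), 0)

  both <- dplyr::bind_rows(neutral_cohort(6), neutral_cohort(6, "followup"))
  ev2 <- evaluate_pre_post(both)
  expect_equal(ev2$n_completers, 6)
  expect_true(all(!tidy(ev2)$significant))
})

test_that("a 27-enrolled cohort with 9 dropouts reports exactly 18 completers", {
  coh <- generate_cohort(27, cohort_spec(dropout = 0), seed = 3)
  drop_ids <- unique(coh$id)[1:9]
  coh <- dplyr::filter(coh, !(id %in% drop_ids & timepoint == "followup"))
  ev <- evaluate_pre_post(coh)
  expect_equal(ev$n_enrolled, 27)
  expect_equal(ev$n_completers, 18)
})

test_that("both paired tests hold their nominal size under the null at n = 18", {
  set.seed(1)
  reps <- 10000
  hit_t <- 0; hit_w <- 0
  for (i in seq_len(reps)) {
    pre <- rnorm(18); post <- pre + rnorm(18)
    if (paired_t_test(pre, post)$p.value <= 0.05) hit_t <- hit_t + 1
    if (wilcoxon_signed_rank(pre, post)$p.value <= 0.05) hit_w <- hit_w + 1
  }
  expect_lt(abs(hit_t / reps - 0.05), 0.01)
  expect_lt(abs(hit_w / reps - 0.05), 0.01)
})
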