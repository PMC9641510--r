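test_that("relative risks convert to years via the Gompertz age shift", {
  expect_equal(rr_to_years(1, 0.0866), 0)
  expect_equal(rr_to_years(2, 0.0866), 8.004, tolerance = 1e-4) # ln(2)/0.0866
  expect_equal(rr_to_years(0.5, 0.0866), -rr_to_years(2, 0.0866))
  expect_error(rr_to_years(0), "> 0")
  expect_error(rr_to_years(-1), "> 0")
  expect_error(rr_to_years(2, slope = 0), "> 0")
})

test_that("rr_to_years is log-additive", {
  rr1 <- c(0.7, 1.3, 2.5); rr2 <- c(1.1, 0.4, 3)
  expect_equal(rr_to_years(rr1 * rr2), rr_to_years(rr1) + rr_to_years(rr2))
})

test_that("profile banding matches the published anchors", {
  cats <- categorize_profile(bmi = 22, smoking = "never", alcohol_units = 10,
                             binge = FALSE, diet_score = 12, met_hours = 25)
  expect_equal(cats$bmi, "<23")
  expect_equal(cats$alcohol, "none_low") # < 14 units/week is no/low
  expect_equal(cats$diet, "optimal")
  expect_equal(cats$activity, "high")

  expect_equal(categorize_profile(bmi = 24, smoking = "ex", alcohol_units = 14,
                                  diet_score = 8, met_hours = 0)$activity, "sedentary")
  expect_equal(categorize_profile(bmi = 31, smoking = "current", alcohol_units = 20,
                                  diet_score = 5, met_hours = 5)$bmi, "30-39.9")
  # BMI derived from height/weight when absent: 70 / 1.7^2 = 24.2
  expect_equal(categorize_profile(height_m = 1.7, weight_kg = 70, smoking = "never",
                                  alcohol_units = 0, diet_score = 8,
                                  met_hours = 10)$bmi, "23-24.9")
  expect_error(categorize_profile(smoking = "never", alcohol_units = 0,
                                  diet_score = 8, met_hours = 10), "BMI")
  expect_error(categorize_profile(bmi = 24, smoking = "pipe", alcohol_units = 0,
                                  diet_score = 8, met_hours = 10), "smoking")
})

test_that("binge flag overrides unit-based alcohol banding", {
  expect_equal(categorize_profile(bmi = 24, smoking = "ex", alcohol_units = 2,
                                  binge = TRUE, diet_score = 8, met_hours = 10)$alcohol,
               "binge")
  expect_equal(categorize_profile(bmi = 24, smoking = "ex", alcohol_units = 30,
                                  binge = FALSE, diet_score = 8, met_hours = 10)$alcohol,
               "moderate")
})

test_that("lifestyle offsets hit the published extremes and the zero reference", {
  best <- lifestyle_offset(list(bmi = "<23", smoking = "never", alcohol = "none_low",
                                diet = "optimal", activity = "high"))
  worst <- lifestyle_offset(list(bmi = ">=40", smoking = "current", alcohol = "binge",
                                 diet = "poor", activity = "sedentary"))
  ref <- lifestyle_offset(list(bmi = "23-24.9", smoking = "ex", alcohol = "moderate",
                               diet = "average", activity = "moderate"))
  expect_equal(best$total, -6)
  expect_equal(worst$total, 28)
  expect_equal(ref$total, 0)
  expect_error(lifestyle_offset(list(bmi = "<23", smoking = "never", alcohol = "none_low",
                                     diet = "mediterranean", activity = "high")),
               "diet.*mediterranean")
  expect_error(lifestyle_offset(list(bmi = "<23")), "missing factor")
})

test_that("total offset is exactly additive over the per-factor breakdown", {
  cfg <- la_config()
  set.seed(11)
  for (i in 1:50) {
    cats <- lapply(cfg$offsets, function(tab) sample(names(tab), 1))
    res <- lifestyle_offset(cats, cfg)
    expect_identical(res$total, sum(res$breakdown$years))
    expect_gte(res$total, -6)
    expect_lte(res$total, 28)
  }
})

test_that("default offsets are monotone from healthiest to least healthy category", {
  cfg <- la_config()
  healthy_order <- list(
    bmi = c("<23", "23-24.9", "25-29.9", "30-39.9", ">=40"),
    smoking = c("never", "ex", "current"),
    alcohol = c("none_low", "moderate", "binge"),
    diet = c("optimal", "average", "poor"),
    activity = c("high", "moderate", "low", "sedentary"))
  for (f in names(healthy_order)) {
    expect_false(is.unsorted(cfg$offsets[[f]][healthy_order[[f]]]), info = f)
  }
})

test_that("a relative-risk table reproduces a years table built from the same risks", {
  b <- 0.0866
  rr <- list(
    bmi = c("<23" = 0.92, "23-24.9" = 1, "25-29.9" = 1.2, "30-39.9" = 1.4, ">=40" = 2.0),
    smoking = c(never = 0.84, ex = 1, current = 2.0),
    alcohol = c(none_low = 0.9, moderate = 1, binge = 1.42),
    diet = c(optimal = 0.92, average = 1, poor = 1.41),
    activity = c(high = 0.92, moderate = 1, low = 1.19, sedentary = 1.41))
  cfg_rr <- suppressWarnings(la_config(rr = rr, gompertz_slope = b))
  years_tab <- lapply(rr, function(v) log(v) / b)
  cfg_years <- suppressWarnings(la_config(offsets = years_tab))
  cats <- list(bmi = "25-29.9", smoking = "current", alcohol = "none_low",
               diet = "poor", activity = "low")
  expect_equal(lifestyle_offset(cats, cfg_rr)$total,
               lifestyle_offset(cats, cfg_years)$total, tolerance = 1e-9)
})
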