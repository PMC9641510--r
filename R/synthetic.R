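#' Specification of a synthetic paired cohort
#'
#' Per-variable baseline distributions, change effects (mean shift + SD of
#' within-person change) and a missing-completely-at-random dropout
#' fraction. Defaults are calibrated to the published baseline marginals
#' of the feasibility cohort (diet score 7.1 (SD 1.8), life satisfaction
#' 30.6 (6.3), positive mood 35.7 (6.4), stress median 15, sleep median
#' 6.5 h, BMI median 24.2 kg/m2, weight median 68 kg, waist 81.3 cm,
#' activity median 13.3 MET-h) and to its observed mean changes (diet
#' +1.4, satisfaction +3.6, sleep +0.5 h, stress -1, BMI -1.4, activity
#' +3.4); change SDs are free calibration parameters, not published.
#' Follow-up values are baseline + a normal change draw, clipped to each
#' instrument's legal range and rounded to its grain. Dropout defaults to
#' 1/3, the completion pattern the feasibility study observed (18 of 27).
#'
#' @param variables named list; each element is a list with `mean`, `sd`
#'   (baseline normal), `change_mean`, `change_sd`, `min`, `max`, and
#'   `grain` (rounding unit; 0 = continuous).
#' @param dropout fraction lost to follow-up, in \[0, 1).
#' @param p_female,p_never_smoker,p_ex_smoker,p_binge category probabilities.
#' @return list of class `lifeage_effect_spec`.
#' @export
cohort_spec <- function(variables = list(), dropout = 1 / 3,
                        p_female = 0.63, p_never_smoker = 0.74,
                        p_ex_smoker = 0.26, p_binge = 0.10) {
  defaults <- list(
    age               = list(mean = 38, sd = 8, change_mean = 0, change_sd = 0, min = 30, max = 60, grain = 1),
    bmi               = list(mean = 24.8, sd = 3.5, change_mean = -1.4, change_sd = 2.0, min = 15, max = 50, grain = 0.1),
    height_m          = list(mean = 1.68, sd = 0.09, change_mean = 0, change_sd = 0, min = 1.4, max = 2.1, grain = 0.01),
    waist_cm          = list(mean = 81.3, sd = 11, change_mean = -3.8, change_sd = 5, min = 50, max = 160, grain = 0.1),
    alcohol_units     = list(mean = 7, sd = 6, change_mean = -0.5, change_sd = 3, min = 0, max = 80, grain = 1),
    met_hours         = list(mean = 14, sd = 12, change_mean = 3.4, change_sd = 8, min = 0, max = 80, grain = 0.1),
    diet_score        = list(mean = 7.1, sd = 1.8, change_mean = 1.4, change_sd = 1.5, min = 0, max = 14, grain = 1),
    positive_mood     = list(mean = 35.7, sd = 6.4, change_mean = 1.8, change_sd = 4, min = 10, max = 50, grain = 1),
    negative_mood     = list(mean = 18, sd = 6, change_mean = -1.5, change_sd = 4, min = 10, max = 50, grain = 1),
    life_satisfaction = list(mean = 30.6, sd = 6.3, change_mean = 3.6, change_sd = 4.5, min = 5, max = 35, grain = 1),
    stress            = list(mean = 16, sd = 7, change_mean = -1, change_sd = 4, min = 0, max = 40, grain = 1),
    sleep_hours       = list(mean = 6.5, sd = 1.0, change_mean = 0.5, change_sd = 0.8, min = 3, max = 12, grain = 0.5)
  )
  vars <- utils::modifyList(defaults, variables)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (v$sd < 0 || v$change_sd < 0) stop_config(sprintf("SDs for '%s' must be >= 0", nm))
    if (v$mean < v$min || v$mean > v$max) {
      stop_config(sprintf("baseline mean for '%s' (%g) lies outside its legal range [%g, %g]",
                          nm, v$mean, v$min, v$max))
    }
  }
  if (dropout < 0 || dropout >= 1) stop_range("dropout must lie in [0, 1)")
  structure(list(variables = vars, dropout = dropout, p_female = p_female,
                 p_never_smoker = p_never_smoker, p_ex_smoker = p_ex_smoker,
                 p_binge = p_binge),
            class = "lifeage_effect_spec")
}

# derive one RNG substream seed per variable from the master seed so the
# draws for a variable do not move when another variable is added
substream_seeds <- function(seed, k) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, k)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

draw_truncnorm <- function(n, mean, sd, lo, hi, grain) {
  x <- rnorm(n, mean, sd)
  x <- clip(x, lo, hi)
  if (grain > 0) x <- round_half_up(x / grain) * grain
  x
}

#' Generate a synthetic paired cohort
#'
#' Draws `n` baseline records from the spec's baseline distributions,
#' applies per-variable change draws to produce follow-up records, and
#' drops each follow-up independently with probability `dropout`
#' (missing completely at random). A single integer seed governs the
#' whole cohort; per-variable substreams are derived from it, so runs are
#' exactly reproducible. All values are clipped to instrument ranges and
#' rounded to instrument grain.
#'
#' @param n number of participants enrolled at baseline.
#' @param spec a [cohort_spec()].
#' @param seed integer seed (required for reproducibility).
#' @param items also back-fill raw questionnaire item columns
#'   (`diet_item_*`, `pos_mood_item_*`, `neg_mood_item_*`,
#'   `satisfaction_item_*`, `stress_item_*`) consistent with the target
#'   scores.
#' @return long tibble (class `lifeage_cohort`): one row per
#'   participant-timepoint with `id`, `timepoint` ("baseline"/"followup")
#'   and measurement columns; follow-up rows exist only for completers.
#'   Attributes `seed` and `spec`.
#' @examples
#' coh <- generate_cohort(30, seed = 7)
#' table(coh$timepoint)
#' @export
generate_cohort <- function(n, spec = cohort_spec(), seed, items = FALSE) {
  if (!inherits(spec, "lifeage_effect_spec")) stop_input("spec must come from cohort_spec()")
  if (n < 0) stop_input("n must be >= 0")
  if (missing(seed) || is.null(seed)) stop_input("an explicit integer seed is required")
  if (n == 0) {
    out <- tibble::tibble(id = character(), timepoint = character())
    class(out) <- c("lifeage_cohort", class(out))
    attr(out, "seed") <- seed; attr(out, "spec") <- spec
    return(out)
  }
  vars <- spec$variables
  # shared streams (categorical, dropout, items) come first so that adding
  # a variable to the spec does not disturb them or the other variables
  seeds <- substream_seeds(seed, 3 + length(vars))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))

  base <- tibble::tibble(id = sprintf("P%03d", seq_len(n)), timepoint = "baseline")
  fu_vals <- list()
  for (i in seq_along(vars)) {
    nm <- names(vars)[i]; v <- vars[[i]]
    set.seed(seeds[3 + i])
    b <- draw_truncnorm(n, v$mean, v$sd, v$min, v$max, v$grain)
    f <- b + rnorm(n, v$change_mean, v$change_sd)
    f <- clip(f, v$min, v$max)
    if (v$grain > 0) f <- round_half_up(f / v$grain) * v$grain
    base[[nm]] <- b
    fu_vals[[nm]] <- f
  }
  set.seed(seeds[1])
  base$sex <- ifelse(runif(n) < spec$p_female, "female", "male")
  u <- runif(n)
  base$smoking <- ifelse(u < spec$p_never_smoker, "never",
                         ifelse(u < spec$p_never_smoker + spec$p_ex_smoker, "ex", "current"))
  base$binge <- runif(n) < spec$p_binge
  base$weight_kg <- round_half_up(base$bmi * base$height_m^2, 1)

  set.seed(seeds[2])
  completes <- runif(n) < (1 - spec$dropout)
  fu <- base[completes, ]
  fu$timepoint <- "followup"
  for (nm in names(fu_vals)) fu[[nm]] <- fu_vals[[nm]][completes]
  fu$weight_kg <- round_half_up(fu$bmi * fu$height_m^2, 1)

  out <- dplyr::bind_rows(base, fu)
  if (items) {
    set.seed(seeds[3])
    out <- backfill_items(out)
  }
  class(out) <- c("lifeage_cohort", class(out))
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  out
}

# distribute a target total over k items each in [lo, hi]; random split so
# repeated cohorts vary, errors if the total is unreachable
distribute_sum <- function(total, k, lo, hi) {
  if (total < k * lo || total > k * hi) {
    stop_range(sprintf("target score %g unreachable with %d items in [%d, %d]", total, k, lo, hi))
  }
  x <- rep(lo, k)
  remainder <- total - k * lo
  while (remainder > 0) {
    open <- which(x < hi)
    pick <- open[sample.int(length(open), 1)]
    add <- min(hi - x[pick], remainder, sample.int(hi - lo, 1))
    x[pick] <- x[pick] + add
    remainder <- remainder - add
  }
  x
}

backfill_items <- function(tab) {
  n <- nrow(tab)
  blocks <- list(
    list(prefix = "diet_item_", k = 14, lo = 0, hi = 1, score = "diet_score"),
    list(prefix = "pos_mood_item_", k = 10, lo = 1, hi = 5, score = "positive_mood"),
    list(prefix = "neg_mood_item_", k = 10, lo = 1, hi = 5, score = "negative_mood"),
    list(prefix = "satisfaction_item_", k = 5, lo = 1, hi = 7, score = "life_satisfaction")
  )
  for (bl in blocks) {
    m <- t(vapply(tab[[bl$score]], distribute_sum, numeric(bl$k),
                  k = bl$k, lo = bl$lo, hi = bl$hi))
    colnames(m) <- paste0(bl$prefix, seq_len(bl$k))
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(m))
  }
  # stress: reverse-coded items 4,5,7,8 -> generate on the coded scale then invert
  coded <- t(vapply(tab$stress, distribute_sum, numeric(10), k = 10, lo = 0, hi = 4))
  coded[, c(4, 5, 7, 8)] <- 4 - coded[, c(4, 5, 7, 8)]
  colnames(coded) <- paste0("stress_item_", 1:10)
  dplyr::bind_cols(tab, tibble::as_tibble(coded))
}

#' Monte-Carlo power of the paired t test
#'
#' Simulates `reps` cohorts of `n` paired differences drawn from
#' normal(`delta`, `sd`), applies the two-sided paired t test to each, and
#' reports the fraction significant at `alpha` with its binomial standard
#' error. With `delta = 0` this estimates the type-I error rate.
#'
#' @param n number of complete pairs per simulated cohort.
#' @param delta true mean paired change.
#' @param sd SD of the paired change, > 0.
#' @param alpha two-sided significance level.
#' @param reps number of simulated cohorts (>= 1000 recommended for
#'   reporting).
#' @param seed integer seed.
#' @return one-row tibble: `power`, `se`, `n`, `delta`, `sd`, `alpha`,
#'   `reps`.
#' @examples
#' simulate_power(n = 24, delta = 0.5, sd = 0.75, reps = 2000, seed = 1)
#' @export
simulate_power <- function(n, delta, sd, alpha = 0.05, reps = 10000, seed) {
  if (n < 2) stop_input("need n >= 2 pairs")
  if (sd <= 0) stop_range("sd must be > 0")
  if (reps < 1) stop_input("reps must be >= 1")
  if (missing(seed) || is.null(seed)) stop_input("an explicit integer seed is required")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  set.seed(seed)
  d <- matrix(rnorm(reps * n, mean = delta, sd = sd), nrow = reps)
  means <- rowMeans(d)
  sds <- sqrt(rowSums((d - means)^2) / (n - 1))
  tstat <- means / (sds / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  pw <- mean(p <= alpha)
  tibble::tibble(power = pw, se = sqrt(pw * (1 - pw) / reps),
                 n = as.integer(n), delta = delta, sd = sd,
                 alpha = alpha, reps = as.integer(reps))
}
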