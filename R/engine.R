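#' Score a cohort table: Life Age for every participant
#'
#' The main pipeline entry point. Takes one row per participant (or
#' participant-timepoint), computes the lifestyle effective-age offset and
#' the psychosocial offset, and returns a tibble with the full additive
#' decomposition: `life_age = age + lifestyle_years + psychosocial_years`
#' and `delta = life_age - age`. Deterministic: identical inputs and
#' configuration give bit-identical results.
#'
#' Recognised columns (units fixed by the schema): `id`, `age` (years),
#' `sex`, `height_m`, `weight_kg`, `bmi` (kg/m^2), `waist_cm`, `smoking`
#' (never/ex/current), `alcohol_units` (UK units/week), `binge` (logical),
#' `moderate_minutes`, `vigorous_minutes`, `met_hours` (MET-hours/week),
#' `diet_score` (0-14), `positive_mood`, `negative_mood` (10-50),
#' `life_satisfaction` (5-35), `stress` (0-40), `sleep_hours` (h/night),
#' `timepoint`. Raw questionnaire items may be supplied instead of (or as
#' well as) precomputed scores via columns `diet_item_1..14`,
#' `pos_mood_item_1..10`, `neg_mood_item_1..10`, `satisfaction_item_1..5`,
#' `stress_item_1..10`; when both are present they must agree. Waist
#' circumference and sex are carried through for reporting but enter no
#' score. Unknown columns are ignored.
#'
#' @param data data frame of participant records.
#' @param config a [la_config()] lifestyle offset configuration.
#' @param norms a [la_norms()] psychosocial norms configuration.
#' @param on_error "collect" (default): rows that fail validation get NA
#'   results and are reported in the `problems` attribute with a warning;
#'   "abort": the first failure is an error carrying the participant id.
#' @return tibble (class `lifeage_scores`) with id/age/timepoint, band and
#'   per-factor year columns, `lifestyle_years`, per-domain year columns,
#'   `psychosocial_years`, `life_age`, `delta`. Attributes: `config_version`,
#'   `config_hash`, `norms_version`, `problems`.
#' @examples
#' neutral <- tibble::tibble(id = "p1", age = 37, bmi = 24, smoking = "ex",
#'   alcohol_units = 16, binge = FALSE, diet_score = 8, met_hours = 12,
#'   positive_mood = 30, negative_mood = 15, life_satisfaction = 24,
#'   stress = 16, sleep_hours = 7)
#' la_score(neutral)$delta # 0
#' @export
la_score <- function(data, config = la_config(), norms = la_norms(),
                     on_error = c("collect", "abort")) {
  on_error <- match.arg(on_error)
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  get_col <- function(nm, default = NA) {
    if (nm %in% names(data)) data[[nm]] else rep(default, n)
  }
  id <- as.character(get_col("id", default = NA_character_))
  id <- ifelse(is.na(id), as.character(seq_len(n)), id)

  if (n == 0) {
    out <- empty_scores()
    attr(out, "config_version") <- config$version
    attr(out, "config_hash") <- config$hash
    attr(out, "norms_version") <- norms$version
    attr(out, "problems") <- tibble::tibble(id = character(), problem = character())
    return(out)
  }

  data <- derive_item_scores(data, id, on_error)
  problems <- attr(data, "item_problems") %||% rep(NA_character_, n)

  age <- as.numeric(get_col2(data, "age", n))
  bmi <- as.numeric(get_col2(data, "bmi", n))
  height_m <- as.numeric(get_col2(data, "height_m", n))
  weight_kg <- as.numeric(get_col2(data, "weight_kg", n))
  bmi_derived <- weight_kg / height_m^2
  # raw BMI and height/weight never conflict: if both routes present, agree to 0.5
  conflict <- !is.na(bmi) & !is.na(bmi_derived) & abs(bmi - bmi_derived) > 0.5
  bmi_use <- ifelse(is.na(bmi), bmi_derived, bmi)

  smoking <- tolower(as.character(get_col2(data, "smoking", n)))
  smoking[smoking %in% c("ex-smoker", "former")] <- "ex"
  smoking[smoking %in% c("never smoked", "non-smoker", "nonsmoker")] <- "never"
  alcohol_units <- as.numeric(get_col2(data, "alcohol_units", n))
  binge <- as.logical(get_col2(data, "binge", n))
  binge[is.na(binge)] <- FALSE
  diet_score <- as.numeric(get_col2(data, "diet_score", n))

  mh <- as.numeric(get_col2(data, "met_hours", n))
  mod_min <- as.numeric(get_col2(data, "moderate_minutes", n))
  vig_min <- as.numeric(get_col2(data, "vigorous_minutes", n))
  mh_derived <- (ifelse(is.na(mod_min), 0, mod_min) * 4 +
                 ifelse(is.na(vig_min), 0, vig_min) * 8) / 60
  mh_derived[is.na(mod_min) & is.na(vig_min)] <- NA
  mh_use <- ifelse(is.na(mh), mh_derived, mh)

  pos <- as.numeric(get_col2(data, "positive_mood", n))
  neg <- as.numeric(get_col2(data, "negative_mood", n))
  cm <- as.numeric(get_col2(data, "combined_mood", n))
  cm <- ifelse(is.na(cm), pos - neg, cm)
  sat <- as.numeric(get_col2(data, "life_satisfaction", n))
  stress <- as.numeric(get_col2(data, "stress", n))
  sleep <- as.numeric(get_col2(data, "sleep_hours", n))

  add_problem <- function(problems, bad, msg) {
    ifelse(bad & is.na(problems), msg, problems)
  }
  problems <- add_problem(problems, is.na(age) | age <= 0, "age missing or non-positive")
  problems <- add_problem(problems, conflict, "bmi inconsistent with height/weight")
  problems <- add_problem(problems, is.na(bmi_use) | bmi_use <= 0,
                          "BMI missing: supply bmi or height_m and weight_kg")
  problems <- add_problem(problems, !smoking %in% c("never", "ex", "current"),
                          "unknown smoking category")
  problems <- add_problem(problems, is.na(alcohol_units) | alcohol_units < 0,
                          "alcohol_units missing or negative")
  problems <- add_problem(problems, is.na(diet_score) | diet_score < 0 | diet_score > 14,
                          "diet_score missing or outside [0, 14]")
  problems <- add_problem(problems, is.na(mh_use) | mh_use < 0,
                          "weekly activity missing (met_hours or minutes)")
  problems <- add_problem(problems, is.na(cm), "mood scores missing")
  problems <- add_problem(problems, is.na(sat), "life_satisfaction missing")
  problems <- add_problem(problems, is.na(stress), "stress missing")
  problems <- add_problem(problems, is.na(sleep) | sleep < 0 | sleep > 24,
                          "sleep_hours missing or outside [0, 24]")

  ok <- is.na(problems)
  if (!all(ok) && on_error == "abort") {
    first <- which(!ok)[1]
    stop_input(sprintf("participant '%s': %s", id[first], problems[first]))
  }
  if (any(ok & (age < 30 | age > 60))) {
    warn(sprintf("%d participant(s) outside the 30-60 year target age range",
                 sum(ok & (age < 30 | age > 60))), class = "lifeage_warning_age")
  }

  out <- tibble::tibble(
    id = id, age = age,
    timepoint = as.character(get_col2(data, "timepoint", n)),
    sex = as.character(get_col2(data, "sex", n)),
    bmi = bmi_use, waist_cm = as.numeric(get_col2(data, "waist_cm", n)),
    bmi_band = NA_character_, smoking_band = NA_character_,
    alcohol_band = NA_character_, diet_band = NA_character_,
    activity_band = NA_character_,
    years_bmi = NA_real_, years_smoking = NA_real_, years_alcohol = NA_real_,
    years_diet = NA_real_, years_activity = NA_real_, lifestyle_years = NA_real_,
    combined_mood = cm,
    years_satisfaction = NA_real_, years_mood = NA_real_, years_stress = NA_real_,
    years_sleep = NA_real_, psychosocial_years = NA_real_,
    life_age = NA_real_, delta = NA_real_
  )

  if (any(ok)) {
    cats <- categorize_profile(bmi = bmi_use[ok], smoking = smoking[ok],
                               alcohol_units = alcohol_units[ok], binge = binge[ok],
                               diet_score = diet_score[ok], met_hours = mh_use[ok],
                               config = config)
    ls <- lifestyle_offset(cats, config)
    ps <- psychosocial_offset(sat[ok], cm[ok], stress[ok], sleep[ok], norms)
    wide_ls <- tidyr::pivot_wider(ls$breakdown, id_cols = "row",
                                  names_from = "factor", values_from = "years")
    wide_ps <- tidyr::pivot_wider(ps$breakdown, id_cols = "row",
                                  names_from = "domain", values_from = "years")
    out$bmi_band[ok] <- cats$bmi
    out$smoking_band[ok] <- cats$smoking
    out$alcohol_band[ok] <- cats$alcohol
    out$diet_band[ok] <- cats$diet
    out$activity_band[ok] <- cats$activity
    out$years_bmi[ok] <- wide_ls$bmi
    out$years_smoking[ok] <- wide_ls$smoking
    out$years_alcohol[ok] <- wide_ls$alcohol
    out$years_diet[ok] <- wide_ls$diet
    out$years_activity[ok] <- wide_ls$activity
    out$lifestyle_years[ok] <- ls$total
    out$years_satisfaction[ok] <- wide_ps$life_satisfaction
    out$years_mood[ok] <- wide_ps$mood
    out$years_stress[ok] <- wide_ps$stress
    out$years_sleep[ok] <- wide_ps$sleep
    out$psychosocial_years[ok] <- ps$total
    out$delta[ok] <- ls$total + ps$total
    out$life_age[ok] <- age[ok] + out$delta[ok]
    stopifnot(all(out$delta[ok] == out$lifestyle_years[ok] + out$psychosocial_years[ok]))
  }

  if (!all(ok)) {
    warn(sprintf("%d row(s) failed validation and were scored as NA; see attr(x, 'problems')",
                 sum(!ok)), class = "lifeage_warning_rows")
  }
  class(out) <- c("lifeage_scores", class(out))
  attr(out, "config_version") <- config$version
  attr(out, "config_hash") <- config$hash
  attr(out, "norms_version") <- norms$version
  attr(out, "problems") <- tibble::tibble(id = id[!ok], problem = problems[!ok])
  out
}

#' @rdname la_score
#' @param profiles for `compute_cohort()`, a data frame of participant
#'   records (alias of `la_score()` with collected per-row failures).
#' @export
compute_cohort <- function(profiles, config = la_config(), norms = la_norms()) {
  la_score(profiles, config, norms, on_error = "collect")
}

get_col2 <- function(data, nm, n) if (nm %in% names(data)) data[[nm]] else rep(NA, n)

empty_scores <- function() {
  out <- tibble::tibble(
    id = character(), age = numeric(), timepoint = character(), sex = character(),
    bmi = numeric(), waist_cm = numeric(), bmi_band = character(),
    smoking_band = character(), alcohol_band = character(), diet_band = character(),
    activity_band = character(), years_bmi = numeric(), years_smoking = numeric(),
    years_alcohol = numeric(), years_diet = numeric(), years_activity = numeric(),
    lifestyle_years = numeric(), combined_mood = numeric(),
    years_satisfaction = numeric(), years_mood = numeric(), years_stress = numeric(),
    years_sleep = numeric(), psychosocial_years = numeric(),
    life_age = numeric(), delta = numeric())
  class(out) <- c("lifeage_scores", class(out))
  out
}

# derive questionnaire scores from raw item columns, enforcing agreement
# with any precomputed score column; per-row problems collected, not fatal
derive_item_scores <- function(data, id, on_error) {
  n <- nrow(data)
  problems <- rep(NA_character_, n)
  note <- function(bad, msg) {
    problems <<- ifelse(bad & is.na(problems), msg, problems)
  }
  item_block <- function(prefix, k) {
    cols <- paste0(prefix, seq_len(k))
    if (!all(cols %in% names(data))) return(NULL)
    as.matrix(data[cols])
  }
  reconcile <- function(derived, score_col, label) {
    if (score_col %in% names(data)) {
      given <- as.numeric(data[[score_col]])
      mismatch <- !is.na(given) & !is.na(derived) & abs(given - derived) > 1e-8
      note(mismatch, sprintf("%s items disagree with precomputed %s", label, score_col))
      data[[score_col]] <<- ifelse(is.na(given), derived, given)
    } else {
      data[[score_col]] <<- derived
    }
  }

  diet <- item_block("diet_item_", 14)
  if (!is.null(diet)) {
    storage.mode(diet) <- "numeric"
    note(rowSums(is.na(diet)) > 0 |
           rowSums(matrix(!(diet %in% c(0, 1)), nrow = nrow(diet))) > 0,
         "diet items must be 14 definite yes/no values")
    reconcile(rowSums(diet), "diet_score", "diet")
  }
  pos <- item_block("pos_mood_item_", 10)
  if (!is.null(pos)) {
    note(rowSums(is.na(pos) | pos < 1 | pos > 5) > 0, "positive mood items outside 1-5")
    reconcile(rowSums(pos), "positive_mood", "positive mood")
  }
  neg <- item_block("neg_mood_item_", 10)
  if (!is.null(neg)) {
    note(rowSums(is.na(neg) | neg < 1 | neg > 5) > 0, "negative mood items outside 1-5")
    reconcile(rowSums(neg), "negative_mood", "negative mood")
  }
  sat <- item_block("satisfaction_item_", 5)
  if (!is.null(sat)) {
    note(rowSums(is.na(sat) | sat < 1 | sat > 7) > 0, "satisfaction items outside 1-7")
    reconcile(rowSums(sat), "life_satisfaction", "life satisfaction")
  }
  st <- item_block("stress_item_", 10)
  if (!is.null(st)) {
    note(rowSums(is.na(st) | st < 0 | st > 4) > 0, "stress items outside 0-4")
    rev_idx <- c(4, 5, 7, 8)
    st[, rev_idx] <- 4 - st[, rev_idx]
    reconcile(rowSums(st), "stress", "perceived stress")
  }
  attr(data, "item_problems") <- problems
  data
}

#' Life Age for a single participant
#'
#' Scores one participant and returns the decomposed result: chronological
#' age, lifestyle years, psychosocial years, Life Age, and the delta
#' (Life Age minus chronological age — the quantity reported in cohort
#' summaries), plus per-factor and per-domain breakdowns and the
#' configuration provenance. Any component failure is an error carrying
#' the participant id.
#'
#' @param profile named list or one-row data frame with the fields
#'   documented in [la_score()].
#' @inheritParams la_score
#' @return A `lifeage_result` list.
#' @examples
#' p <- list(id = "p1", age = 37, bmi = 22, smoking = "never",
#'   alcohol_units = 5, binge = FALSE, diet_score = 12, met_hours = 25,
#'   positive_mood = 30, negative_mood = 15, life_satisfaction = 24,
#'   stress = 16, sleep_hours = 7)
#' compute_life_age(p)$delta # optimal lifestyle, neutral psychosocial: -6
#' @export
compute_life_age <- function(profile, config = la_config(), norms = la_norms()) {
  if (!is.data.frame(profile)) {
    profile <- tibble::as_tibble(profile[!vapply(profile, is.null, logical(1))])
  }
  if (nrow(profile) != 1) stop_input("compute_life_age scores exactly one participant")
  scores <- la_score(profile, config, norms, on_error = "abort")
  res <- structure(list(
    id = scores$id,
    chronological_age = scores$age,
    lifestyle_years = scores$lifestyle_years,
    psychosocial_years = scores$psychosocial_years,
    life_age = scores$life_age,
    delta = scores$delta,
    lifestyle_breakdown = tibble::tibble(
      factor = c("bmi", "smoking", "alcohol", "diet", "activity"),
      category = c(scores$bmi_band, scores$smoking_band, scores$alcohol_band,
                   scores$diet_band, scores$activity_band),
      years = c(scores$years_bmi, scores$years_smoking, scores$years_alcohol,
                scores$years_diet, scores$years_activity)),
    psychosocial_breakdown = tibble::tibble(
      domain = c("life_satisfaction", "mood", "stress", "sleep"),
      years = c(scores$years_satisfaction, scores$years_mood,
                scores$years_stress, scores$years_sleep)),
    config_version = config$version, config_hash = config$hash,
    norms_version = norms$version
  ), class = "lifeage_result")
  stopifnot(res$delta == res$lifestyle_years + res$psychosocial_years)
  res
}

#' @export
print.lifeage_result <- function(x, ...) {
  cat(sprintf("Life Age for participant '%s'\n", x$id))
  cat(sprintf("  chronological age : %.1f y\n", x$chronological_age))
  cat(sprintf("  lifestyle years   : %+.1f y\n", x$lifestyle_years))
  cat(sprintf("  psychosocial years: %+.1f y\n", x$psychosocial_years))
  cat(sprintf("  Life Age          : %.1f y  (delta %+.1f y)\n", x$life_age, x$delta))
  cat(sprintf("  config %s (%s), norms %s\n",
              x$config_version, x$config_hash, x$norms_version))
  invisible(x)
}
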