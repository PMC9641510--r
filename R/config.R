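#' Default lifestyle offset configuration
#'
#' The lifestyle component of Life Age assigns each participant a signed
#' year offset per modifiable factor (BMI band, smoking status, alcohol
#' band, Mediterranean-diet adherence band, physical-activity band) and
#' sums them. The shipped table is a calibration choice anchored to the
#' published extremes of the score: the optimal profile (BMI < 23,
#' never-smoker, no/low alcohol, optimal diet, high activity) totals
#' exactly -6 years and the worst profile (BMI >= 40, current smoker,
#' binge drinker, poor diet, sedentary) totals exactly +28 years. Each
#' factor has a reference category with offset 0. The per-factor values
#' are calibrated, not sourced from published relative risks; users with
#' published risks can supply them via `rr` plus a Gompertz slope and the
#' offsets are derived with [rr_to_years()].
#'
#' @param offsets named list, one named numeric vector of year offsets per
#'   factor (`bmi`, `smoking`, `alcohol`, `diet`, `activity`). Defaults to
#'   the shipped calibration table.
#' @param rr optional named list with the same shape holding relative risks
#'   of all-cause mortality instead of years; when supplied, offsets are
#'   derived as `log(rr)/gompertz_slope` and `offsets` is ignored.
#' @param gompertz_slope per-year log-hazard slope of adult all-cause
#'   mortality used to convert relative risks to years (default 0.0866/yr,
#'   a hazard doubling time of about 8 years).
#' @param thresholds banding thresholds: BMI cut points, the weekly alcohol
#'   unit boundary, diet-score bands, and activity bands in MET-hours/week.
#' @param version character tag embedded in every result for provenance.
#'
#' @return A `lifeage_config` list with elements `offsets`, `thresholds`,
#'   `gompertz_slope`, `version`, and `hash` (content fingerprint).
#' @examples
#' cfg <- la_config()
#' sum(vapply(cfg$offsets, min, numeric(1))) # -6, the optimal profile
#' @export
la_config <- function(offsets = NULL, rr = NULL, gompertz_slope = 0.0866,
                      thresholds = NULL, version = NULL) {
  default_offsets <- list(
    bmi      = c("<23" = -1, "23-24.9" = 0, "25-29.9" = 2, "30-39.9" = 4, ">=40" = 8),
    smoking  = c(never = -2, ex = 0, current = 8),
    alcohol  = c(none_low = -1, moderate = 0, binge = 4),
    diet     = c(optimal = -1, average = 0, poor = 4),
    activity = c(high = -1, moderate = 0, low = 2, sedentary = 4)
  )
  default_thresholds <- list(
    bmi_breaks = c(23, 25, 30, 40),
    alcohol_units_low = 14,      # < 14 units/week = no/low
    diet_optimal_min = 10,       # PREDIMED score >= 10 optimal, <= 6 poor
    diet_poor_max = 6,
    activity_high_min = 20,      # MET-hours/week
    activity_moderate_min = 10,  # 150 min moderate at 4 MET = 10 MET-h
    activity_low_min = 1
  )
  custom <- !is.null(offsets) || !is.null(rr)
  if (!is.null(rr)) {
    if (!(is.numeric(gompertz_slope) && length(gompertz_slope) == 1 && gompertz_slope > 0)) {
      stop_config("gompertz_slope must be a single positive number")
    }
    offsets <- lapply(rr, rr_to_years, slope = gompertz_slope)
  }
  offsets <- offsets %||% default_offsets
  thresholds <- utils::modifyList(default_thresholds, thresholds %||% list())
  version <- version %||% (if (custom) "user" else "default-1.0")

  cfg <- structure(
    list(offsets = offsets, thresholds = thresholds,
         gompertz_slope = gompertz_slope, version = version),
    class = "lifeage_config")
  cfg$hash <- config_hash(cfg)
  validate_config(cfg)
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(cfg[c("offsets", "thresholds", "gompertz_slope", "version")],
                         auto_unbox = TRUE, digits = NA))
}

validate_config <- function(cfg) {
  needed <- c("bmi", "smoking", "alcohol", "diet", "activity")
  missing_factors <- setdiff(needed, names(cfg$offsets))
  if (length(missing_factors)) {
    stop_config(paste0("offset table missing factor(s): ",
                       paste(missing_factors, collapse = ", ")))
  }
  for (f in needed) {
    v <- cfg$offsets[[f]]
    if (!is.numeric(v) || is.null(names(v)) || any(!nzchar(names(v))) || anyNA(v)) {
      stop_config(sprintf("offsets for factor '%s' must be a fully named numeric vector", f))
    }
    if (!any(abs(v) < 1e-12)) {
      stop_config(sprintf("factor '%s' has no reference category with offset 0", f))
    }
  }
  best <- sum(vapply(cfg$offsets[needed], min, numeric(1)))
  worst <- sum(vapply(cfg$offsets[needed], max, numeric(1)))
  if (identical(cfg$version, "default-1.0")) {
    if (abs(best - (-6)) > 1e-9 || abs(worst - 28) > 1e-9) {
      stop_config(sprintf(
        "default table extremes must sum to -6 and +28 years, got %g and %g", best, worst))
    }
  } else if (abs(best - (-6)) > 1e-9 || abs(worst - 28) > 1e-9) {
    warn(sprintf(
      "user offset table extremes sum to %g and %g years (shipped calibration is -6/+28); extreme-sum check skipped",
      best, worst), class = "lifeage_warning_config")
  }
  cfg
}

#' Default psychosocial population norms
#'
#' The psychosocial component converts life satisfaction, combined mood
#' (positive minus negative affect), perceived stress, and sleep into
#' years by distance from a population norm, each domain clipped to
#' \[-2, +2\] years. The slope is 1 year per SD of distance by default
#' (per-domain `years_per_sd` is configurable); sleep is mapped by
#' absolute deviation from an optimum of 7 h/night (U-shaped risk), never
#' below 0 years. Shipped norm means/SDs are documented placeholders to be
#' replaced with a reference population when one is available.
#'
#' @param life_satisfaction,mood,stress lists with `mean`, `sd`,
#'   `direction` (+1 higher-is-better, -1 higher-is-worse) and
#'   `years_per_sd`.
#' @param sleep list with `optimum_hours` and `years_per_hour`.
#' @param version character provenance tag.
#' @return A `lifeage_norms` list.
#' @examples
#' domain_years(30.6, "life_satisfaction", la_norms()) # healthier than norm -> negative
#' @export
la_norms <- function(life_satisfaction = list(mean = 24, sd = 6, direction = 1, years_per_sd = 1),
                     mood = list(mean = 15, sd = 10, direction = 1, years_per_sd = 1),
                     stress = list(mean = 16, sd = 7, direction = -1, years_per_sd = 1),
                     sleep = list(optimum_hours = 7, years_per_hour = 1),
                     version = "default-1.0") {
  norms <- structure(
    list(life_satisfaction = life_satisfaction, mood = mood, stress = stress,
         sleep = sleep, version = version),
    class = "lifeage_norms")
  for (d in c("life_satisfaction", "mood", "stress")) {
    nd <- norms[[d]]
    if (!is.numeric(nd$sd) || nd$sd <= 0) {
      stop_config(sprintf("norm SD for domain '%s' must be > 0", d))
    }
    if (!is.numeric(nd$years_per_sd) || nd$years_per_sd <= 0) {
      stop_config(sprintf("years_per_sd for domain '%s' must be > 0", d))
    }
    if (!nd$direction %in% c(-1, 1)) {
      stop_config(sprintf("direction for domain '%s' must be +1 or -1", d))
    }
  }
  norms$hash <- fnv1a(jsonlite::toJSON(unclass(norms), auto_unbox = TRUE, digits = NA))
  norms
}

#' Load lifestyle offsets and psychosocial norms from a YAML or JSON file
#'
#' The file may contain top-level keys `offsets`, `rr`, `gompertz_slope`,
#' `thresholds`, `norms`, and `version`; anything omitted falls back to
#' the shipped defaults. The assembled configuration is validated against
#' all structural invariants; the -6/+28 extreme-sum check applies to the
#' shipped default table and is relaxed to a warning for user overrides.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `config` ([la_config()]) and `norms`
#'   ([la_norms()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  offsets <- if (!is.null(raw$offsets)) lapply(raw$offsets, unlist)
  rr <- if (!is.null(raw$rr)) lapply(raw$rr, unlist)
  cfg <- la_config(offsets = offsets, rr = rr,
                   gompertz_slope = raw$gompertz_slope %||% 0.0866,
                   thresholds = raw$thresholds,
                   version = raw$version %||% if (is.null(offsets) && is.null(rr)) NULL else "user")
  norms_args <- raw$norms %||% list()
  norms <- do.call(la_norms, norms_args)
  list(config = cfg, norms = norms)
}

#' @export
print.lifeage_config <- function(x, ...) {
  cat(sprintf("<lifeage_config %s  hash %s  gompertz slope %g/yr>\n",
              x$version, x$hash, x$gompertz_slope))
  for (f in names(x$offsets)) {
    cat(sprintf("  %-9s %s\n", f,
                paste(sprintf("%s=%+g", names(x$offsets[[f]]), x$offsets[[f]]), collapse = " ")))
  }
  invisible(x)
}
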