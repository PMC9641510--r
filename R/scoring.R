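#' Score the 14-item Mediterranean diet questionnaire
#'
#' One point per PREDIMED criterion met; the total (0-14) is banded into
#' low adherence (< 7 per the trial definition; a score of exactly 7,
#' which the banding labels leave unassigned, is classed as low so that
#' high always means >= 8) and high adherence (>= 8).
#'
#' @param items logical (or 0/1) vector of exactly 14 criterion outcomes.
#' @return list with `score` (integer 0-14) and `band` ("low" or "high").
#' @examples
#' score_mediterranean_diet(rep(TRUE, 14))
#' score_mediterranean_diet(c(rep(TRUE, 9), rep(FALSE, 5)))$band # "high"
#' @export
score_mediterranean_diet <- function(items) {
  if (length(items) != 14) {
    stop_input(sprintf("the Mediterranean diet score requires exactly 14 items, got %d",
                       length(items)))
  }
  if (anyNA(items)) {
    stop_input(sprintf("diet item %d is missing; each criterion must be a definite yes/no",
                       which(is.na(items))[1]))
  }
  if (is.numeric(items) && !all(items %in% c(0, 1))) {
    stop_range("diet items must be logical or 0/1")
  }
  score <- as.integer(sum(as.logical(items)))
  list(score = score, band = diet_adherence_band(score))
}

#' @rdname score_mediterranean_diet
#' @param score integer diet score 0-14.
#' @export
diet_adherence_band <- function(score) {
  if (any(score < 0 | score > 14, na.rm = TRUE)) stop_range("diet score must lie in [0, 14]")
  ifelse(score <= 7, "low", "high")
}

#' Score positive and negative affect subscales
#'
#' Ten items per subscale, each rated 1-5; subscale scores are plain sums
#' (range 10-50 each). Positive items cover states such as feeling proud,
#' alert, inspired; negative items irritability, nervousness, distress.
#'
#' @param positive_items,negative_items integer ratings, 10 each, in 1-5.
#' @return list with `positive` and `negative` sums.
#' @export
score_mood <- function(positive_items, negative_items) {
  p <- check_items(positive_items, 10, 1, 5, "positive mood")
  n <- check_items(negative_items, 10, 1, 5, "negative mood")
  list(positive = sum(p), negative = sum(n))
}

#' Combined mood score
#'
#' The single mood analysis variable: positive affect plus negative affect
#' times -1, i.e. `positive - negative`, ranging over \[-40, +40\] for
#' 10-item 1-5 subscales. Vectorized; missing subscales are an error, not
#' imputed.
#'
#' @param positive,negative subscale sums.
#' @return numeric combined mood.
#' @examples
#' combined_mood(35.7, 17) # 18.7
#' @export
combined_mood <- function(positive, negative) {
  if (length(positive) != length(negative)) {
    stop_input("positive and negative mood scores must have equal length")
  }
  if (anyNA(positive) || anyNA(negative)) {
    stop_input("combined mood requires both subscale scores; missing values are not imputed")
  }
  positive + (negative * -1)
}

#' Score the 5-item life-satisfaction scale
#'
#' Five items rated 1-7; the total is the plain sum, 5-35. A 5-item, 1-7
#' response format is adopted because it is the scale on which the
#' cohort's printed satisfaction summaries (mean near 30, SD near 6) live.
#'
#' @param items integer ratings, 5 items in 1-7.
#' @return integer sum 5-35.
#' @export
score_life_satisfaction <- function(items) {
  sum(check_items(items, 5, 1, 7, "life satisfaction"))
}

#' Score the 10-item perceived stress scale
#'
#' Ten items rated 0-4 with the positively worded items (4, 5, 7, 8 by
#' default) reverse-coded as `4 - rating`; the total runs 0-40, higher
#' meaning more stress.
#'
#' @param items integer ratings, 10 items in 0-4.
#' @param reverse_items indices of reverse-coded items.
#' @return integer sum 0-40.
#' @export
score_perceived_stress <- function(items, reverse_items = c(4, 5, 7, 8)) {
  x <- check_items(items, 10, 0, 4, "perceived stress")
  x[reverse_items] <- 4 - x[reverse_items]
  sum(x)
}

#' Weekly physical activity in MET-hours
#'
#' Harmonizes activity reporting: MET-hours/week given directly pass
#' through; otherwise minutes of moderate and vigorous activity are
#' weighted by MET intensity (defaults 4.0 and 8.0 MET) and converted to
#' hours. If both a direct value and minutes are supplied they must agree.
#'
#' @param moderate_minutes,vigorous_minutes minutes per week, >= 0.
#' @param met_hours_direct optional MET-hours/week, passed through.
#' @param met_moderate,met_vigorous MET intensities of the two classes.
#' @return numeric MET-hours/week (vectorized).
#' @examples
#' met_hours(150, 0) # 10 MET-hours
#' @export
met_hours <- function(moderate_minutes = NULL, vigorous_minutes = NULL,
                      met_hours_direct = NULL,
                      met_moderate = 4.0, met_vigorous = 8.0) {
  have_minutes <- !is.null(moderate_minutes) || !is.null(vigorous_minutes)
  if (is.null(met_hours_direct) && !have_minutes) {
    stop_input("provide weekly activity minutes or MET-hours directly")
  }
  if (have_minutes) {
    moderate_minutes <- moderate_minutes %||% rep(0, length(vigorous_minutes))
    vigorous_minutes <- vigorous_minutes %||% rep(0, length(moderate_minutes))
    if (any(moderate_minutes < 0 | vigorous_minutes < 0, na.rm = TRUE)) {
      stop_range("activity minutes must be non-negative")
    }
    derived <- (moderate_minutes * met_moderate + vigorous_minutes * met_vigorous) / 60
  }
  if (!is.null(met_hours_direct)) {
    if (any(met_hours_direct < 0, na.rm = TRUE)) stop_range("MET-hours must be non-negative")
    if (have_minutes) {
      both <- !is.na(met_hours_direct) & !is.na(derived)
      if (any(abs(met_hours_direct[both] - derived[both]) > 0.5)) {
        stop_input("direct MET-hours and activity minutes are inconsistent")
      }
    }
    return(met_hours_direct)
  }
  derived
}

#' Does a weekly activity report meet the aerobic guideline?
#'
#' TRUE when moderate activity reaches 150 min/week or vigorous activity
#' reaches 75 min/week. An optional equivalent-minutes blend
#' (moderate + 2 x vigorous >= 150) is available but off by default.
#'
#' @param moderate_minutes,vigorous_minutes minutes per week.
#' @param equivalent_minutes use the blended rule instead of the OR rule.
#' @return logical (vectorized).
#' @examples
#' meets_activity_guideline(150, 0)
#' meets_activity_guideline(0, 75)
#' @export
meets_activity_guideline <- function(moderate_minutes, vigorous_minutes,
                                     equivalent_minutes = FALSE) {
  if (any(moderate_minutes < 0 | vigorous_minutes < 0, na.rm = TRUE)) {
    stop_range("activity minutes must be non-negative")
  }
  if (equivalent_minutes) {
    moderate_minutes + 2 * vigorous_minutes >= 150
  } else {
    moderate_minutes >= 150 | vigorous_minutes >= 75
  }
}
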