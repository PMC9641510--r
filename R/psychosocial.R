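#' Years offset for one psychosocial domain
#'
#' Maps a questionnaire score to years by its standardized distance from
#' the population norm, signed so that healthier-than-norm scores yield
#' negative years (a "younger" Life Age), and clipped to \[-2, +2\]:
#' `clip(-direction * (score - mean)/sd * years_per_sd, -2, 2)`.
#'
#' @param score questionnaire score (vectorized).
#' @param domain "life_satisfaction", "mood", or "stress".
#' @param norms a [la_norms()].
#' @return years in \[-2, 2\].
#' @examples
#' domain_years(24, "life_satisfaction") # at norm -> 0
#' @export
domain_years <- function(score, domain, norms = la_norms()) {
  nd <- norms[[domain]]
  if (is.null(nd) || is.null(nd$mean)) {
    stop_config(sprintf("no norms defined for domain '%s'", domain))
  }
  if (!is.numeric(nd$sd) || nd$sd <= 0) {
    stop_config(sprintf("norm SD for domain '%s' must be > 0", domain))
  }
  clip(-nd$direction * (score - nd$mean) / nd$sd * nd$years_per_sd, -2, 2)
}

#' Years offset for sleep duration
#'
#' Both short and long sleep carry excess risk, so sleep is mapped by
#' absolute deviation from the optimum (7 h/night by default):
#' `min(2, |hours - optimum| * years_per_hour)`. Never negative — optimal
#' sleep contributes 0 years, it earns no credit.
#'
#' @param hours sleep hours per night (vectorized).
#' @param norms a [la_norms()].
#' @return years in \[0, 2\].
#' @examples
#' sleep_years(6.5) # 0.5
#' @export
sleep_years <- function(hours, norms = la_norms()) {
  if (any(hours < 0 | hours > 24, na.rm = TRUE)) {
    stop_range("sleep hours must lie in [0, 24]")
  }
  pmin(2, abs(hours - norms$sleep$optimum_hours) * norms$sleep$years_per_hour)
}

#' Total psychosocial well-being offset
#'
#' Sums the four domain offsets (life satisfaction, combined mood,
#' perceived stress, sleep), each individually clipped to \[-2, +2\]
#' (sleep to \[0, +2\]); under defaults the total spans \[-6, +8\]. All
#' four inputs are required — there are no partial totals.
#'
#' @param life_satisfaction,mood,stress,sleep_hours domain inputs
#'   (vectorized; `mood` is the combined positive-minus-negative score).
#' @param norms a [la_norms()].
#' @return list with `total` (years per profile) and `breakdown` (tibble:
#'   row, domain, years).
#' @examples
#' psychosocial_offset(24, 15, 16, 7)$total # all at norm/optimum -> 0
#' @export
psychosocial_offset <- function(life_satisfaction, mood, stress, sleep_hours,
                                norms = la_norms()) {
  inputs <- list(life_satisfaction = life_satisfaction, mood = mood,
                 stress = stress, sleep = sleep_hours)
  missing_domains <- names(inputs)[vapply(inputs, function(x) is.null(x) || anyNA(x), logical(1))]
  if (length(missing_domains)) {
    stop_input(paste0("missing psychosocial domain(s): ",
                      paste(missing_domains, collapse = ", "),
                      "; no partial totals are computed"))
  }
  years <- list(
    life_satisfaction = domain_years(life_satisfaction, "life_satisfaction", norms),
    mood = domain_years(mood, "mood", norms),
    stress = domain_years(stress, "stress", norms),
    sleep = sleep_years(sleep_hours, norms)
  )
  n <- length(years$life_satisfaction)
  breakdown <- tibble::tibble(
    row = rep(seq_len(n), times = 4),
    domain = rep(names(years), each = n),
    years = unlist(years, use.names = FALSE)
  ) |> dplyr::arrange(.data$row)
  list(total = Reduce(`+`, years), breakdown = breakdown)
}
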