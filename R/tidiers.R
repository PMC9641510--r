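#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-variable test results of an evaluation
#'
#' @param x a `lifeage_eval` from [evaluate_pre_post()].
#' @param ... unused.
#' @return tibble with one row per tested variable: `variable`, `method`,
#'   `n`, `estimate`, `statistic`, `p.value`, `significant`.
#' @method tidy lifeage_eval
#' @export
tidy.lifeage_eval <- function(x, ...) {
  tibble::as_tibble(x$tests)
}

#' One-row evaluation overview
#'
#' @inheritParams tidy.lifeage_eval
#' @return tibble: `n_enrolled`, `n_completers`, `completion`,
#'   `n_tests`, `n_significant`, `alpha`.
#' @method glance lifeage_eval
#' @export
glance.lifeage_eval <- function(x, ...) {
  tibble::tibble(
    n_enrolled = x$n_enrolled,
    n_completers = x$n_completers,
    completion = ifelse(x$n_enrolled > 0, x$n_completers / x$n_enrolled, NA_real_),
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$significant),
    alpha = x$alpha)
}

#' Tidy a single Life Age result into a long component table
#'
#' @param x a `lifeage_result` from [compute_life_age()].
#' @param ... unused.
#' @return tibble: `component` ("lifestyle"/"psychosocial"), `term`
#'   (factor or domain), `category` (lifestyle band or NA), `years`.
#' @method tidy lifeage_result
#' @export
tidy.lifeage_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$lifestyle_breakdown, component = "lifestyle",
                  term = .data$factor, .keep = "unused"),
    dplyr::mutate(x$psychosocial_breakdown, component = "psychosocial",
                  term = .data$domain, category = NA_character_, .keep = "unused")
  ) |>
    dplyr::select("component", "term", "category", "years")
}

#' One-row Life Age overview
#'
#' @inheritParams tidy.lifeage_result
#' @return tibble: `id`, `chronological_age`, `lifestyle_years`,
#'   `psychosocial_years`, `life_age`, `delta`.
#' @method glance lifeage_result
#' @export
glance.lifeage_result <- function(x, ...) {
  tibble::tibble(id = x$id, chronological_age = x$chronological_age,
                 lifestyle_years = x$lifestyle_years,
                 psychosocial_years = x$psychosocial_years,
                 life_age = x$life_age, delta = x$delta)
}
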