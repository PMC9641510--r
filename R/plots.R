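#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_col geom_line
#'   geom_point geom_vline geom_hline facet_wrap labs theme_minimal
#'   position_dodge coord_flip
#' @export
ggplot2::autoplot

#' Distribution of Life Age deltas across a scored cohort
#'
#' Histogram of `delta` (Life Age minus chronological age); negative
#' values mean a Life Age younger than the calendar age.
#'
#' @param object a `lifeage_scores` tibble from [la_score()].
#' @param binwidth histogram bin width in years.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lifeage_scores
#' @export
autoplot.lifeage_scores <- function(object, binwidth = 2, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$delta))
  ggplot(dat, aes(x = .data$delta)) +
    geom_histogram(binwidth = binwidth, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "Life Age delta (years)", y = "participants",
         title = "Life Age relative to chronological age") +
    theme_minimal()
}

#' Component breakdown of a single Life Age result
#'
#' Bar chart of the signed year contribution of every lifestyle factor
#' and psychosocial domain.
#'
#' @param object a `lifeage_result` from [compute_life_age()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lifeage_result
#' @export
autoplot.lifeage_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = stats::reorder(.data$term, .data$years), y = .data$years,
                  fill = .data$component)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    coord_flip() +
    labs(x = NULL, y = "years added (+) or removed (-)",
         title = sprintf("Life Age components: participant %s", object$id)) +
    theme_minimal()
}

#' Effect estimates of a pre/post evaluation
#'
#' Dot plot of the per-variable paired change estimates, marking which
#' reached significance at the evaluation's alpha.
#'
#' @param object a `lifeage_eval` from [evaluate_pre_post()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lifeage_eval
#' @export
autoplot.lifeage_eval <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = .data$estimate, y = stats::reorder(.data$variable, .data$estimate),
                  colour = .data$significant)) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    geom_point(size = 3) +
    labs(x = "paired change (follow-up minus baseline)", y = NULL,
         colour = sprintf("p <= %g", object$alpha),
         title = sprintf("Pre/post changes (%d completers of %d enrolled)",
                         object$n_completers, object$n_enrolled)) +
    theme_minimal()
}

#' Empirical power curve of the paired design
#'
#' Runs [simulate_power()] over a grid of pair counts and plots the
#' estimated power with the design target marked.
#'
#' @param n_grid integer vector of complete-pair counts.
#' @param delta,sd,alpha design parameters (see [simulate_power()]).
#' @param reps simulations per grid point.
#' @param seed integer seed.
#' @param target horizontal reference line (default 0.90).
#' @return a ggplot; the data are in its `data` slot.
#' @export
plot_power_curve <- function(n_grid = seq(8, 40, by = 4), delta = 0.5, sd = 0.75,
                             alpha = 0.05, reps = 2000, seed = 1, target = 0.90) {
  dat <- purrr::map_dfr(seq_along(n_grid), function(i) {
    simulate_power(n_grid[i], delta, sd, alpha, reps, seed = seed + i)
  })
  ggplot(dat, aes(x = .data$n, y = .data$power)) +
    geom_hline(yintercept = target, linetype = "dashed") +
    geom_line() + geom_point() +
    labs(x = "complete pairs", y = "empirical power",
         title = sprintf("Paired t test power (delta %g, SD %g, alpha %g)",
                         delta, sd, alpha)) +
    theme_minimal()
}
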