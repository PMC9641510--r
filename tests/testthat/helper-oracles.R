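# Independent oracles and shared fixtures, built in code.

# Brute-force two-sided exact p for the Wilcoxon signed-rank test:
# enumerate every sign assignment explicitly via expand.grid (independent
# of the convolution used by the package) and count assignments at least
# as far from the null center of W+ as the observed statistic.
wilcoxon_enumeration_p <- function(pre, post) {
  d <- post - pre
  d <- d[!is.na(d) & d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  center <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% r)
  mean(abs(w_all - center) >= abs(w_obs - center) - 1e-9)
}

# A profile sitting at every reference category and every norm: delta 0.
neutral_profile <- function(id = "p1", age = 37) {
  list(id = id, age = age, bmi = 24, smoking = "ex", alcohol_units = 16,
       binge = FALSE, diet_score = 8, met_hours = 12, positive_mood = 30,
       negative_mood = 15, life_satisfaction = 24, stress = 16, sleep_hours = 7)
}

neutral_cohort <- function(n, timepoint = "baseline") {
  tibble::tibble(id = sprintf("n%02d", seq_len(n)), age = 37, bmi = 24,
                 smoking = "ex", alcohol_units = 16, binge = FALSE,
                 diet_score = 8, met_hours = 12, positive_mood = 30,
                 negative_mood = 15, life_satisfaction = 24, stress = 16,
                 sleep_hours = 7, timepoint = timepoint)
}
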