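#' @importFrom rlang %||% abort warn .data
#' @importFrom stats qnorm pt pnorm sd median quantile rnorm rgamma rlnorm rbinom runif
NULL

# round half away from zero (display convention for percentages: 62.5 -> 63)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a 32-bit over a character scalar; content fingerprint for configs
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # XOR into the low byte only (b < 256); h itself can exceed 2^31 so
    # bitwXor cannot be applied to it directly
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by 16777619 without overflow, via split arithmetic
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # render as hex; h < 2^32 so split into two 16-bit halves for sprintf
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_input <- function(msg, ...) abort(msg, class = "lifeage_error_input", ...)
stop_range <- function(msg, ...) abort(msg, class = "lifeage_error_range", ...)
stop_config <- function(msg, ...) abort(msg, class = "lifeage_error_config", ...)

is_wholeish <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# check a rating vector: length, integer values within [lo, hi]; names the
# first offending item so users can fix the questionnaire row
check_items <- function(items, n, lo, hi, what) {
  if (length(items) != n) {
    stop_input(sprintf("%s requires exactly %d items, got %d", what, n, length(items)))
  }
  if (anyNA(items)) {
    stop_input(sprintf("%s item %d is missing; items are never imputed",
                       what, which(is.na(items))[1]))
  }
  bad <- which(items < lo | items > hi | !is_wholeish(items))
  if (length(bad)) {
    stop_range(sprintf("%s item %d has value %s outside the %d-%d integer scale",
                       what, bad[1], format(items[bad[1]]), lo, hi))
  }
  invisible(as.numeric(items))
}
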