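# Shared validation helpers. Validation failures signal condition class
# "ivmseq_validation_error" so callers (and the pipeline gate) can tell
# bad input apart from a failed contamination check.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("ivmseq_validation_error", "error")))
}

stop_contamination <- function(...) {
  stop(errorCondition(paste0(...), class = c("ivmseq_contamination_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) != 1L) || anyNA(x)) {
    stop_validation("'", name, "' must be a non-missing number")
  }
  if (any(x < lower) || any(x > upper)) {
    stop_validation("'", name, "' must lie in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_validation("'", name, "' must be an integer")
  invisible(as.integer(x))
}

# Sample skewness (g1, the method-of-moments estimator).
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}
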