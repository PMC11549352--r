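# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("agequant_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_invalid(...)
  invisible(TRUE)
}

# Trapezoidal integral of y over x; x must be sorted increasing.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Centred moving average with edge truncation (used for trace smoothing).
moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  half <- window %/% 2L
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(y[lo:hi])
  }
  out
}

# Standard error of the mean, NA-dropping.
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
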