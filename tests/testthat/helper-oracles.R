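# Independent brute-force oracles used to check package implementations.
# These deliberately share no code with R/.

# Poisson CFU log-likelihood, maximized by dense search + optimize().
oracle_cfu_grid <- function(counts, dilutions, volumes, upper = NULL) {
  exposure <- volumes / dilutions
  loglik <- function(lam) sum(stats::dpois(counts, lam * exposure, log = TRUE))
  if (is.null(upper)) upper <- 10 * (sum(counts) + 1) / sum(exposure)
  grid <- seq(upper / 1e5, upper, length.out = 20000)
  lam0 <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  stats::optimize(loglik, c(max(lam0 - upper / 1e4, 1e-12),
                            lam0 + upper / 1e4), maximum = TRUE)$maximum
}

# Brute-force two-group log-rank statistic (hypergeometric variance,
# censored records leave the risk set after their time).
oracle_logrank <- function(time, event, group) {
  gA <- levels(factor(group))[1]
  ev_times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == gA)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == gA)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Step-by-step Kaplan-Meier product-limit estimate; returns a function of t.
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n <- sum(time >= t)
    d <- sum(event & time == t)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  list(time = ev_times, surv = surv)
}

oracle_km_median <- function(time, event) {
  km <- oracle_km(time, event)
  i <- which(km$surv <= 0.5)
  if (length(i) == 0) NA_real_ else km$time[i[1]]
}

# Brute-force presence filter: per-strain detection counting.
oracle_presence <- function(mat, design, min_reps = 2) {
  keep <- vapply(seq_len(nrow(mat)), function(i) {
    any(vapply(unique(design$strain), function(s) {
      cols <- design$sample[design$strain == s]
      sum(!is.na(mat[i, cols])) >= min_reps
    }, logical(1)))
  }, logical(1))
  rownames(mat)[keep]
}

# Brute-force consensus hit calling by sign enumeration.
oracle_consensus <- function(gis_values, cutoff, min_repeats) {
  g <- gis_values[!is.na(gis_values)]
  neg <- sum(g <= -cutoff); pos <- sum(g >= cutoff)
  if (neg >= min_repeats && pos >= min_repeats) return("none")
  if (neg >= min_repeats) return("negative")
  if (pos >= min_repeats) return("positive")
  "none"
}
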