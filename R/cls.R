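#' Poisson maximum-likelihood CFU estimation from serial-dilution plating
#'
#' Viable-cell density in a chronological-lifespan (CLS) assay is measured by
#' plating a dilution series and counting colonies. With colony counts
#' \eqn{y_j} observed on plates with dilution factors \eqn{d_j} and plated
#' volumes \eqn{v_j} (mL), the counts are modelled as independent
#' \eqn{y_j \sim \mathrm{Poisson}(\lambda v_j / d_j)} where \eqn{\lambda} is
#' the CFU concentration per mL of the undiluted culture. The unique MLE is
#' the closed form
#' \deqn{\hat\lambda = \sum_j y_j \Big/ \sum_j v_j / d_j}
#' over countable plates. The confidence interval is the exact (Garwood)
#' Poisson interval on the summed count, scaled by the total exposure
#' \eqn{\sum_j v_j/d_j}.
#'
#' Plates whose counts exceed \code{max_countable} (default 400) are treated
#' as uncountable lawns (merged colonies violate the count model) and are
#' excluded, as are plates with \code{countable = FALSE}.
#'
#' @param record data frame with columns \code{colony_count} (non-negative
#'   integer), \code{dilution_factor} (>= 1) and \code{plated_volume_ml}
#'   (> 0); optionally a logical \code{countable} column.
#' @param max_countable maximum colony count considered countable.
#' @param conf_level confidence level for the exact Poisson interval.
#' @return object of class \code{cfu_estimate}: list with
#'   \code{cfu_per_ml_hat}, \code{ci_low}, \code{ci_high},
#'   \code{n_plates_used}.
#' @examples
#' rec <- data.frame(colony_count = c(30, 3),
#'                   dilution_factor = c(1e3, 1e4),
#'                   plated_volume_ml = 0.1)
#' estimate_cfu_mle(rec)
#' @export
estimate_cfu_mle <- function(record, max_countable = 400, conf_level = 0.95) {
  assert_that(is.data.frame(record) && nrow(record) > 0,
              "record must be a non-empty data frame")
  need <- c("colony_count", "dilution_factor", "plated_volume_ml")
  assert_that(all(need %in% names(record)),
              "record must have columns: ", paste(need, collapse = ", "))
  assert_that(all(record$dilution_factor >= 1),
              "dilution_factor must be >= 1")
  assert_that(all(record$plated_volume_ml > 0),
              "plated_volume_ml must be positive")
  assert_that(all(record$colony_count >= 0) &&
                all(record$colony_count == round(record$colony_count)),
              "colony_count must be non-negative integers")

  countable <- record$colony_count <= max_countable
  if (!is.null(record$countable)) countable <- countable & record$countable
  if (!any(countable)) {
    stop_invalid("no countable plates (all counts > ", max_countable,
                 " or flagged uncountable)")
  }
  y <- record$colony_count[countable]
  exposure <- record$plated_volume_ml[countable] /
    record$dilution_factor[countable]
  E <- sum(exposure)
  assert_that(E > 0, "zero total exposure")

  total <- sum(y)
  alpha <- 1 - conf_level
  # Garwood exact interval on a Poisson total, via the gamma identity.
  lo <- if (total == 0) 0 else stats::qgamma(alpha / 2, total)
  hi <- stats::qgamma(1 - alpha / 2, total + 1)

  structure(list(cfu_per_ml_hat = total / E,
                 ci_low = lo / E,
                 ci_high = hi / E,
                 n_plates_used = sum(countable)),
            class = "cfu_estimate")
}

#' @export
print.cfu_estimate <- function(x, ...) {
  cat(sprintf("CFU estimate: %.4g /mL (95%% CI %.4g - %.4g; %d plates)\n",
              x$cfu_per_ml_hat, x$ci_low, x$ci_high, x$n_plates_used))
  invisible(x)
}

#' Relative-viability lifespan curve from per-timepoint CFU estimates
#'
#' Converts per-replicate CFU estimates into percentage viability relative to
#' Day 0 (defined as 100 percent survival; in the assay, Day 0 is the day the
#' culture reaches stable maximal density). Percentages are computed within
#' each biological replicate, then averaged across replicates, with the
#' standard error across replicates reported per timepoint.
#'
#' @param estimates data frame with columns \code{replicate},
#'   \code{timepoint_day} and \code{cfu_per_ml} (the per-replicate MLEs).
#' @param day0 the timepoint used as the 100 percent reference (default 0).
#' @return list with \code{per_replicate} (replicate, timepoint_day,
#'   percent_viability) and \code{curve} (timepoint_day, percent_viability
#'   mean, se, n_replicates).
#' @export
viability_curve <- function(estimates, day0 = 0) {
  need <- c("replicate", "timepoint_day", "cfu_per_ml")
  assert_that(is.data.frame(estimates) && all(need %in% names(estimates)),
              "estimates must have columns: ", paste(need, collapse = ", "))
  reps <- split(estimates, estimates$replicate)
  per_rep <- do.call(rbind, lapply(reps, function(df) {
    ref <- df$cfu_per_ml[df$timepoint_day == day0]
    assert_that(length(ref) == 1L,
                "each replicate needs exactly one Day ", day0, " estimate")
    assert_that(ref > 0, "Day ", day0,
                " estimate is zero for replicate ", df$replicate[1],
                ": viability ratio undefined")
    data.frame(replicate = df$replicate,
               timepoint_day = df$timepoint_day,
               percent_viability = 100 * df$cfu_per_ml / ref)
  }))
  rownames(per_rep) <- NULL

  days <- sort(unique(per_rep$timepoint_day))
  curve <- do.call(rbind, lapply(days, function(d) {
    p <- per_rep$percent_viability[per_rep$timepoint_day == d]
    data.frame(timepoint_day = d,
               percent_viability = mean(p),
               se = if (length(p) >= 2) stats::sd(p) / sqrt(length(p)) else 0,
               n_replicates = length(p))
  }))
  list(per_replicate = per_rep, curve = curve)
}
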