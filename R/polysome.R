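#' Segment a polysome absorbance trace into ribosomal regions
#'
#' A polysome profile is an A254 absorbance trace along a sucrose gradient,
#' resolving (in order) free ribosomal subunits (40S/60S), the 80S monosome,
#' and polysome peaks of increasing ribosome number. This function labels
#' those regions either from user-supplied boundaries or automatically:
#' the trace is smoothed with a moving average, local maxima above a
#' prominence threshold are found, the first \code{n_free_peaks} peaks are
#' grouped as the free-subunit region, the next peak is the monosome and
#' later peaks become \code{polysome_2}, \code{polysome_3}, ... Region
#' boundaries sit at inter-peak local minima. The baseline value is the
#' absorbance at the local minimum on the trailing side of the monosome
#' peak (traces are conventionally aligned at that valley).
#'
#' @param position,absorbance trace samples; positions strictly increasing,
#'   at least 100 points.
#' @param manual_boundaries optional data frame with \code{label},
#'   \code{start}, \code{end}; validated and adopted as-is (baseline still
#'   taken from the monosome trailing valley).
#' @param smooth_window moving-average window (points) for peak finding.
#' @param min_prominence minimum peak height above the neighbouring valleys,
#'   as a fraction of the trace's dynamic range.
#' @param n_free_peaks number of leading peaks forming the free-subunit
#'   cluster (1 when 40S/60S are unresolved, 2 when resolved).
#' @return list of class \code{peak_segmentation} with \code{regions}
#'   (data frame: label, start, end), \code{baseline_value}, \code{peaks}
#'   (positions of detected maxima).
#' @export
segment_trace <- function(position, absorbance, manual_boundaries = NULL,
                          smooth_window = 9, min_prominence = 0.05,
                          n_free_peaks = 1) {
  assert_that(length(position) == length(absorbance),
              "position and absorbance must have equal length")
  assert_that(length(position) >= 100, "trace needs >= 100 points")
  assert_that(all(diff(position) > 0), "positions must be strictly increasing")

  sm <- moving_average(absorbance, smooth_window)
  rng <- diff(range(sm))
  if (rng < .Machine$double.eps * 100) {
    stop_invalid("flat trace: no peaks to segment")
  }

  # Local maxima on the smoothed trace.
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                     sm[2:(n - 1)] >= sm[3:n], FALSE)
  peaks <- which(is_max)
  peaks <- peaks[sm[peaks] - min(sm) >= min_prominence * rng]
  # Merge neighbouring maxima not separated by a valley at least
  # min_prominence * range below the lower of the two: noise bumps on a
  # peak shoulder collapse into the taller peak.
  while (length(peaks) >= 2) {
    dropped <- FALSE
    for (k in seq_len(length(peaks) - 1)) {
      v <- min(sm[peaks[k]:peaks[k + 1]])
      if (min(sm[peaks[k]], sm[peaks[k + 1]]) - v < min_prominence * rng) {
        peaks <- peaks[-if (sm[peaks[k]] < sm[peaks[k + 1]]) k else k + 1]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  if (length(peaks) < 2 && is.null(manual_boundaries)) {
    stop_invalid("no monosome peak identifiable; supply manual_boundaries")
  }

  valley_between <- function(i1, i2) {
    seg <- i1:i2
    seg[which.min(sm[seg])]
  }
  # Noise-robust baseline: the trace level at the valley, estimated as the
  # median of all raw samples whose smoothed value sits at that level
  # (within 1% of the dynamic range). This pools the valley bottom with any
  # signal-free stretches at the same level, instead of trusting a single
  # noisy sample; stretches at other levels are excluded, so a valley that
  # rides above the tails still defines its own baseline.
  baseline_at <- function(i) {
    flat <- which(abs(sm - sm[i]) < 0.01 * rng)
    stats::median(absorbance[flat])
  }

  if (!is.null(manual_boundaries)) {
    mb <- manual_boundaries
    assert_that(all(c("label", "start", "end") %in% names(mb)),
                "manual boundaries need label, start, end")
    assert_that(all(mb$start < mb$end), "each region needs start < end")
    assert_that(sum(mb$label == "monosome") == 1,
                "exactly one monosome region required")
    o <- order(mb$start)
    mb <- mb[o, ]
    assert_that(all(utils::head(mb$end, -1) <= utils::tail(mb$start, -1) +
                      1e-9), "regions must not overlap")
    regions <- data.frame(label = mb$label, start = mb$start, end = mb$end)
    mono_end <- mb$end[mb$label == "monosome"]
    baseline <- baseline_at(which.min(abs(position - mono_end)))
    return(structure(list(regions = regions, baseline_value = baseline,
                          peaks = position[peaks]),
                     class = "peak_segmentation"))
  }

  n_free <- min(n_free_peaks, length(peaks) - 1)
  mono_idx <- n_free + 1
  assert_that(length(peaks) >= mono_idx,
              "no monosome peak identifiable; supply manual_boundaries")

  # Boundaries at inter-peak minima, with the trace ends as outer limits.
  cuts <- integer(0)
  for (k in seq_len(length(peaks) - 1)) {
    cuts <- c(cuts, valley_between(peaks[k], peaks[k + 1]))
  }
  # Merge the free-subunit cluster: drop cuts internal to it.
  if (n_free > 1) cuts <- cuts[-seq_len(n_free - 1)]
  # Baseline: valley on the trailing side of the monosome peak (computed
  # before trimming so the outer limits can reference it).
  mono_peak <- peaks[mono_idx]
  trail_end <- if (length(peaks) > mono_idx) peaks[mono_idx + 1] else n
  mono_valley <- valley_between(mono_peak, trail_end)
  baseline <- baseline_at(mono_valley)

  # Trim the outer limits to where the smoothed trace leaves the baseline:
  # open-ended regions would otherwise integrate clipped noise over long
  # signal-free stretches.
  thr <- sm[mono_valley] + 0.01 * rng
  first_i <- peaks[1]
  while (first_i > 1 && sm[first_i] >= thr) first_i <- first_i - 1L
  first_i <- max(1L, first_i - smooth_window)
  last_i <- peaks[length(peaks)]
  while (last_i < n && sm[last_i] >= thr) last_i <- last_i + 1L
  last_i <- min(n, last_i + smooth_window)
  bounds <- c(first_i, cuts, last_i)
  n_regions <- length(bounds) - 1
  labels <- c("free_subunits", "monosome",
              if (n_regions > 2) paste0("polysome_", seq_len(n_regions - 2) + 1))
  regions <- data.frame(label = labels,
                        start = position[utils::head(bounds, -1)],
                        end = position[utils::tail(bounds, -1)])
  structure(list(regions = regions, baseline_value = baseline,
                 peaks = position[peaks]),
            class = "peak_segmentation")
}

#' Integrate region areas and ribosome-content metrics
#'
#' Computes, per segmented region, the trapezoidal integral of the
#' baseline-subtracted absorbance (clipped below at zero). The
#' polysome:monosome ratio P/M is the summed polysome area divided by the
#' monosome area; ribosome content P+M is their sum. The free-subunit region
#' is excluded from both P and M.
#'
#' @param position,absorbance the trace.
#' @param segmentation a \code{peak_segmentation}.
#' @return list of class \code{ribosome_metrics}: \code{region_auc} (named),
#'   \code{monosome_auc}, \code{polysome_auc_total}, \code{pm_ratio}
#'   (NA when M = 0), \code{ribosome_content}.
#' @export
integrate_auc <- function(position, absorbance, segmentation) {
  assert_that(inherits(segmentation, "peak_segmentation"),
              "segmentation must come from segment_trace")
  base <- segmentation$baseline_value
  y <- pmax(absorbance - base, 0)
  regs <- segmentation$regions
  auc <- vapply(seq_len(nrow(regs)), function(i) {
    sel <- position >= regs$start[i] & position <= regs$end[i]
    trapz(position[sel], y[sel])
  }, numeric(1))
  names(auc) <- regs$label
  M <- sum(auc[regs$label == "monosome"])
  P <- sum(auc[startsWith(regs$label, "polysome")])
  structure(list(region_auc = auc,
                 monosome_auc = M,
                 polysome_auc_total = P,
                 pm_ratio = if (M > 0) P / M else NA_real_,
                 ribosome_content = P + M),
            class = "ribosome_metrics")
}

#' Ribosome content relative to a control sample
#'
#' Ratio of total ribosome content (P+M) of a sample to that of a named
#' control (e.g. an empty-vector strain). Assumes equal lysate loading,
#' which the fractionation protocol enforces upstream by OD260
#' normalization.
#'
#' @param sample_metrics,control_metrics \code{ribosome_metrics} objects.
#' @return the ratio (P+M)_sample / (P+M)_control; NA when the control
#'   content is zero.
#' @export
relative_content <- function(sample_metrics, control_metrics) {
  assert_that(inherits(sample_metrics, "ribosome_metrics") &&
                inherits(control_metrics, "ribosome_metrics"),
              "inputs must be ribosome_metrics")
  if (control_metrics$ribosome_content <= 0) return(NA_real_)
  sample_metrics$ribosome_content / control_metrics$ribosome_content
}

#' Per-fraction mRNA distribution from qPCR Ct values
#'
#' Converts per-fraction qPCR threshold cycles into the percentage of an
#' mRNA in each gradient fraction: the Ct of each detected fraction is
#' subtracted from the maximum Ct (the least-abundant detected fraction),
#' the resulting delta-Ct is exponentiated (2^dCt) to a relative quantity,
#' undetected fractions contribute zero, and the quantities are normalised
#' to percentages summing to 100. The statistic is invariant to adding a
#' constant to all Ct values.
#'
#' @param ct numeric vector of per-fraction Ct values, NA = undetected.
#' @return percentage per fraction (same length as \code{ct}, summing
#'   to 100).
#' @export
fraction_distribution <- function(ct) {
  assert_that(is.numeric(ct) && length(ct) >= 2,
              "ct must be a numeric vector over >= 2 fractions")
  det <- !is.na(ct)
  assert_that(any(det), "all fractions undetected")
  rel <- numeric(length(ct))
  rel[det] <- 2^(max(ct[det]) - ct[det])
  100 * rel / sum(rel)
}
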