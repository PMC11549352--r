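#' @name chirp
#' @title Enrichment calling for RNA-pulldown (ChIRP-MS) protein matrices
#'
#' @description
#' An RNA pulldown followed by mass spectrometry yields a proteins x samples
#' intensity matrix with abundant missing values. Proteins genuinely bound
#' to the target RNA should be recovered in pulldowns from strains that
#' express the RNA (wild type, overexpression) but not from a deletion
#' control, so calling proceeds in four stages: a presence filter
#' (\code{\link{presence_filter}}), sentinel imputation plus normalization
#' (\code{\link{impute_and_normalize}}), a moderated-t differential
#' enrichment test per contrast (\code{\link{differential_enrichment}}),
#' and thresholding on FDR and log2 fold change
#' (\code{\link{call_bound}}).
#'
#' The design is a data frame with columns \code{sample}, \code{strain},
#' \code{replicate}; matrices have proteins as rownames and samples as
#' colnames.
NULL

check_chirp_design <- function(mat, design) {
  assert_that(is.matrix(mat) && !is.null(rownames(mat)) &&
                !is.null(colnames(mat)),
              "matrix must have protein rownames and sample colnames")
  assert_that(all(c("sample", "strain", "replicate") %in% names(design)),
              "design must have sample, strain, replicate")
  assert_that(setequal(colnames(mat), design$sample),
              "design samples must match matrix columns")
}

#' Presence filter: require detection in enough replicates of one strain
#'
#' Removes proteins not identified (non-missing) in at least \code{min_reps}
#' replicates of at least one strain; such proteins are sporadic
#' identifications that cannot be tested. The number removed is reported
#' via a message.
#'
#' @param mat proteins x samples intensity matrix (NA = not identified).
#' @param design sample design (see \link{chirp}).
#' @param min_reps minimum replicates with detection within a strain.
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
presence_filter <- function(mat, design, min_reps = 2) {
  check_chirp_design(mat, design)
  strains <- unique(design$strain)
  keep <- rep(FALSE, nrow(mat))
  for (s in strains) {
    cols <- design$sample[design$strain == s]
    keep <- keep | rowSums(!is.na(mat[, cols, drop = FALSE])) >= min_reps
  }
  dropped <- sum(!keep)
  message(dropped, " of ", nrow(mat),
          " proteins removed by presence filter (", sum(keep), " retained)")
  out <- mat[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("presence filter left an empty matrix")
  out
}

#' Sentinel imputation and per-sample normalization
#'
#' Remaining missing intensities are imputed with 1 (hence exactly 0 after
#' log2), the matrix is log2-transformed, and each sample is calibrated by
#' a robust affine map: subtract the sample median, divide by the sample
#' median absolute deviation, then rescale to the across-sample median
#' location and spread so the output stays on the log2-intensity scale.
#' This per-sample affine calibration is a deterministic stand-in for a
#' variance-stabilizing normalization; calibration parameters are attached
#' as the \code{"calibration"} attribute.
#'
#' @param mat presence-filtered intensity matrix (raw scale, NA = missing).
#' @param calibrate apply the per-sample affine calibration (default TRUE);
#'   \code{FALSE} returns plain imputed log2 intensities.
#' @return matrix of normalized log2 intensities with a \code{calibration}
#'   attribute (data frame: sample, median, mad).
#' @export
impute_and_normalize <- function(mat, calibrate = TRUE) {
  assert_that(is.matrix(mat) && nrow(mat) > 0, "matrix must be non-empty")
  imp <- mat
  imp[is.na(imp)] <- 1
  assert_that(all(imp > 0), "intensities must be positive")
  lg <- log2(imp)
  if (!calibrate) return(lg)

  meds <- apply(lg, 2, stats::median)
  mads <- apply(lg, 2, stats::mad)
  nfin <- colSums(is.finite(lg))
  assert_that(all(nfin >= 3), "each sample needs >= 3 finite values")
  assert_that(all(mads > 0),
              "a sample has zero spread; cannot calibrate")
  med_ref <- stats::median(meds)
  mad_ref <- stats::median(mads)
  out <- sweep(lg, 2, meds, "-")
  out <- sweep(out, 2, mads, "/") * mad_ref + med_ref
  attr(out, "calibration") <- data.frame(sample = colnames(lg),
                                         median = meds, mad = mads,
                                         row.names = NULL)
  out
}

# Moment-matching estimate of the empirical-Bayes variance prior (d0, s0^2)
# from per-protein sample variances s2 with d residual df each. Under the
# hierarchical model s2 ~ s0^2 * F(d, d0), the squared coefficient of
# variation of s2 is 2 (d + d0 - 2) / (d (d0 - 4)); solving for d0 gives a
# closed form. Underdispersion (cv2 * d <= 2) yields d0 = Inf (complete
# shrinkage to the common variance).
estimate_variance_prior <- function(s2, d) {
  m1 <- mean(s2)
  if (m1 <= 0) return(list(d0 = Inf, s0_sq = 0))
  cv2 <- stats::var(s2) / m1^2
  if (!is.finite(cv2) || cv2 * d <= 2) return(list(d0 = Inf, s0_sq = m1))
  d0 <- (4 * cv2 * d + 2 * d - 4) / (cv2 * d - 2)
  list(d0 = d0, s0_sq = m1 * (d0 - 2) / d0)
}

#' Moderated-t differential enrichment per contrast
#'
#' For each protein and each contrast (pair of strains), computes the mean
#' log2 difference, a pooled two-sample variance shrunk toward an
#' empirical-Bayes prior estimated by moment matching across proteins
#' (posterior variance \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}),
#' a moderated t statistic with \eqn{d_0 + d} degrees of freedom, and
#' Benjamini-Hochberg FDR within each contrast. Setting \code{d0 = 0}
#' disables shrinkage and reproduces the ordinary two-sample pooled t test.
#'
#' @param norm normalized log2 matrix from
#'   \code{\link{impute_and_normalize}}.
#' @param design sample design.
#' @param contrasts list of length-2 character vectors
#'   \code{c(test_strain, reference_strain)}.
#' @param d0 optional fixed prior df overriding the moment-matched estimate
#'   (0 = ordinary t).
#' @return data frame with \code{protein}, \code{contrast},
#'   \code{log2_fold_change}, \code{moderated_t}, \code{df},
#'   \code{p_value}, \code{fdr}; prior parameters in attribute
#'   \code{"prior"}.
#' @export
differential_enrichment <- function(norm, design,
                                    contrasts = list(
                                      c("wildtype", "deletion_control"),
                                      c("overexpression", "deletion_control")),
                                    d0 = NULL) {
  check_chirp_design(norm, design)
  priors <- list()
  out <- lapply(contrasts, function(ct) {
    assert_that(length(ct) == 2, "each contrast must name two strains")
    a_cols <- design$sample[design$strain == ct[1]]
    b_cols <- design$sample[design$strain == ct[2]]
    nA <- length(a_cols); nB <- length(b_cols)
    assert_that(nA >= 2 && nB >= 2,
                "each arm of contrast ", ct[1], " vs ", ct[2],
                " needs >= 2 replicates")
    d <- nA + nB - 2
    assert_that(d > 0, "zero residual degrees of freedom")
    A <- norm[, a_cols, drop = FALSE]
    B <- norm[, b_cols, drop = FALSE]
    diff <- rowMeans(A) - rowMeans(B)
    ssA <- rowSums((A - rowMeans(A))^2)
    ssB <- rowSums((B - rowMeans(B))^2)
    s2 <- (ssA + ssB) / d

    if (is.null(d0)) {
      prior <- estimate_variance_prior(s2, d)
    } else if (d0 == 0) {
      prior <- list(d0 = 0, s0_sq = 0)
    } else {
      prior <- list(d0 = d0, s0_sq = mean(s2))
    }
    s2_post <- if (is.infinite(prior$d0)) {
      rep(prior$s0_sq, length(s2))
    } else {
      (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
    }
    se <- sqrt(s2_post * (1 / nA + 1 / nB))
    tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
    df_tot <- d + prior$d0
    p <- 2 * stats::pt(-abs(tstat), df = df_tot)
    p[is.infinite(tstat)] <- 0
    label <- paste(ct[1], "vs", ct[2])
    priors[[label]] <<- prior
    data.frame(protein = rownames(norm), contrast = label,
               log2_fold_change = diff, moderated_t = tstat,
               df = df_tot, p_value = p,
               fdr = stats::p.adjust(p, method = "BH"),
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "prior") <- priors
  res
}

#' Call RNA-bound proteins from enrichment results
#'
#' A protein is called bound when it passes \code{fdr <= fdr_max} and
#' \code{log2_fold_change >= lfc_min} (both inclusive) in \emph{either}
#' contrast (the test and/or the overexpression pulldown versus the
#' deletion control).
#'
#' @param results data frame from \code{\link{differential_enrichment}}.
#' @param fdr_max,lfc_min inclusive thresholds.
#' @return character vector of bound protein ids.
#' @export
call_bound <- function(results, fdr_max = 0.005, lfc_min = 6.5) {
  assert_that(all(c("protein", "fdr", "log2_fold_change") %in%
                    names(results)),
              "results must come from differential_enrichment")
  pass <- results$fdr <= fdr_max & results$log2_fold_change >= lfc_min
  sort(unique(results$protein[pass]))
}
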