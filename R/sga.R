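#' @name sga
#' @title Synthetic genetic array (SGA) colony-size interaction scoring
#'
#' @description
#' The SGA pipeline scores genetic interactions from arrayed colony sizes:
#' query-mutant double mutants are compared against a neutral control query
#' across replicate plates. Raw sizes carry non-genetic artefacts (failed
#' library positions, spatial gradients from pinning/incubation, plate-scale
#' differences) that must be removed before scoring. The pipeline stages are
#' \code{\link{filter_colonies}}, \code{\link{spatial_normalize}},
#' \code{\link{exclude_linked}}, \code{\link{compute_gis}} and
#' \code{\link{call_hits}}, wrapped end to end by \code{\link{sga_score}}.
#'
#' Plate data are long data frames with columns \code{plate_id},
#' \code{repeat_id}, \code{arm} ("query" or "control"), \code{field}
#' (plate-layout index), \code{row}, \code{col}, \code{size_px} (NA for an
#' absent colony). The gene map gives \code{field}, \code{row}, \code{col},
#' \code{gene_id}; annotations give \code{gene_id}, \code{chromosome},
#' \code{position_bp}.
NULL

position_key <- function(df) paste(df$field, df$row, df$col, sep = ":")

#' Exclude failed library positions from control plates
#'
#' Positions whose control colony is absent or small (< \code{threshold_px},
#' default 100 pixels) in any control plate are marked as excluded
#' screen-wide: such positions reflect absent mutants or pinning failures,
#' and keeping them would produce false interaction calls. The mask is
#' applied to query plates too. Small colonies on \emph{query} plates are
#' never filtered; they are the negative-interaction signal itself.
#'
#' @param plates SGA plate data frame (see \link{sga}).
#' @param threshold_px minimum control colony size considered valid.
#' @return list with \code{mask} (data frame of excluded field/row/col) and
#'   \code{plates} (input with a logical \code{excluded} column).
#' @export
filter_colonies <- function(plates, threshold_px = 100) {
  assert_that(all(c("plate_id", "repeat_id", "arm", "field", "row", "col",
                    "size_px") %in% names(plates)),
              "plates must have plate_id, repeat_id, arm, field, row, col, size_px")
  ctrl <- plates[plates$arm == "control", , drop = FALSE]
  assert_that(nrow(ctrl) > 0, "control plates are required")
  bad <- is.na(ctrl$size_px) | ctrl$size_px < threshold_px
  bad_keys <- unique(position_key(ctrl)[bad])
  keys <- position_key(plates)
  plates$excluded <- keys %in% bad_keys
  if (all(plates$excluded)) stop_invalid("all positions excluded")
  mask <- unique(ctrl[bad, c("field", "row", "col"), drop = FALSE])
  rownames(mask) <- NULL
  list(mask = mask, plates = plates)
}

# 2D moving median with reflect padding; NAs (excluded positions) ignored.
moving_median_2d <- function(m, window) {
  nr <- nrow(m); nc <- ncol(m)
  assert_that(window %% 2 == 1, "window must be odd")
  assert_that(window <= nr && window <= nc,
              "window larger than grid")
  half <- window %/% 2
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  ri <- reflect(seq(1 - half, nr + half), nr)
  ci <- reflect(seq(1 - half, nc + half), nc)
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- pad[i:(i + 2 * half), j:(j + 2 * half)]
      out[i, j] <- stats::median(win, na.rm = TRUE)
    }
  }
  out
}

#' Spatially normalize one colony-size grid
#'
#' Removes smooth positional artefacts in two stages: (1) a 2D moving-median
#' surface (window \code{window}, reflect-padded, excluded positions ignored)
#' is divided out and re-centred on the plate median; (2) residual row and
#' column effects are removed by dividing each entry by its row median and
#' column median relative to the plate median. The plate median is preserved
#' to within ~1 percent; isolated outlier colonies are not absorbed by the
#' median surface.
#'
#' @param m numeric matrix of colony sizes (NA = excluded/absent).
#' @param window odd moving-median window (default 5).
#' @return normalized matrix of the same shape.
#' @export
spatial_normalize_matrix <- function(m, window = 5) {
  assert_that(is.matrix(m), "m must be a matrix")
  assert_that(mean(!is.na(m)) >= 0.5, ">= 50% of positions must be present")
  plate_med <- stats::median(m, na.rm = TRUE)
  surface <- moving_median_2d(m, window)
  surface[surface <= 0 | is.na(surface)] <- plate_med
  out <- m / surface * plate_med

  med2 <- stats::median(out, na.rm = TRUE)
  row_eff <- apply(out, 1, stats::median, na.rm = TRUE) / med2
  col_eff <- apply(out, 2, stats::median, na.rm = TRUE) / med2
  row_eff[!is.finite(row_eff) | row_eff <= 0] <- 1
  col_eff[!is.finite(col_eff) | col_eff <= 0] <- 1
  sweep(sweep(out, 1, row_eff, "/"), 2, col_eff, "/")
}

#' Spatially normalize all plates of a screen
#'
#' Applies \code{\link{spatial_normalize_matrix}} to every plate in a long
#' SGA plate table (excluded positions are set aside as NA and remain
#' excluded).
#'
#' @param plates plate data frame, ideally after
#'   \code{\link{filter_colonies}} (an \code{excluded} column is honoured).
#' @param window odd moving-median window.
#' @return the plate data frame with a \code{size_norm} column.
#' @export
spatial_normalize <- function(plates, window = 5) {
  plates$size_norm <- NA_real_
  for (pid in unique(plates$plate_id)) {
    idx <- which(plates$plate_id == pid)
    sub <- plates[idx, ]
    nr <- max(sub$row); nc <- max(sub$col)
    m <- matrix(NA_real_, nr, nc)
    sz <- sub$size_px
    if (!is.null(sub$excluded)) sz[sub$excluded] <- NA_real_
    m[cbind(sub$row, sub$col)] <- sz
    norm <- spatial_normalize_matrix(m, window)
    plates$size_norm[idx] <- norm[cbind(sub$row, sub$col)]
  }
  plates
}

#' Exclude genes linked to the query or control marker loci
#'
#' Double mutants of genes physically near a marker locus are depleted by
#' genetic linkage rather than interaction, so genes on the same chromosome
#' within \code{radius_bp} (inclusive, default 250 kb) of either locus are
#' excluded from scoring.
#'
#' @param annotations data frame with \code{gene_id}, \code{chromosome},
#'   \code{position_bp}.
#' @param loci character vector of marker gene ids (must be annotated).
#' @param radius_bp linkage exclusion radius in bp.
#' @return character vector of excluded gene ids.
#' @export
exclude_linked <- function(annotations, loci, radius_bp = 250000) {
  assert_that(all(c("gene_id", "chromosome", "position_bp") %in%
                    names(annotations)),
              "annotations must have gene_id, chromosome, position_bp")
  assert_that(!anyDuplicated(annotations$gene_id),
              "one annotation per gene_id required")
  excluded <- character(0)
  for (locus in loci) {
    hit <- annotations[annotations$gene_id == locus, , drop = FALSE]
    assert_that(nrow(hit) == 1, "locus ", locus, " has no annotation")
    same <- annotations$chromosome == hit$chromosome
    near <- abs(annotations$position_bp - hit$position_bp) <= radius_bp
    excluded <- union(excluded, annotations$gene_id[same & near])
  }
  excluded
}

#' Genetic interaction scores from normalized colony sizes
#'
#' For each gene and repeat, the genetic interaction score (GIS) is the
#' log10 ratio of the median normalized query colony size to the median
#' normalized control colony size, clipped to [-2, +2]. Negative scores are
#' aggravating (double mutant smaller than expected), positive scores
#' alleviating. A control median of zero yields +2 when the query median is
#' positive and NA otherwise; genes absent from either arm in a repeat get
#' NA for that repeat.
#'
#' @param plates normalized plate table (output of
#'   \code{\link{spatial_normalize}}).
#' @param gene_map data frame with \code{field}, \code{row}, \code{col},
#'   \code{gene_id}.
#' @param excluded_genes optional gene ids to drop (e.g. linked loci).
#' @return data frame with \code{gene_id}, \code{repeat_id}, \code{gis}.
#' @export
compute_gis <- function(plates, gene_map, excluded_genes = NULL) {
  assert_that("size_norm" %in% names(plates),
              "plates must be normalized first (size_norm column)")
  keys <- position_key(plates)
  map_keys <- position_key(gene_map)
  plates$gene_id <- gene_map$gene_id[match(keys, map_keys)]
  dat <- plates[!is.na(plates$gene_id) & !isTRUE(plates$excluded), ]
  if (!is.null(dat$excluded)) dat <- dat[!dat$excluded, ]
  if (!is.null(excluded_genes)) {
    dat <- dat[!(dat$gene_id %in% excluded_genes), ]
  }
  assert_that(nrow(dat) > 0, "no scoreable colonies")

  agg <- stats::aggregate(size_norm ~ gene_id + repeat_id + arm, data = dat,
                          FUN = function(x) stats::median(x, na.rm = TRUE))
  qm <- agg[agg$arm == "query", ]
  cm <- agg[agg$arm == "control", ]
  key_q <- paste(qm$gene_id, qm$repeat_id)
  key_c <- paste(cm$gene_id, cm$repeat_id)
  common <- intersect(key_q, key_c)
  q <- qm$size_norm[match(common, key_q)]
  ctl <- cm$size_norm[match(common, key_c)]

  gis <- ifelse(ctl > 0, log10(q / ctl),
                ifelse(q > 0, Inf, NA_real_))
  gis <- pmin(pmax(gis, -2), 2)
  out <- data.frame(gene_id = qm$gene_id[match(common, key_q)],
                    repeat_id = qm$repeat_id[match(common, key_q)],
                    gis = gis)
  out[order(out$gene_id, out$repeat_id), ]
}

#' Call consensus interaction hits across repeats
#'
#' Per repeat, a gene is scored negative when its GIS is at or below
#' \code{-cutoff} and positive at or above \code{+cutoff}. The consensus
#' call requires the same sign in at least \code{min_repeats} repeats;
#' genes where both signs independently reach \code{min_repeats} are
#' flagged ambiguous and called \code{"none"} rather than dropped silently.
#'
#' @param gis data frame from \code{\link{compute_gis}}.
#' @param cutoff absolute GIS threshold for a per-repeat call.
#' @param min_repeats repeats required for a consensus.
#' @return data frame with \code{gene_id}, \code{n_repeats_scored},
#'   \code{n_negative}, \code{n_positive}, \code{consensus_call},
#'   \code{n_supporting_repeats}, \code{ambiguous}.
#' @export
call_hits <- function(gis, cutoff = 0.1, min_repeats = 2) {
  assert_that(all(c("gene_id", "repeat_id", "gis") %in% names(gis)),
              "gis must have gene_id, repeat_id, gis")
  res <- lapply(split(gis, gis$gene_id), function(df) {
    g <- df$gis[!is.na(df$gis)]
    n_neg <- sum(g <= -cutoff)
    n_pos <- sum(g >= cutoff)
    amb <- n_neg >= min_repeats && n_pos >= min_repeats
    call <- if (amb) "none"
            else if (n_neg >= min_repeats) "negative"
            else if (n_pos >= min_repeats) "positive"
            else "none"
    support <- switch(call, negative = n_neg, positive = n_pos, none = 0L)
    data.frame(gene_id = df$gene_id[1], n_repeats_scored = length(g),
               n_negative = n_neg, n_positive = n_pos,
               consensus_call = call, n_supporting_repeats = support,
               ambiguous = amb)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score a full SGA screen end to end
#'
#' Runs artefact filtering, spatial normalization, linkage exclusion, GIS
#' computation and consensus hit calling in sequence.
#'
#' @param plates raw plate table (see \link{sga}).
#' @param gene_map position-to-gene map.
#' @param annotations optional gene annotations for linkage exclusion.
#' @param query_locus,control_locus marker gene ids for linkage exclusion
#'   (used only when \code{annotations} supplied).
#' @param window moving-median window.
#' @param threshold_px control colony-size filter.
#' @param radius_bp linkage radius.
#' @param cutoff,min_repeats hit-calling parameters.
#' @return list with \code{gis} (per gene x repeat), \code{hits}
#'   (consensus table), \code{mask} (excluded positions),
#'   \code{excluded_genes} (linked loci).
#' @export
sga_score <- function(plates, gene_map, annotations = NULL,
                      query_locus = NULL, control_locus = NULL,
                      window = 5, threshold_px = 100, radius_bp = 250000,
                      cutoff = 0.1, min_repeats = 2) {
  filt <- filter_colonies(plates, threshold_px = threshold_px)
  norm <- spatial_normalize(filt$plates, window = window)
  excl <- character(0)
  if (!is.null(annotations)) {
    loci <- c(query_locus, control_locus)
    scored <- unique(gene_map$gene_id)
    missing_ann <- setdiff(scored, annotations$gene_id)
    if (length(missing_ann) > 0) {
      warning(length(missing_ann),
              " scored genes lack annotations; retained without linkage check")
    }
    if (length(loci) > 0) excl <- exclude_linked(annotations, loci, radius_bp)
  }
  gis <- compute_gis(norm, gene_map, excluded_genes = excl)
  hits <- call_hits(gis, cutoff = cutoff, min_repeats = min_repeats)
  list(gis = gis, hits = hits, mask = filt$mask, excluded_genes = excl)
}
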