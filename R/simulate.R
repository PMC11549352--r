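#' @name simulate
#' @title Seeded synthetic-data generators with recorded ground truth
#'
#' @description
#' Each generator emulates one input type consumed by the analysis modules
#' and returns the simulated data together with a \code{truth} record of
#' the parameters used, so every downstream stage can be tested against a
#' known answer without any external data. All randomness flows from the
#' explicit \code{seed} argument through a local RNG state (the global
#' \code{.Random.seed} is restored on exit); identical seeds give
#' identical outputs.
NULL

with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate serial-dilution colony counts
#'
#' Plate counts are Poisson with mean \code{true_cfu_per_ml *
#' plated_volume_ml / dilution}, independently per plate, mirroring a
#' robotics-based CFU assay where each timepoint is plated over a 10-fold
#' dilution series in duplicate.
#'
#' @param true_cfu_per_ml CFU concentration per timepoint; names (if any)
#'   are used as timepoint labels, else days 0, 1, 2, ...
#' @param dilutions dilution factors (>= 1).
#' @param plated_volume_ml volume plated per plate (mL).
#' @param plates_per_dilution plates per dilution (default duplicate).
#' @param seed RNG seed.
#' @return list with \code{data} (data frame: timepoint_day,
#'   dilution_factor, plated_volume_ml, plate, colony_count) and
#'   \code{truth} (data frame: timepoint_day, true_cfu_per_ml).
#' @export
simulate_dilution_counts <- function(true_cfu_per_ml,
                                     dilutions = 10^(2:5),
                                     plated_volume_ml = 0.1,
                                     plates_per_dilution = 2,
                                     seed = 1) {
  assert_that(all(is.finite(true_cfu_per_ml)) && all(true_cfu_per_ml >= 0),
              "true_cfu_per_ml must be finite and non-negative")
  assert_that(all(dilutions >= 1), "dilutions must be >= 1")
  assert_that(plated_volume_ml > 0, "plated_volume_ml must be positive")
  assert_that(plates_per_dilution >= 1,
              "plates_per_dilution must be >= 1")
  days <- names(true_cfu_per_ml) %||% as.character(seq_along(true_cfu_per_ml) - 1)

  with_seed(seed, {
    grid <- expand.grid(plate = seq_len(plates_per_dilution),
                        dilution_factor = dilutions,
                        timepoint_day = days,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    lambda <- true_cfu_per_ml[match(grid$timepoint_day, days)] *
      plated_volume_ml / grid$dilution_factor
    grid$plated_volume_ml <- plated_volume_ml
    grid$colony_count <- stats::rpois(nrow(grid), lambda)
    grid <- grid[, c("timepoint_day", "dilution_factor",
                     "plated_volume_ml", "plate", "colony_count")]
    list(data = grid,
         truth = data.frame(timepoint_day = days,
                            true_cfu_per_ml = unname(true_cfu_per_ml)))
  })
}

#' Simulate an SGA colony screen with planted interactions
#'
#' Generates matched query and control plate sets in 384 (16 x 24) format:
#' baseline colony sizes are lognormal, multiplied by a smooth spatial
#' surface (a radial bowl plus a linear ramp across columns, relative
#' amplitude \code{gradient_amplitude}), and, in query plates only, by the
#' planted interaction factor \code{10^effect_log10} for
#' \code{n_interactors} randomly chosen genes. Each gene occupies
#' \code{replicates_per_gene} randomly scattered positions per plate set
#' (emulating quadruplicate pinning). A fraction \code{small_colony_rate}
#' of positions is replaced screen-wide by failed colonies (< 100 px) on
#' control plates, emulating absent library mutants.
#'
#' @param n_genes genes in the screen.
#' @param n_interactors genes given a planted interaction.
#' @param effect_log10 planted interaction effect (true GIS); scalar or
#'   vector of length \code{n_interactors}.
#' @param gradient_amplitude relative amplitude of the spatial surface.
#' @param small_colony_rate fraction of positions with failed control
#'   colonies (in [0, 1)).
#' @param n_repeats independent screen repeats.
#' @param replicates_per_gene colony positions per gene per plate set.
#' @param grid_rows,grid_cols plate format (default 16 x 24 = 384).
#' @param baseline_px median colony size in pixels.
#' @param size_sdlog lognormal sdlog of colony-size noise (~12 percent CV
#'   by default, typical of replicate colony sizes).
#' @param seed RNG seed.
#' @return list with \code{plates} (long table, see \link{sga}),
#'   \code{gene_map} and \code{truth} (gene_id, true_gis).
#' @export
simulate_colony_screen <- function(n_genes = 500, n_interactors = 20,
                                   effect_log10 = -0.5,
                                   gradient_amplitude = 0.3,
                                   small_colony_rate = 0.05,
                                   n_repeats = 3, replicates_per_gene = 4,
                                   grid_rows = 16, grid_cols = 24,
                                   baseline_px = 600, size_sdlog = 0.12,
                                   seed = 1) {
  assert_that(small_colony_rate >= 0 && small_colony_rate < 1,
              "small_colony_rate must be in [0, 1)")
  assert_that(n_interactors <= n_genes,
              "n_interactors cannot exceed n_genes")
  per_plate <- grid_rows * grid_cols
  n_pos <- n_genes * replicates_per_gene
  n_fields <- ceiling(n_pos / per_plate)

  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    interactors <- sort(sample(genes, n_interactors))
    eff <- rep_len(effect_log10, n_interactors)
    truth <- data.frame(gene_id = genes, true_gis = 0)
    truth$true_gis[match(interactors, genes)] <- eff

    # Random gene layout over the plate set, shared by query and control.
    slots <- data.frame(
      field = rep(seq_len(n_fields), each = per_plate),
      row = rep(rep(seq_len(grid_rows), each = grid_cols), n_fields),
      col = rep(rep(seq_len(grid_cols), grid_rows), n_fields))
    assign_idx <- sample(nrow(slots), n_pos)
    gene_map <- slots[assign_idx, ]
    gene_map$gene_id <- rep(genes, each = replicates_per_gene)
    gene_map <- gene_map[order(gene_map$field, gene_map$row, gene_map$col), ]
    rownames(gene_map) <- NULL

    # Spatial surface per plate: radial bowl + linear column ramp.
    surface_at <- function(row, col) {
      r <- sqrt(((row - (grid_rows + 1) / 2) / (grid_rows / 2))^2 +
                  ((col - (grid_cols + 1) / 2) / (grid_cols / 2))^2)
      ramp <- (col - 1) / (grid_cols - 1) - 0.5
      1 + gradient_amplitude * (0.5 * (1 - pmin(r, 1.4) / 1.4) + 0.5 * ramp)
    }

    # Failed library positions, fixed across repeats (control plates only).
    fail_pos <- sample(nrow(gene_map),
                       round(small_colony_rate * nrow(gene_map)))

    plates <- list()
    for (rep_id in seq_len(n_repeats)) {
      for (arm in c("query", "control")) {
        sizes <- baseline_px *
          stats::rlnorm(nrow(gene_map), meanlog = 0, sdlog = size_sdlog) *
          surface_at(gene_map$row, gene_map$col)
        if (arm == "query") {
          planted <- match(gene_map$gene_id, interactors)
          fac <- ifelse(is.na(planted), 1, 10^eff[planted])
          sizes <- sizes * fac
        } else if (length(fail_pos) > 0) {
          sizes[fail_pos] <- stats::runif(length(fail_pos), 0, 99)
        }
        plates[[paste(arm, rep_id)]] <- data.frame(
          plate_id = paste0(arm, "_r", rep_id, "_f", gene_map$field),
          repeat_id = rep_id, arm = arm,
          field = gene_map$field, row = gene_map$row, col = gene_map$col,
          size_px = sizes)
      }
    }
    plates <- do.call(rbind, plates)
    rownames(plates) <- NULL
    list(plates = plates,
         gene_map = gene_map[, c("field", "row", "col", "gene_id")],
         truth = truth,
         planted = interactors)
  })
}

#' Simulate a polysome absorbance trace with known region areas
#'
#' The trace is a constant baseline plus one Gaussian bump per region
#' (free subunits, monosome, polysomes) with the stated areas, plus white
#' noise. Adjacent peaks overlapping by more than ~1 percent of their area
#' at the chosen widths are recorded as a warning in the truth metadata.
#'
#' @param region_areas named vector of areas in region order, names from
#'   \code{c("free_subunits", "monosome", "polysome_2", ...)}.
#' @param peak_locations,peak_widths Gaussian centres and SDs (gradient
#'   position units), same length as \code{region_areas}.
#' @param baseline_level constant baseline absorbance.
#' @param noise_sd white-noise SD.
#' @param positions sampling grid along the gradient.
#' @param seed RNG seed.
#' @return list with \code{data} (data frame: position, absorbance) and
#'   \code{truth} (list: region_areas, peak_locations, peak_widths,
#'   baseline_level, boundaries data frame, overlap_warning flag).
#' @export
simulate_polysome_trace <- function(region_areas = c(free_subunits = 3,
                                                     monosome = 2,
                                                     polysome_2 = 1.2,
                                                     polysome_3 = 0.8,
                                                     polysome_4 = 0.5),
                                    peak_locations = NULL,
                                    peak_widths = NULL,
                                    baseline_level = 0.02,
                                    noise_sd = 0.002,
                                    positions = seq(0, 10, length.out = 1000),
                                    seed = 1) {
  k <- length(region_areas)
  assert_that(k >= 2, "need at least free-subunit and monosome regions")
  assert_that(all(region_areas >= 0), "areas must be non-negative")
  if (is.null(peak_locations)) {
    peak_locations <- seq(1.2, by = 1.4, length.out = k)
  }
  # Default width keeps adjacent peaks ~3.9 SD apart: overlap well under
  # 1% of area and inter-peak valleys that reach the baseline, as in a
  # well-resolved gradient run.
  if (is.null(peak_widths)) peak_widths <- rep(0.18, k)
  assert_that(length(peak_locations) == k && length(peak_widths) == k,
              "locations/widths must match region_areas")
  assert_that(all(diff(peak_locations) > 0),
              "peak locations must be increasing")

  # Overlap check: mass of each Gaussian beyond the midpoint to its
  # neighbour, relative to its own area.
  overlap <- FALSE
  for (i in seq_len(k - 1)) {
    mid <- (peak_locations[i] + peak_locations[i + 1]) / 2
    tail_i <- stats::pnorm(mid, peak_locations[i], peak_widths[i],
                           lower.tail = FALSE)
    tail_j <- stats::pnorm(mid, peak_locations[i + 1], peak_widths[i + 1])
    if (tail_i > 0.01 || tail_j > 0.01) overlap <- TRUE
  }
  if (overlap) warning("adjacent peaks overlap beyond 1% of area")

  with_seed(seed, {
    y <- rep(baseline_level, length(positions))
    for (i in seq_len(k)) {
      y <- y + region_areas[i] *
        stats::dnorm(positions, peak_locations[i], peak_widths[i])
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    mids <- (peak_locations[-k] + peak_locations[-1]) / 2
    boundaries <- data.frame(label = names(region_areas),
                             start = c(min(positions), mids),
                             end = c(mids, max(positions)))
    list(data = data.frame(position = positions, absorbance = y),
         truth = list(region_areas = region_areas,
                      peak_locations = peak_locations,
                      peak_widths = peak_widths,
                      baseline_level = baseline_level,
                      boundaries = boundaries,
                      overlap_warning = overlap))
  })
}

#' Simulate per-fraction qPCR Cts from a known mRNA distribution
#'
#' Inverse of \code{\link{fraction_distribution}}: given true percentages
#' per fraction, the Ct of fraction f is
#' \code{ct_at_max_fraction - log2(p_f / p_min_positive)} plus Gaussian
#' noise; fractions with zero percentage are emitted as undetected (NA).
#' At zero noise, \code{fraction_distribution} recovers the input exactly.
#'
#' @param true_percentages vector summing to 100 (non-negative, at least
#'   one positive).
#' @param ct_at_max_fraction Ct of the least-abundant detected fraction.
#' @param noise_sd Gaussian Ct measurement noise.
#' @param seed RNG seed.
#' @return list with \code{data} (data frame: fraction, ct) and
#'   \code{truth} (the input percentages).
#' @export
simulate_fraction_ct <- function(true_percentages, ct_at_max_fraction = 30,
                                 noise_sd = 0, seed = 1) {
  assert_that(all(true_percentages >= 0), "percentages must be >= 0")
  assert_that(any(true_percentages > 0), "at least one positive percentage")
  assert_that(abs(sum(true_percentages) - 100) <= 1e-6,
              "percentages must sum to 100")
  with_seed(seed, {
    p <- true_percentages
    pmin_pos <- min(p[p > 0])
    ct <- ifelse(p > 0, ct_at_max_fraction - log2(p / pmin_pos), NA_real_)
    det <- !is.na(ct)
    if (noise_sd > 0) ct[det] <- ct[det] + stats::rnorm(sum(det), 0, noise_sd)
    list(data = data.frame(fraction = seq_along(p), ct = ct),
         truth = data.frame(fraction = seq_along(p),
                            true_percentage = p))
  })
}

#' Simulate an RNA-pulldown protein intensity matrix
#'
#' Log2 latent intensities are Gaussian per protein; \code{n_bound}
#' proteins are shifted upward by \code{bound_log2_effect} in every strain
#' except the deletion control (the RNA is absent there, so bound proteins
#' fall back to background). Dropout is missing-not-at-random: the
#' probability of a missing value is a decreasing logistic function of the
#' latent log2 intensity, \code{plogis(intercept - slope * latent)}.
#'
#' @param n_proteins,n_bound matrix size and number of planted bound
#'   proteins.
#' @param strains strain labels; must include \code{"deletion_control"}.
#' @param replicates replicates per strain (>= 2).
#' @param bound_log2_effect planted log2 enrichment of bound proteins in
#'   non-deletion strains.
#' @param base_mean,base_sd distribution of per-protein baseline log2
#'   intensity.
#' @param within_sd replicate-to-replicate log2 noise.
#' @param missing_model c(intercept, slope) of the logistic dropout model;
#'   \code{c(-Inf, 0)} disables missingness.
#' @param seed RNG seed.
#' @return list with \code{matrix} (proteins x samples, raw intensity
#'   scale, NA = missing), \code{design} (sample, strain, replicate) and
#'   \code{truth} (data frame: protein, bound, baseline_log2).
#' @export
simulate_protein_matrix <- function(n_proteins = 250, n_bound = 68,
                                    strains = c("wildtype", "overexpression",
                                                "deletion_control"),
                                    replicates = 3,
                                    bound_log2_effect = 8,
                                    base_mean = 10, base_sd = 2,
                                    within_sd = 0.5,
                                    missing_model = c(intercept = 3,
                                                      slope = 0.8),
                                    seed = 1) {
  assert_that(n_bound <= n_proteins, "n_bound cannot exceed n_proteins")
  assert_that("deletion_control" %in% strains,
              "strains must include deletion_control")
  assert_that(replicates >= 2, "need >= 2 replicates")

  with_seed(seed, {
    proteins <- sprintf("prot%04d", seq_len(n_proteins))
    bound <- seq_len(n_bound)
    baseline <- stats::rnorm(n_proteins, base_mean, base_sd)
    design <- expand.grid(replicate = seq_len(replicates),
                          strain = strains,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design$sample <- paste(design$strain, design$replicate, sep = "_")
    design <- design[, c("sample", "strain", "replicate")]

    mat <- matrix(NA_real_, n_proteins, nrow(design),
                  dimnames = list(proteins, design$sample))
    for (j in seq_len(nrow(design))) {
      mu <- baseline
      if (design$strain[j] != "deletion_control") {
        mu[bound] <- mu[bound] + bound_log2_effect
      }
      latent <- stats::rnorm(n_proteins, mu, within_sd)
      a <- missing_model[[1]]; b <- missing_model[[2]]
      p_miss <- if (is.infinite(a) && a < 0) rep(0, n_proteins) else
        stats::plogis(a - b * latent)
      drop <- stats::runif(n_proteins) < p_miss
      vals <- 2^latent
      vals[drop] <- NA_real_
      mat[, j] <- vals
    }
    list(matrix = mat, design = design,
         truth = data.frame(protein = proteins,
                            bound = seq_len(n_proteins) %in% bound,
                            baseline_log2 = baseline))
  })
}

#' Simulate microbioreactor growth curves
#'
#' Biomass curves follow one of the parametric forms in
#' \code{\link{growth_model_value}} plus heteroscedastic Gaussian noise
#' whose SD scales with the signal
#' (\code{noise_sd * (0.2 + 0.8 y / A)}), emulating optical biomass
#' readings whose error grows with density. Defaults emulate a
#' microbioreactor sampling every 10 minutes over 24 h.
#'
#' @param model model name.
#' @param A,mu,lambda,nu true parameters.
#' @param noise_sd noise scale (same units as biomass; "2 percent noise"
#'   means \code{noise_sd = 0.02 * A}).
#' @param n_curves replicate wells.
#' @param t_max,n_timepoints sampling design (hours).
#' @param seed RNG seed.
#' @return list with \code{data} (data frame: well_id, time_h, biomass)
#'   and \code{truth} (model and parameters).
#' @export
simulate_growth_curves <- function(model = "gompertz", A = 1, mu = 0.2,
                                   lambda = 2, nu = 1, noise_sd = 0.02,
                                   n_curves = 1, t_max = 24,
                                   n_timepoints = 145, seed = 1) {
  model <- match.arg(model, growth_models)
  assert_that(A > 0 && mu > 0, "A and mu must be positive")
  assert_that(lambda >= 0, "lambda must be >= 0")
  with_seed(seed, {
    t <- seq(0, t_max, length.out = n_timepoints)
    mean_y <- growth_model_value(model, t, A, mu, lambda, nu)
    out <- do.call(rbind, lapply(seq_len(n_curves), function(w) {
      sd_t <- noise_sd * (0.2 + 0.8 * mean_y / A)
      data.frame(well_id = paste0("well", w), time_h = t,
                 biomass = mean_y + stats::rnorm(length(t), 0, sd_t))
    }))
    list(data = out,
         truth = list(model = model, A = A, mu = mu, lambda = lambda,
                      nu = nu, noise_sd = noise_sd))
  })
}

#' Simulate survival tables under a Gompertz or exponential hazard
#'
#' Event times are drawn by inverse-transform sampling from a Gompertz
#' hazard \eqn{h(t) = a e^{bt}} (exponential when \code{b = 0}). Each
#' individual is independently censored with probability
#' \code{censor_rate}, at a uniform fraction of its drawn event time
#' (emulating losses during vial transfers). Defaults emulate a fly cohort
#' with a median lifespan near 65 days.
#'
#' @param n_per_group named vector of group sizes.
#' @param hazard_params named list (per group) of \code{list(a, b)}.
#' @param censor_rate probability a record is censored.
#' @param seed RNG seed.
#' @return list with \code{data} (data frame: time, event, group) and
#'   \code{truth} (the hazard parameters).
#' @export
simulate_lifespans <- function(n_per_group = c(control = 150, treated = 150),
                               hazard_params = list(
                                 control = list(a = 1e-4, b = 0.1),
                                 treated = list(a = 1e-4, b = 0.1)),
                               censor_rate = 0.05, seed = 1) {
  assert_that(all(n_per_group >= 1), "n_per_group must be >= 1")
  assert_that(setequal(names(n_per_group), names(hazard_params)),
              "groups of n_per_group and hazard_params must match")
  assert_that(censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      a <- hazard_params[[g]]$a
      b <- hazard_params[[g]]$b %||% 0
      assert_that(a > 0 && b >= 0, "hazard a must be > 0, b >= 0")
      u <- stats::runif(n)
      t <- if (b == 0) -log(u) / a else log(1 - b / a * log(u)) / b
      cens <- stats::runif(n) < censor_rate
      time <- ifelse(cens, t * stats::runif(n), t)
      data.frame(time = time, event = !cens, group = g)
    }))
    rownames(out) <- NULL
    list(data = out, truth = hazard_params)
  })
}
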