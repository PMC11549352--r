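# Generators: determinism, stated distributions, round trips.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("all generators are deterministic given a seed", {
  gens <- list(
    function(s) simulate_dilution_counts(c(`0` = 1e6, `4` = 1e4), seed = s),
    function(s) simulate_colony_screen(n_genes = 40, n_interactors = 4,
                                       seed = s),
    function(s) simulate_polysome_trace(seed = s),
    function(s) simulate_fraction_ct(rep(100 / 12, 12), noise_sd = 0.2,
                                     seed = s),
    function(s) simulate_protein_matrix(n_proteins = 50, n_bound = 5,
                                        seed = s),
    function(s) simulate_growth_curves(noise_sd = 0.02, seed = s),
    function(s) simulate_lifespans(seed = s))
  for (gen in gens) {
    expect_identical(gen(7), gen(7))
    expect_false(identical(gen(7)$data %||% gen(7), gen(8)$data %||% gen(8)))
  }
})

test_that("dilution counts follow the Poisson plating model", {
  # Zero rate: all counts zero.
  z <- simulate_dilution_counts(c(`0` = 0, `2` = 0), seed = 1)
  expect_true(all(z$data$colony_count == 0))

  # Law of large numbers: 10 000 plates at expected count 10.
  big <- simulate_dilution_counts(c(`0` = 1e6), dilutions = 1e4,
                                  plated_volume_ml = 0.1,
                                  plates_per_dilution = 10000, seed = 2)
  counts <- big$data$colony_count
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10), 3 * se)
  # Poisson mean/variance match within Monte-Carlo error.
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)

  expect_error(simulate_dilution_counts(c(`0` = 1), dilutions = 0.5),
               "dilutions")
  expect_error(simulate_dilution_counts(c(`0` = 1), plated_volume_ml = -1),
               "volume")
})

test_that("colony screen plants truth and respects the null", {
  sc <- simulate_colony_screen(n_genes = 60, n_interactors = 10,
                               effect_log10 = -1, seed = 3)
  expect_equal(sum(sc$truth$true_gis == -1), 10)
  expect_setequal(sc$truth$gene_id[sc$truth$true_gis == -1], sc$planted)
  # Every gene mapped, query/control plates share positions.
  expect_equal(sort(unique(sc$gene_map$gene_id)), sort(sc$truth$gene_id))

  # Null case: no gradient, no effect -> query and control sizes from the
  # same distribution (location test non-significant in most seeds).
  rej <- 0
  for (s in 1:20) {
    sc0 <- simulate_colony_screen(n_genes = 50, n_interactors = 0,
                                  gradient_amplitude = 0,
                                  small_colony_rate = 0, n_repeats = 1,
                                  seed = s)
    q <- sc0$plates$size_px[sc0$plates$arm == "query"]
    ctl <- sc0$plates$size_px[sc0$plates$arm == "control"]
    if (stats::wilcox.test(q, ctl)$p.value < 0.01) rej <- rej + 1
  }
  expect_lte(rej, 2)

  expect_error(simulate_colony_screen(n_genes = 10, n_interactors = 11),
               "n_interactors")
  expect_error(simulate_colony_screen(small_colony_rate = 1), "rate")
})

test_that("polysome trace truth areas are consistent by construction", {
  tr <- simulate_polysome_trace(region_areas = c(free_subunits = 1,
                                                 monosome = 1,
                                                 polysome_2 = 1),
                                noise_sd = 0, baseline_level = 0, seed = 1)
  # Numerically integrate the noiseless trace over truth boundaries.
  d <- tr$data; b <- tr$truth$boundaries
  areas <- vapply(seq_len(nrow(b)), function(i) {
    sel <- d$position >= b$start[i] & d$position <= b$end[i]
    sum(diff(d$position[sel]) *
          (head(d$absorbance[sel], -1) + tail(d$absorbance[sel], -1)) / 2)
  }, numeric(1))
  expect_equal(areas[2] / areas[2], 1)      # P/M on symmetric construction
  expect_lt(abs(areas[3] / areas[2] - 1), 1e-3)
  expect_lt(abs(sum(areas[2:3]) - 2), 0.01)

  expect_warning(
    simulate_polysome_trace(peak_locations = c(1, 1.1, 2),
                            region_areas = c(free_subunits = 1,
                                             monosome = 1, polysome_2 = 1),
                            seed = 1),
    "overlap")
})

test_that("fraction Ct generator round-trips and encodes undetected", {
  # Flat distribution: all Ct equal.
  flat <- simulate_fraction_ct(rep(100 / 12, 12), noise_sd = 0, seed = 1)
  expect_equal(diff(range(flat$data$ct)), 0)

  # Zero percentages emitted as undetected.
  half <- simulate_fraction_ct(c(50, 50, 0, 0), noise_sd = 0, seed = 1)
  expect_equal(half$data$ct[1], half$data$ct[2])
  expect_true(all(is.na(half$data$ct[3:4])))

  # Round-trip identity at zero noise.
  p <- c(5, 10, 20, 40, 15, 7, 3)
  sim <- simulate_fraction_ct(p, noise_sd = 0, seed = 2)
  expect_equal(fraction_distribution(sim$data$ct), p, tolerance = 1e-12)

  expect_error(simulate_fraction_ct(c(50, 40)), "sum")
})

test_that("protein matrix plants bound structure and MNAR dropout", {
  pm <- simulate_protein_matrix(n_proteins = 200, n_bound = 20,
                                bound_log2_effect = 6,
                                missing_model = c(-Inf, 0), seed = 4)
  expect_false(anyNA(pm$matrix))       # dropout disabled in the limit
  wt <- pm$matrix[, pm$design$sample[pm$design$strain == "wildtype"]]
  del <- pm$matrix[, pm$design$sample[pm$design$strain == "deletion_control"]]
  bound <- pm$truth$protein[pm$truth$bound]
  shift <- rowMeans(log2(wt[bound, ])) - rowMeans(log2(del[bound, ]))
  expect_lt(abs(mean(shift) - 6), 0.5)

  # With dropout on, low-intensity proteins are missing more often.
  pm2 <- simulate_protein_matrix(n_proteins = 500, n_bound = 0,
                                 missing_model = c(3, 0.8), seed = 5)
  miss_rate <- rowMeans(is.na(pm2$matrix))
  lowhigh <- split(miss_rate, pm2$truth$baseline_log2 >
                     median(pm2$truth$baseline_log2))
  expect_gt(mean(lowhigh[["FALSE"]]), mean(lowhigh[["TRUE"]]))

  expect_error(simulate_protein_matrix(n_proteins = 5, n_bound = 6),
               "n_bound")
})

test_that("growth generator matches its closed form", {
  sim <- simulate_growth_curves(model = "gompertz", A = 1, mu = 0.2,
                                lambda = 2, noise_sd = 0, seed = 1)
  d <- sim$data
  # Value at t = lambda under the stated Gompertz form is A*exp(-e).
  y_at_lambda <- approx(d$time_h, d$biomass, xout = 2)$y
  expect_equal(y_at_lambda, exp(-exp(1)), tolerance = 1e-6)
  # Inflection tangent value A*exp(-1) occurs at t = lambda + A/(mu*e).
  t_inf <- 2 + 1 / (0.2 * exp(1))
  expect_equal(approx(d$time_h, d$biomass, xout = t_inf)$y, exp(-1),
               tolerance = 1e-3)
  # Asymptote.
  expect_equal(tail(d$biomass, 1), 1, tolerance = 1e-2)
  expect_error(simulate_growth_curves(model = "weibull"), "arg")
})

test_that("lifespan generator censors as stated", {
  no_cens <- simulate_lifespans(censor_rate = 0, seed = 1)
  expect_true(all(no_cens$data$event))
  some <- simulate_lifespans(censor_rate = 0.3, seed = 2)
  expect_gt(sum(!some$data$event), 0)
  expect_true(all(some$data$time > 0))
})
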