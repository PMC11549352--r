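# SGA filtering, spatial normalization, linkage exclusion, GIS, hit calls.

make_plate <- function(sizes, arm = "control", rep_id = 1, field = 1,
                       nr = 8, nc = 12) {
  data.frame(plate_id = paste0(arm, "_r", rep_id, "_f", field),
             repeat_id = rep_id, arm = arm, field = field,
             row = rep(seq_len(nr), each = nc),
             col = rep(seq_len(nc), nr),
             size_px = sizes)
}

test_that("control-plate filter applies the 100 px boundary screen-wide", {
  sizes <- rep(500, 96)
  sizes[1] <- 99    # excluded
  sizes[2] <- 100   # retained (boundary)
  sizes[3] <- NA    # absent -> excluded
  plates <- rbind(make_plate(sizes, "control"),
                  make_plate(rep(500, 96), "query"))
  out <- filter_colonies(plates)
  expect_equal(nrow(out$mask), 2)
  # Mask applied to the query arm too.
  q <- out$plates[out$plates$arm == "query", ]
  expect_equal(sum(q$excluded), 2)

  # No artefacts -> empty mask, nothing excluded.
  clean <- rbind(make_plate(rep(500, 96), "control"),
                 make_plate(rep(500, 96), "query"))
  out2 <- filter_colonies(clean)
  expect_equal(nrow(out2$mask), 0)
  expect_false(any(out2$plates$excluded))

  expect_error(filter_colonies(rbind(make_plate(rep(10, 96), "control"))),
               "all positions")
})

test_that("excluded fraction tracks the simulated failure rate", {
  sc <- simulate_colony_screen(n_genes = 480, small_colony_rate = 0.05,
                               replicates_per_gene = 1, seed = 6)
  out <- filter_colonies(sc$plates)
  n_pos <- nrow(sc$gene_map)
  frac <- nrow(out$mask) / n_pos
  bounds <- qbinom(c(0.005, 0.995), n_pos, 0.05) / n_pos
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("spatial normalization is identity on flat plates", {
  m <- matrix(700, 16, 24)
  out <- spatial_normalize_matrix(m)
  expect_equal(out, m, tolerance = 1e-12)
  expect_error(spatial_normalize_matrix(m, window = 25), "window")
})

test_that("spatial normalization removes a 30% radial gradient", {
  nr <- 16; nc <- 24
  r <- sqrt(outer(((1:nr) - 8.5) / 8, rep(1, nc))^2 +
              outer(rep(1, nr), ((1:nc) - 12.5) / 12)^2)
  surface <- 1 + 0.3 * cos(pi * pmin(r, 1) / 2)
  m <- 600 * surface
  out <- spatial_normalize_matrix(m)
  cv_in <- sd(m) / mean(m)
  cv_out <- sd(out) / mean(out)
  expect_gte(cv_in / cv_out, 5)
  # Plate median preserved to within 1%.
  expect_lt(abs(median(out) / median(m) - 1), 0.01)
})

test_that("an isolated outlier colony is not absorbed by the surface", {
  set.seed(2)
  m <- matrix(rlnorm(16 * 24, log(600), 0.05), 16, 24)
  m[8, 12] <- 10 * median(m)
  out <- spatial_normalize_matrix(m)
  neighbours <- out[6:10, 10:14]
  local_med <- median(neighbours[-13])   # drop the outlier itself
  expect_gt(out[8, 12] / local_med, 8)
  expect_lt(out[8, 12] / local_med, 12)
})

test_that("linkage exclusion is inclusive at the radius and per-chromosome", {
  ann <- data.frame(gene_id = c("qry", "g_at", "g_far", "g_chr2", "ctl",
                                "g_ctl_near"),
                    chromosome = c("I", "I", "I", "II", "II", "II"),
                    position_bp = c(1e6, 1e6 + 250000, 1e6 + 250001,
                                    1e6, 5e6, 5e6 + 1000))
  ex <- exclude_linked(ann, c("qry", "ctl"))
  expect_true(all(c("qry", "g_at", "ctl", "g_ctl_near") %in% ex))
  expect_false("g_far" %in% ex)
  expect_false("g_chr2" %in% ex)   # different locus position, same chr as qry? no: chr II far from ctl

  # Brute-force oracle on random annotations.
  set.seed(11)
  ann2 <- data.frame(gene_id = paste0("g", 1:300),
                     chromosome = sample(c("I", "II", "III"), 300, TRUE),
                     position_bp = sample.int(5e6, 300))
  loci <- sample(ann2$gene_id, 2)
  ex2 <- exclude_linked(ann2, loci)
  brute <- ann2$gene_id[sapply(seq_len(300), function(i) {
    any(sapply(loci, function(L) {
      a <- ann2[ann2$gene_id == L, ]
      ann2$chromosome[i] == a$chromosome &&
        abs(ann2$position_bp[i] - a$position_bp) <= 250000
    }))
  })]
  expect_setequal(ex2, brute)

  expect_error(exclude_linked(ann, "nosuch"), "annotation")
})

test_that("GIS is the clipped log10 median ratio", {
  gm <- data.frame(field = 1, row = 1:6, col = 1,
                   gene_id = c("a", "a", "b", "b", "c", "c"))
  mk <- function(arm, sizes) {
    data.frame(plate_id = arm, repeat_id = 1, arm = arm, field = 1,
               row = 1:6, col = 1, size_px = sizes, size_norm = sizes)
  }
  # ratio 1 -> 0; ratio 10 -> 1; ratio 1e4 -> clipped 2
  plates <- rbind(mk("query", c(100, 100, 1000, 1000, 1e6, 1e6)),
                  mk("control", c(100, 100, 100, 100, 100, 100)))
  gis <- compute_gis(plates, gm)
  expect_equal(gis$gis[gis$gene_id == "a"], 0)
  expect_equal(gis$gis[gis$gene_id == "b"], 1)
  expect_equal(gis$gis[gis$gene_id == "c"], 2)

  # ratio 0.5 -> log10(0.5); independent evaluation via log()
  plates2 <- rbind(mk("query", rep(50, 6)), mk("control", rep(100, 6)))
  gis2 <- compute_gis(plates2, gm)
  expect_equal(unique(gis2$gis), log(0.5) / log(10), tolerance = 1e-12)

  # control median 0 -> +2 if query positive
  plates3 <- rbind(mk("query", rep(10, 6)), mk("control", rep(0, 6)))
  gis3 <- compute_gis(plates3, gm)
  expect_true(all(gis3$gis == 2))

  # excluded genes are dropped
  gis4 <- compute_gis(plates, gm, excluded_genes = "b")
  expect_false("b" %in% gis4$gene_id)
})

test_that("query/control swap negates unclipped GIS", {
  sc <- simulate_colony_screen(n_genes = 60, n_interactors = 6,
                               effect_log10 = -0.4, small_colony_rate = 0,
                               seed = 8)
  norm <- spatial_normalize(sc$plates)
  gis <- compute_gis(norm, sc$gene_map)
  swapped <- norm
  swapped$arm <- ifelse(norm$arm == "query", "control", "query")
  gis_sw <- compute_gis(swapped, sc$gene_map)
  merged <- merge(gis, gis_sw, by = c("gene_id", "repeat_id"))
  expect_equal(merged$gis.x, -merged$gis.y, tolerance = 1e-10)
  expect_true(all(abs(gis$gis) <= 2))
})

test_that("consensus hit calling matches sign enumeration", {
  gis <- data.frame(gene_id = rep(c("g1", "g2"), each = 3),
                    repeat_id = rep(1:3, 2),
                    gis = c(-0.3, -0.2, 0.05, 0.09, 0.09, 0.09))
  hits <- call_hits(gis)
  g1 <- hits[hits$gene_id == "g1", ]
  expect_equal(g1$consensus_call, "negative")
  expect_equal(g1$n_supporting_repeats, 2)
  expect_equal(hits$consensus_call[hits$gene_id == "g2"], "none")

  # Ambiguous: both signs reach min_repeats (4 repeats).
  amb <- data.frame(gene_id = "g", repeat_id = 1:4,
                    gis = c(-0.5, -0.5, 0.5, 0.5))
  h <- call_hits(amb)
  expect_true(h$ambiguous)
  expect_equal(h$consensus_call, "none")

  # Random tables against the enumeration oracle.
  set.seed(21)
  for (i in 1:30) {
    g <- data.frame(gene_id = "x", repeat_id = 1:5,
                    gis = round(runif(5, -0.5, 0.5), 2))
    got <- call_hits(g, cutoff = 0.1, min_repeats = 2)
    expect_equal(got$consensus_call,
                 oracle_consensus(g$gis, 0.1, 2))
  }
})

test_that("full pipeline recovers planted interactions", {
  sc <- simulate_colony_screen(n_genes = 150, n_interactors = 10,
                               effect_log10 = -0.5,
                               gradient_amplitude = 0.3, seed = 13)
  ann <- data.frame(gene_id = c(sc$truth$gene_id, "qryL", "ctlL"),
                    chromosome = "I",
                    position_bp = c(seq(1e6, by = 4e5,
                                        length.out = nrow(sc$truth)),
                                    2e8, 3e8))
  res <- sga_score(sc$plates, sc$gene_map, annotations = ann,
                   query_locus = "qryL", control_locus = "ctlL")
  called <- res$hits$gene_id[res$hits$consensus_call == "negative"]
  planted <- sc$truth$gene_id[sc$truth$true_gis != 0]
  expect_gte(mean(planted %in% called), 0.9)
  expect_true(all(abs(res$gis$gis) <= 2))
})
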