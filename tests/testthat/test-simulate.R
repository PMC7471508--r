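# smaller-than-default specs keep the generator tests fast; the default
# "zeb2-like" spec itself is exercised in the pipeline and acceptance tests
small_spec <- function(seed = 1, ...) {
  simulation_spec(region_length = 4e5, resolution = 20000,
                  tad_boundaries = c(7L, 14L),
                  loops = list(list(bin_i = 4L, bin_j = 11L, gamma = 8)),
                  enhancers = data.frame(start = c(221000, 225000),
                                         end = c(222000, 225600),
                                         motif = c("SOX10", "ETS1")),
                  n_pairs = 2e4, seed = seed, ...)
}

test_that("spec validation rejects inconsistent structure", {
  expect_error(simulation_spec(target_fragment_bp = 10), ">= 50")
  expect_error(simulation_spec(tad_boundaries = c(5L, 500L)), "inside")
  expect_error(simulation_spec(loops = list(list(bin_i = 5L, bin_j = 5L,
                                                 gamma = 2))), "bin_i < bin_j")
  expect_error(simulation_spec(loops = list(list(bin_i = 5L, bin_j = 6L,
                                                 gamma = 2))), ">= 2 bins")
  expect_error(simulation_spec(enhancers = data.frame(
    start = 1, end = 3e6, motif = "SOX10")), "outside")
})

test_that("specs round-trip losslessly through YAML and reject unknown keys", {
  spec <- small_spec()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_spec(spec, tmp)
  back <- read_simulation_spec(tmp)
  expect_equal(unclass(back), unclass(spec))

  lines <- readLines(tmp)
  writeLines(c(lines, "mystery_knob: 3"), tmp)
  expect_error(read_simulation_spec(tmp), "unknown key")
})

test_that("generated genomes hit the target fragment size and are reproducible", {
  spec <- simulation_spec(region_length = 1e6, seed = 7,
                          tad_boundaries = integer(0), loops = list(),
                          enhancers = NULL)
  g <- make_genome(spec)
  st <- fragment_stats(g$fragment_map)
  expect_lt(abs(st$mean - 500) / 500, 0.15)
  # truth map is exactly the digest of the emitted sequence
  fm2 <- digest_region(g$sequence, restriction_enzyme("ApoI"), g$region)
  expect_equal(g$fragment_map$fragments, fm2$fragments)
  # same spec, same seed -> identical sequence
  g2 <- make_genome(simulation_spec(region_length = 1e6, seed = 7,
                                    tad_boundaries = integer(0),
                                    loops = list(), enhancers = NULL))
  expect_identical(g$sequence, g2$sequence)
  g3 <- make_genome(simulation_spec(region_length = 1e6, seed = 8,
                                    tad_boundaries = integer(0),
                                    loops = list(), enhancers = NULL))
  expect_false(identical(g$sequence, g3$sequence))
})

test_that("contact probabilities follow the declared closed form", {
  # alpha = 1, tau = 0, no loops: w proportional to 1/(d+1)
  spec <- simulation_spec(region_length = 1e6, tau = 0, loops = list(),
                          tad_boundaries = integer(0), enhancers = NULL)
  P <- contact_probabilities(spec)
  expect_equal(P[1, 3] / P[1, 10], 10 / 3)
  # d <= 1 carries no probability; upper triangle sums to 1
  expect_true(all(diag(P) == 0))
  expect_true(all(P[cbind(1:49, 2:50)] == 0))
  expect_equal(sum(P[upper.tri(P)]), 1)
  # Toeplitz when no TAD/loop structure
  expect_equal(P[2, 10], P[11, 19])

  # planted loop multiplies exactly one pixel by gamma
  spec_l <- simulation_spec(region_length = 1e6, tau = 0,
                            tad_boundaries = integer(0), enhancers = NULL,
                            loops = list(list(bin_i = 10L, bin_j = 40L,
                                              gamma = 10)))
  P0 <- contact_probabilities(spec)
  Pl <- contact_probabilities(spec_l)
  # compare unnormalized weights: renormalize by another untouched pixel
  expect_equal((Pl[11, 41] / Pl[1, 20]) / (P0[11, 41] / P0[1, 20]), 10)

  # within-TAD enrichment is exp(tau)
  spec_t <- simulation_spec(region_length = 1e6, tau = 1.5, loops = list(),
                            tad_boundaries = c(25L), enhancers = NULL)
  Pt <- contact_probabilities(spec_t)
  # bins (0,9) intra-TAD0; (19,28) cross the boundary at 25; (26,35)
  # intra-TAD1 — all at separation 9
  expect_equal(Pt[1, 10] / Pt[20, 29], exp(1.5))   # intra vs inter
  expect_equal(Pt[1, 10] / Pt[27, 36], 1)          # both intra, same d
  expect_equal(Pt[20, 29] / Pt[27, 36], exp(-1.5)) # inter vs intra
})

test_that("simulated pairs reproduce the truth matrix exactly through the pipeline", {
  spec <- simulation_spec(n_pairs = 5e4, seed = 1)
  sim <- simulate_t2c_experiment(spec, withr::local_tempdir())
  expect_equal(nrow(sim$pairs), 5e4)
  pairs <- read_pairs(sim$paths[["pairs"]])
  expect_equal(nrow(pairs), 5e4)
  cm <- assign_pairs(pairs, sim$genome$fragment_map, filter_config())
  expect_equal(cm$metadata$totals$kept, 5e4)   # nothing dropped by default
  bm <- bin_matrix(cm, spec$resolution)
  expect_equal(as_dense_matrix(bm), as_dense_matrix(sim$truth_matrix))
})

test_that("empirical contact frequency decays with distance", {
  spec <- simulation_spec(tau = 0, loops = list(), n_pairs = 1e5, seed = 9)
  g <- list(region = genomic_interval(spec$chrom, 0, spec$region_length))
  # bin-level check straight from the truth matrix
  set.seed(9)
  bm <- draw_truth_matrix(spec)
  e <- expected_by_distance(bm)
  sel <- e$distance >= 2
  rho <- cor(e$distance[sel], e$expected[sel], method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("planted tracks are recovered by the enhancer and motif callers", {
  spec <- small_spec(seed = 3)
  g <- make_genome(spec)
  planted <- plant_tracks(spec, g)
  # enhancer candidates at the planted intervals (anchor = distal loop bin)
  anchor <- spec_distal_anchor(spec)
  expect_equal(anchor$start, 11 * 20000)
  cand <- call_enhancer_candidates(anchor, planted$peaks,
                                   planted$conservation, merge_gap = 2000)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$start, spec$enhancers$start)
  expect_equal(cand$end, spec$enhancers$end)
  expect_true(all(cand$mean_conservation == 1))
  # planted motif consensus found at the recorded offset with relative 1.0
  hits <- annotate_enhancers(cand, planted$genome$sequence, g$region,
                             toy_motif_set(), threshold = 0.90)
  for (k in seq_len(nrow(planted$truth$motifs))) {
    tm <- planted$truth$motifs[k, ]
    h <- hits[hits$candidate == tm$enhancer & hits$motif == tm$motif &
                hits$offset == tm$offset_rel & hits$strand == "+", ]
    expect_equal(nrow(h), 1)
    expect_equal(h$relative, 1.0)
  }
  # conservation: baseline 0.1 outside enhancers
  outside <- genomic_interval(spec$chrom, 0, 1000)
  expect_equal(mean_conservation(outside, planted$conservation), 0.1)
})

test_that("zero planted enhancers propagate to empty calls", {
  spec <- simulation_spec(region_length = 4e5, resolution = 20000,
                          tad_boundaries = c(7L, 14L),
                          loops = list(list(bin_i = 4L, bin_j = 11L,
                                            gamma = 8)),
                          enhancers = NULL, n_pairs = 1e3, seed = 2)
  g <- make_genome(spec)
  planted <- plant_tracks(spec, g)
  expect_equal(nrow(planted$peaks), 0)
  cand <- call_enhancer_candidates(spec_distal_anchor(spec), planted$peaks,
                                   planted$conservation)
  expect_equal(nrow(cand), 0)
})

test_that("the full generator is byte-identical under a fixed seed", {
  spec <- small_spec(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_t2c_experiment(spec, d1)
  s2 <- simulate_t2c_experiment(spec, d2)
  for (f in names(s1$paths)) {
    p1 <- s1$paths[[f]]; p2 <- s2$paths[[f]]
    if (f %in% c("truth_matrix")) {
      p1 <- paste0(p1, ".triplets.tsv"); p2 <- paste0(p2, ".triplets.tsv")
    }
    expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)),
                     label = sprintf("md5 of %s", f))
  }
})
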