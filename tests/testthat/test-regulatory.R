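# The printed coordinates exercised here are the capture design and
# enhancer-cluster coordinates of the human ZEB2 locus (hg19).

test_that("printed coordinates parse under both conventions", {
  # capture region, printed 1-based inclusive: 7.4 Mb at one decimal
  cap <- parse_genome_coordinate("chr2: 143270465–150642631", "inclusive")
  expect_equal(interval_length(cap), 7372167)
  expect_equal(round(interval_length(cap) / 1e6, 1), 7.4)

  # region A, printed as 20-kb bin edges
  a <- parse_genome_coordinate("chr2:145260000-145280000")
  expect_equal(interval_length(a), 20000)

  # commas tolerated; empty/inverted ranges rejected
  expect_equal(interval_length(parse_genome_coordinate("chr2:145,260,000-145,280,000")),
               20000)
  expect_error(parse_genome_coordinate("chr2:100-100"), "empty")
  expect_error(parse_genome_coordinate("chr2:200-100"), "empty|parse")
  expect_error(parse_genome_coordinate("nonsense"), "parse")
})

test_that("interval distance reproduces the printed locus arithmetic", {
  # ZEB2 is minus-strand: its TSS-side coordinate is the larger printed
  # gene coordinate; distance to the distal anchor rounds to 500 kb
  zeb2 <- parse_genome_coordinate("chr2:145141942-145277958", "inclusive")
  region_b <- parse_genome_coordinate("chr2:145760000-145780000")
  d <- interval_distance(zeb2, region_b)
  expect_equal(d, 482042)
  expect_equal(round(d / 1e5) * 1e5, 5e5)
  expect_equal(interval_distance(region_b, zeb2), d)   # symmetric

  # the two 5-kb loop anchors: start-to-start span 295 kb
  a1 <- parse_genome_coordinate("chr2:145305000-145310000")
  a2 <- parse_genome_coordinate("chr2:145600000-145605000")
  expect_equal(a2$start - a1$start, 295000)

  # overlap -> 0; different chromosomes -> error
  expect_equal(interval_distance(genomic_interval("chr1", 0, 100),
                                 genomic_interval("chr1", 50, 150)), 0)
  expect_error(interval_distance(genomic_interval("chr1", 0, 100),
                                 genomic_interval("chr2", 0, 100)),
               "different chromosomes")
})

test_that("mean conservation is the length-weighted track average", {
  int <- genomic_interval("chr1", 100, 200)
  # constant coverage
  t1 <- data.frame(chrom = "chr1", start = 0, end = 500, score = 0.8)
  expect_equal(mean_conservation(int, t1), 0.8)
  # half covered -> v/2
  t2 <- data.frame(chrom = "chr1", start = 100, end = 150, score = 0.8)
  expect_equal(mean_conservation(int, t2), 0.4)
  # empty / wrong-chromosome tracks -> 0
  expect_equal(mean_conservation(int, t1[0, ]), 0)
  t3 <- t1; t3$chrom <- "chr9"
  expect_equal(mean_conservation(int, t3), 0)
  # overlapping steps are rejected
  t4 <- data.frame(chrom = "chr1", start = c(0, 100), end = c(150, 300),
                   score = c(1, 2))
  expect_error(mean_conservation(int, t4), "overlap")
})

test_that("mean conservation equals the per-base brute-force oracle", {
  set.seed(31)
  for (k in 1:20) {
    edges <- sort(sample(0:400, 9))
    keep <- which(c(TRUE, diff(edges) > 0))
    edges <- edges[keep]
    n_seg <- floor(length(edges) / 2)
    track <- data.frame(chrom = "chr1",
                        start = edges[seq(1, 2 * n_seg, 2)],
                        end = edges[seq(2, 2 * n_seg, 2)],
                        score = round(runif(n_seg), 2))
    int <- genomic_interval("chr1", 50, 350)
    expect_equal(mean_conservation(int, track),
                 naive_mean_conservation(50, 350, track))
  }
})

test_that("the three printed enhancer peaks yield three named candidates", {
  region_b <- parse_genome_coordinate("chr2:145760000-145780000")
  peaks <- rbind(
    .gi_df(parse_genome_coordinate("chr2:145764483-145765504", "inclusive")),
    .gi_df(parse_genome_coordinate("chr2:145769677-145770210", "inclusive")),
    .gi_df(parse_genome_coordinate("chr2:145779965-145780193", "inclusive")))
  cand <- call_enhancer_candidates(region_b, peaks, merge_gap = 2000)
  expect_equal(nrow(cand), 3)
  expect_equal(cand$name, c("Enh1", "Enh2", "Enh3"))
  # any-overlap: Enh3 extends past the anchor end and is kept whole
  expect_gt(cand$end[3], region_b$end)
  # with truncation requested it is clipped instead
  cand_t <- call_enhancer_candidates(region_b, peaks, merge_gap = 2000,
                                     truncate = TRUE)
  expect_equal(cand_t$end[3], region_b$end)
})

test_that("peak merging follows the gap rule and matches the naive oracle", {
  anchor <- genomic_interval("chr1", 0, 100000)
  # two peaks 1,500 bp apart: merged at gap 2,000, separate at 1,000
  peaks <- data.frame(chrom = "chr1", start = c(10000, 12500),
                      end = c(11000, 13000))
  expect_equal(nrow(call_enhancer_candidates(anchor, peaks,
                                             merge_gap = 2000)), 1)
  expect_equal(nrow(call_enhancer_candidates(anchor, peaks,
                                             merge_gap = 1000)), 2)

  set.seed(17)
  for (k in 1:20) {
    n <- sample(2:8, 1)
    starts <- sort(sample(0:90000, n))
    ends <- starts + sample(200:3000, n, replace = TRUE)
    gap <- sample(c(0, 500, 2000), 1)
    cand <- call_enhancer_candidates(anchor, data.frame(
      chrom = "chr1", start = starts, end = ends), merge_gap = gap)
    # peaks may overlap each other; the oracle merge handles containment
    oracle <- naive_merge(starts, pmax(ends, starts + 1), gap)
    expect_equal(cand$start, oracle$start)
    expect_equal(cand$end, oracle$end)
    expect_equal(sum(cand$n_peaks), n)
  }
})

test_that("candidate calling is idempotent and permutation-stable", {
  anchor <- genomic_interval("chr1", 0, 50000)
  set.seed(23)
  starts <- sort(sample(0:45000, 6))
  peaks <- data.frame(chrom = "chr1", start = starts, end = starts + 800)
  cand <- call_enhancer_candidates(anchor, peaks, merge_gap = 1500)
  # merging the merged candidates changes nothing
  again <- call_enhancer_candidates(
    anchor, data.frame(chrom = cand$chrom, start = cand$start,
                       end = cand$end), merge_gap = 1500)
  expect_equal(again$start, cand$start)
  expect_equal(again$end, cand$end)
  # input permutation does not change names or intervals
  perm <- peaks[sample(nrow(peaks)), ]
  cand2 <- call_enhancer_candidates(anchor, perm, merge_gap = 1500)
  expect_equal(cand2, cand)
})

test_that("conservation filtering and empty inputs behave as declared", {
  anchor <- genomic_interval("chr1", 0, 10000)
  expect_equal(nrow(call_enhancer_candidates(anchor, NULL)), 0)
  expect_equal(nrow(call_enhancer_candidates(
    anchor, data.frame(chrom = "chr2", start = 1, end = 5))), 0)
  peaks <- data.frame(chrom = "chr1", start = c(1000, 5000),
                      end = c(1500, 5500))
  cons <- data.frame(chrom = "chr1", start = 1000, end = 1500, score = 1)
  cand <- call_enhancer_candidates(anchor, peaks, cons, min_cons = 0.5)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 1000)
  expect_equal(cand$mean_conservation, 1)
})

test_that("candidates serialize to BED + JSON", {
  anchor <- genomic_interval("chr1", 0, 10000)
  peaks <- data.frame(chrom = "chr1", start = c(1000, 5000),
                      end = c(1500, 5500))
  cand <- call_enhancer_candidates(anchor, peaks)
  tmp <- withr::local_tempdir()
  paths <- write_enhancer_candidates(cand, file.path(tmp, "enh"))
  bed <- read_bed(paths[["bed"]])
  expect_equal(bed$start, cand$start)
  expect_equal(bed$name, cand$name)
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$name, cand$name)
})
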