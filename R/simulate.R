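#' Specification of a synthetic capture experiment
#'
#' Describes everything the generator needs: a capture region with a target
#' restriction-fragment spacing, a bin-level contact model (power-law
#' distance decay, within-TAD enrichment, planted point loops), planted
#' enhancers carrying named motif instances, a read-pair budget and a seed.
#' The defaults describe the shipped "zeb2-like" experiment: a 2-Mb region
#' at 20-kb resolution (100 bins) with three TADs, one loop spanning 25
#' bins whose distal anchor holds three enhancers — the synthetic analogue
#' of a promoter contacting a cluster of distal regulatory elements across
#' several hundred kb.
#'
#' The contact model assigns pixel `(i, j)`, `|i - j| >= 2`, the
#' unnormalized weight
#' `(|i - j| + 1)^(-alpha) * exp(tau * same_tad) * gamma_loop`,
#' normalized to sum 1 over the upper triangle; separations 0 and 1 carry
#' zero probability, mirroring their exclusion from loop calling.
#'
#' @param region_length capture-region length in bp.
#' @param chrom synthetic chromosome name.
#' @param target_fragment_bp target mean restriction-fragment size
#'   (>= 50, < 1024; planted site spacing is adjusted for the background
#'   site rate of uniform sequence so the overall mean hits the target).
#' @param resolution bin width in bp.
#' @param tad_boundaries 0-based bin indices at which a new TAD starts.
#' @param alpha distance-decay exponent (> 0).
#' @param tau within-TAD log-enrichment (>= 0); contacts inside one TAD are
#'   `exp(tau)`-fold enriched.
#' @param loops list of `list(bin_i, bin_j, gamma)` planted point loops
#'   (0-based bins, `bin_i < bin_j`, `gamma >= 1`).
#' @param enhancers data.frame `start`, `end`, `motif` (region coordinates,
#'   0-based half-open) of planted enhancers; motif names must exist in
#'   [toy_motif_set()] (or the profile set passed to [plant_tracks()]).
#' @param n_pairs number of ligation pairs to simulate.
#' @param seed RNG seed; all generator randomness derives from it.
#' @return a `simulation_spec` object.
#' @export
simulation_spec <- function(region_length = 2e6,
                            chrom = "chrS",
                            target_fragment_bp = 500,
                            resolution = 20000,
                            tad_boundaries = c(15L, 75L),
                            alpha = 1,
                            tau = 1,
                            loops = list(list(bin_i = 30L, bin_j = 55L,
                                              gamma = 8)),
                            enhancers = data.frame(
                              start = c(1104000, 1108600, 1119000),
                              end = c(1105000, 1109200, 1119300),
                              motif = c("SOX10", "ETS1", "HOXB2")),
                            n_pairs = 1e5,
                            seed = 1L) {
  if (target_fragment_bp < 50) stop("target_fragment_bp must be >= 50")
  if (alpha <= 0) stop("alpha must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  n_bins <- ceiling(region_length / resolution)
  tad_boundaries <- sort(as.integer(tad_boundaries))
  if (length(tad_boundaries) &&
      (min(tad_boundaries) < 1L || max(tad_boundaries) >= n_bins))
    stop("tad_boundaries must be bin indices strictly inside the region")
  for (lp in loops) {
    if (lp$bin_i >= lp$bin_j) stop("loop bins must satisfy bin_i < bin_j")
    if (lp$bin_j - lp$bin_i < 2L) stop("loop separation must be >= 2 bins")
    if (lp$bin_j >= n_bins) stop("loop bin beyond region")
    if (lp$gamma < 1) stop("loop gamma must be >= 1")
  }
  if (!is.null(enhancers) && nrow(enhancers)) {
    if (any(enhancers$start >= enhancers$end))
      stop("enhancer intervals must be non-empty")
    if (any(enhancers$start < 0 | enhancers$end > region_length))
      stop("enhancer outside region")
  }
  structure(list(region_length = region_length, chrom = chrom,
                 target_fragment_bp = target_fragment_bp,
                 resolution = resolution,
                 tad_boundaries = tad_boundaries,
                 alpha = alpha, tau = tau, loops = loops,
                 enhancers = enhancers, n_pairs = n_pairs,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @exportS3Method base::print
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %s bp, %s-bp bins, %d TADs, %d loop(s), %d enhancer(s), %s pairs, seed %d\n",
    format(x$region_length, scientific = FALSE),
    format(x$resolution, scientific = FALSE),
    length(x$tad_boundaries) + 1L, length(x$loops),
    if (is.null(x$enhancers)) 0L else nrow(x$enhancers),
    format(x$n_pairs, scientific = FALSE), x$seed))
  invisible(x)
}

#' Serialize / restore a simulation spec (YAML)
#'
#' Round-trips losslessly; unknown keys in the file are rejected.
#'
#' @param spec a [simulation_spec()].
#' @param path file path.
#' @return `write_simulation_spec`: `path` invisibly;
#'   `read_simulation_spec`: the restored spec.
#' @export
write_simulation_spec <- function(spec, path) {
  x <- unclass(spec)
  x$enhancers <- if (is.null(x$enhancers)) list() else
    lapply(seq_len(nrow(x$enhancers)), function(k)
      list(start = x$enhancers$start[k], end = x$enhancers$end[k],
           motif = x$enhancers$motif[k]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_spec
#' @export
read_simulation_spec <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("region_length", "chrom", "target_fragment_bp", "resolution",
             "tad_boundaries", "alpha", "tau", "loops", "enhancers",
             "n_pairs", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop(sprintf("unknown key(s) in simulation spec: %s",
                 paste(unknown, collapse = ", ")))
  enh <- if (!length(x$enhancers)) NULL else
    data.frame(start = vapply(x$enhancers, `[[`, numeric(1), "start"),
               end = vapply(x$enhancers, `[[`, numeric(1), "end"),
               motif = vapply(x$enhancers, `[[`, character(1), "motif"))
  simulation_spec(region_length = x$region_length, chrom = x$chrom,
                  target_fragment_bp = x$target_fragment_bp,
                  resolution = x$resolution,
                  tad_boundaries = unlist(x$tad_boundaries),
                  alpha = x$alpha, tau = x$tau,
                  loops = x$loops, enhancers = enh,
                  n_pairs = x$n_pairs, seed = x$seed)
}

#' Built-in synthetic motif profiles
#'
#' Five toy count profiles named after transcription factors commonly
#' scanned for in enhancer analyses (ETS1, FOXD2, HOXB2, SOX10, YY1). They
#' are synthetic near-deterministic profiles built in code — one dominant
#' base per column — not database entries; their consensus sequences avoid
#' the ApoI core `AATT` so planting them does not systematically add
#' restriction sites.
#'
#' @param dominant count given to the consensus base per column (others
#'   get 1).
#' @return named list of [pwm()] objects.
#' @export
toy_motif_set <- function(dominant = 97) {
  consensi <- c(ETS1 = "ACCGGAAGTG", FOXD2 = "TGTTTACTTTG",
                HOXB2 = "TGATTAATGG", SOX10 = "AACAATGGC",
                YY1 = "GCCGCCATTTT")
  lapply(stats::setNames(names(consensi), names(consensi)), function(nm) {
    b <- .base_codes(consensi[[nm]])
    m <- matrix(1, nrow = 4, ncol = length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(b, seq_along(b))] <- dominant
    pwm(nm, m)
  })
}

#' Generate a synthetic capture-region genome
#'
#' Emits i.i.d. uniform background bases with concrete ApoI sites
#' (instances of `RAATTY`) planted at exponential spacing. Uniform sequence
#' already contains `RAATTY` once per 1024 bp on average (4 of the 4096
#' hexamers match), so the planted spacing is chosen such that planted plus
#' background sites together give the target mean fragment size. The truth
#' fragment map is obtained by digesting the emitted sequence, so it is
#' exact by construction, background sites included.
#'
#' @param spec a [simulation_spec()].
#' @return list with `sequence` (character string), `region`
#'   (a [genomic_interval()]) and `fragment_map` (the ApoI digest of the
#'   emitted sequence).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  L <- spec$region_length
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  p_background <- 4 / 4096           # RAATTY hexamers under uniform bases
  rate <- 1 / spec$target_fragment_bp - p_background
  if (rate <= 0)
    stop("target_fragment_bp must be below the background spacing (1024 bp)")
  mean_gap <- 1 / rate
  n_est <- ceiling(L * rate * 1.3) + 25L
  gaps <- 6 + round(stats::rexp(n_est, rate = 1 / (mean_gap - 6)))
  starts <- cumsum(gaps)
  starts <- starts[starts + 6 <= L]
  if (length(starts)) {
    r_base <- sample(c("A", "G"), length(starts), replace = TRUE)
    y_base <- sample(c("C", "T"), length(starts), replace = TRUE)
    for (k in seq_along(starts)) {
      s <- starts[k]  # 0-based site start
      bases[(s + 1):(s + 6)] <- c(r_base[k], "A", "A", "T", "T", y_base[k])
    }
  }
  sequence <- paste(bases, collapse = "")
  region <- genomic_interval(spec$chrom, 0, L)
  fm <- digest_region(sequence, restriction_enzyme("ApoI"), region)
  list(sequence = sequence, region = region, fragment_map = fm)
}

#' Bin-level contact probabilities of a simulation spec
#'
#' @param spec a [simulation_spec()].
#' @return an `n x n` symmetric matrix of probabilities; zero on the
#'   diagonal and at separation 1, normalized so the upper triangle sums
#'   to 1.
#' @export
contact_probabilities <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- ceiling(spec$region_length / spec$resolution)
  bin0 <- 0:(n - 1L)
  tad <- findInterval(bin0, spec$tad_boundaries)
  d <- abs(outer(bin0, bin0, "-"))
  w <- (d + 1)^(-spec$alpha)
  same <- outer(tad, tad, "==")
  w <- w * exp(spec$tau * same)
  for (lp in spec$loops) {
    i <- lp$bin_i + 1L
    j <- lp$bin_j + 1L
    w[i, j] <- w[i, j] * lp$gamma
    w[j, i] <- w[j, i] * lp$gamma
  }
  w[d < 2] <- 0
  w / sum(w[upper.tri(w)])
}

# uniform draw of one element of pool[[b]] for every entry of `bins`
.sample_in_bins <- function(bins, pool) {
  out <- integer(length(bins))
  for (b in unique(bins)) {
    sel <- which(bins == b)
    ids <- pool[[b]]
    out[sel] <- if (length(ids) == 1L) rep(ids, length(sel))
      else sample(ids, length(sel), replace = TRUE)
  }
  out
}

#' Simulate ligation pairs from the bin-level contact model
#'
#' Draws `n_pairs` bin pairs from [contact_probabilities()], then places
#' each endpoint at a uniform position inside a uniformly chosen fragment
#' whose midpoint lies in the bin — the same midpoint rule [bin_matrix()]
#' uses, so running [assign_pairs()] + [bin_matrix()] on the emitted pairs
#' with default filters reproduces the truth matrix exactly.
#'
#' @param spec a [simulation_spec()].
#' @param genome result of [make_genome()] (or the same structure with a
#'   post-[plant_tracks()] fragment map).
#' @return list with `pairs` (data.frame in [read_pairs()] layout) and
#'   `truth_matrix` (binned `contact_matrix` of the drawn counts).
#' @export
simulate_pairs <- function(spec, genome) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$n_pairs < 1) stop("n_pairs must be >= 1")
  set.seed(spec$seed + 1L)
  P <- contact_probabilities(spec)
  n <- nrow(P)
  region <- genome$region
  fm <- genome$fragment_map
  ut <- which(upper.tri(P), arr.ind = TRUE)
  probs <- P[ut]
  counts <- as.vector(stats::rmultinom(1, spec$n_pairs, probs))
  nz <- counts > 0
  truth <- Matrix::sparseMatrix(i = ut[nz, 1], j = ut[nz, 2], x = counts[nz],
                                dims = c(n, n))
  truth_cm <- .new_contact_matrix(
    "bin", .make_bins(region, spec$resolution), region, truth,
    list(source = "simulation truth", seed = spec$seed,
         totals = list(input = spec$n_pairs, kept = spec$n_pairs,
                       dropped = list())),
    resolution = spec$resolution)
  idx <- rep(seq_along(probs), counts)
  bi <- ut[idx, 1]
  bj <- ut[idx, 2]
  # fragments eligible per bin (midpoint rule, as in bin_matrix)
  mid <- (fm$fragments$start + fm$fragments$end) / 2
  fbin <- pmin(floor((mid - region$start) / spec$resolution) + 1L, n)
  pool <- split(seq_len(nrow(fm$fragments)), factor(fbin, levels = 1:n))
  if (any(!lengths(pool)))
    stop("a bin contains no fragment midpoint; increase bin size or region")
  f1 <- .sample_in_bins(bi, pool)
  f2 <- .sample_in_bins(bj, pool)
  w1 <- fm$fragments$end[f1] - fm$fragments$start[f1]
  w2 <- fm$fragments$end[f2] - fm$fragments$start[f2]
  p1 <- fm$fragments$start[f1] + floor(stats::runif(length(f1)) * w1)
  p2 <- fm$fragments$start[f2] + floor(stats::runif(length(f2)) * w2)
  N <- length(f1)
  ord <- sample.int(max(N, 1L))
  pairs <- data.frame(
    read_id = sprintf("sim%07d", seq_len(N)),
    chrom1 = region$chrom, pos1 = p1[ord] + 1,
    strand1 = sample(c("+", "-"), N, replace = TRUE),
    chrom2 = region$chrom, pos2 = p2[ord] + 1,
    strand2 = sample(c("+", "-"), N, replace = TRUE),
    mapq1 = 60L, mapq2 = 60L, stringsAsFactors = FALSE)
  # keep mate bins matched with positions after the shuffle
  list(pairs = pairs, truth_matrix = truth_cm)
}

#' Plant peaks, conservation and motif instances over the enhancers
#'
#' Writes the consensus of each enhancer's named motif into the genome
#' sequence at the enhancer's centre, emits one H3K27ac-style peak per
#' enhancer, and builds a conservation track with score 1.0 over enhancers
#' on a 0.1 baseline. All planted facts are returned as a truth record.
#' Because editing the sequence can create or destroy restriction sites,
#' the fragment map in the returned genome is re-digested from the edited
#' sequence.
#'
#' @param spec a [simulation_spec()].
#' @param genome result of [make_genome()].
#' @param pwms motif profiles to draw consensi from (default
#'   [toy_motif_set()]).
#' @return list with `genome` (edited sequence + refreshed fragment map),
#'   `peaks` (data.frame), `conservation` (data.frame) and `truth`
#'   (list: `enhancers` data.frame, `motifs` data.frame with absolute and
#'   enhancer-relative planted offsets).
#' @export
plant_tracks <- function(spec, genome, pwms = toy_motif_set()) {
  stopifnot(inherits(spec, "simulation_spec"))
  region <- genome$region
  enh <- spec$enhancers
  baseline <- 0.1
  if (is.null(enh) || !nrow(enh)) {
    cons <- data.frame(chrom = region$chrom, start = region$start,
                       end = region$end, score = baseline)
    return(list(genome = genome,
                peaks = data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), name = character()),
                conservation = cons,
                truth = list(enhancers = enh,
                             motifs = data.frame(motif = character(),
                                                 enhancer = character(),
                                                 offset_abs = numeric(),
                                                 offset_rel = numeric()))))
  }
  if (any(enh$start < region$start | enh$end > region$end))
    stop("enhancer outside region")
  enh <- enh[order(enh$start), , drop = FALSE]
  missing <- setdiff(enh$motif, names(pwms))
  if (length(missing))
    stop(sprintf("no profile for planted motif(s): %s",
                 paste(missing, collapse = ", ")))
  bases <- strsplit(genome$sequence, "")[[1]]
  motifs <- data.frame(motif = character(), enhancer = character(),
                       offset_abs = numeric(), offset_rel = numeric())
  for (k in seq_len(nrow(enh))) {
    cons_seq <- pwm_consensus(pwms[[enh$motif[k]]])
    Lm <- nchar(cons_seq)
    if (Lm > enh$end[k] - enh$start[k])
      stop(sprintf("enhancer %d shorter than motif %s", k, enh$motif[k]))
    off <- enh$start[k] + floor((enh$end[k] - enh$start[k] - Lm) / 2)
    bases[(off + 1):(off + Lm)] <- strsplit(cons_seq, "")[[1]]
    motifs <- rbind(motifs, data.frame(
      motif = enh$motif[k], enhancer = sprintf("Enh%d", k),
      offset_abs = off, offset_rel = off - enh$start[k]))
  }
  sequence <- paste(bases, collapse = "")
  fm <- digest_region(sequence, restriction_enzyme("ApoI"), region)
  genome$sequence <- sequence
  genome$fragment_map <- fm
  peaks <- data.frame(chrom = region$chrom, start = enh$start,
                      end = enh$end,
                      name = sprintf("peak_%d", seq_len(nrow(enh))))
  # conservation: 0.1 baseline with 1.0 steps over the (sorted) enhancers
  edges <- sort(unique(c(region$start, enh$start, enh$end, region$end)))
  seg <- data.frame(start = edges[-length(edges)], end = edges[-1])
  in_enh <- vapply(seq_len(nrow(seg)), function(i)
    any(seg$start[i] >= enh$start & seg$end[i] <= enh$end), logical(1))
  cons <- data.frame(chrom = region$chrom, start = seg$start, end = seg$end,
                     score = ifelse(in_enh, 1.0, baseline))
  truth_enh <- data.frame(name = sprintf("Enh%d", seq_len(nrow(enh))),
                          chrom = region$chrom, start = enh$start,
                          end = enh$end, motif = enh$motif)
  list(genome = genome, peaks = peaks, conservation = cons,
       truth = list(enhancers = truth_enh, motifs = motifs))
}

#' Distal anchor interval of a simulation spec's strongest loop
#'
#' @param spec a [simulation_spec()].
#' @return a [genomic_interval()] covering the downstream (`bin_j`) anchor
#'   bin of the maximal-gamma loop.
#' @export
spec_distal_anchor <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!length(spec$loops)) stop("spec has no planted loops")
  gam <- vapply(spec$loops, `[[`, numeric(1), "gamma")
  lp <- spec$loops[[which.max(gam)]]
  s <- lp$bin_j * spec$resolution
  genomic_interval(spec$chrom, s, min(s + spec$resolution,
                                      spec$region_length))
}

#' Run the full generator and write every pipeline input to a directory
#'
#' Stages: genome generation, track/motif planting, digestion of the final
#' sequence, pair simulation. Writes `genome.fa`, `fragments.bed`,
#' `pairs.tsv`, the truth matrix (`truth_matrix.triplets.tsv` + sidecar),
#' `peaks.bed`, `conservation.bedGraph`, `motifs.jaspar`, `spec.yaml` and
#' `truth.json`. Byte-identical outputs under a fixed seed.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if missing).
#' @param pwms motif profiles (default [toy_motif_set()]).
#' @return list with the in-memory objects (`genome`, `pairs`,
#'   `truth_matrix`, `peaks`, `conservation`, `truth`, `paths`).
#' @export
simulate_t2c_experiment <- function(spec, out_dir, pwms = toy_motif_set()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(spec)
  planted <- plant_tracks(spec, genome, pwms = pwms)
  genome <- planted$genome
  sim <- simulate_pairs(spec, genome)
  paths <- c(fasta = file.path(out_dir, "genome.fa"),
             fragments = file.path(out_dir, "fragments.bed"),
             pairs = file.path(out_dir, "pairs.tsv"),
             truth_matrix = file.path(out_dir, "truth_matrix"),
             peaks = file.path(out_dir, "peaks.bed"),
             conservation = file.path(out_dir, "conservation.bedGraph"),
             motifs = file.path(out_dir, "motifs.jaspar"),
             spec = file.path(out_dir, "spec.yaml"),
             truth = file.path(out_dir, "truth.json"))
  seqset <- Biostrings::DNAStringSet(genome$sequence)
  names(seqset) <- spec$chrom
  Biostrings::writeXStringSet(seqset, paths["fasta"], width = 80)
  write_fragment_bed(genome$fragment_map, paths["fragments"])
  write_pairs(sim$pairs, paths["pairs"])
  write_matrix(sim$truth_matrix, paths["truth_matrix"])
  if (nrow(planted$peaks)) write_bed(planted$peaks, paths["peaks"])
  else file.create(paths["peaks"])
  write_bedgraph(planted$conservation, paths["conservation"])
  write_jaspar(pwms, paths["motifs"])
  write_simulation_spec(spec, paths["spec"])
  jsonlite::write_json(planted$truth, paths["truth"], auto_unbox = FALSE,
                       digits = NA, dataframe = "columns")
  list(genome = genome, pairs = sim$pairs, truth_matrix = sim$truth_matrix,
       peaks = planted$peaks, conservation = planted$conservation,
       truth = planted$truth, paths = paths)
}
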