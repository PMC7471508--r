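# Independent brute-force oracles used to validate the vectorized /
# library-backed implementations. These deliberately share no code with the
# package internals.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# position-by-position scan; N in the sequence matches nothing but N
naive_cut_scan <- function(sequence, pattern, cut_offset) {
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  L <- length(p)
  hits <- integer(0)
  for (i in seq_len(length(s) - L + 1)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      base <- s[i + k - 1]
      if (base == "N") {
        if (p[k] != "N") { ok <- FALSE; break }
      } else if (!(base %in% IUPAC_SETS[[p[k]]])) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, i - 1L + cut_offset)
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# double-loop insulation values (raw window means), NA outside w..n-1-w
naive_insulation_raw <- function(m, w) {
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (i0 in w:(n - 1 - w)) {       # 0-based bin index
    acc <- c()
    for (a0 in (i0 - w + 1):i0) {
      for (b0 in (i0 + 1):(i0 + w)) {
        acc <- c(acc, m[a0 + 1, b0 + 1])
      }
    }
    raw[i0 + 1] <- mean(acc)
  }
  raw
}

# per-window brute-force PWM scorer; returns data.frame(offset, strand, rel)
naive_pwm_scan <- function(sequence, counts, pseudocount = 0.8,
                           bg = rep(0.25, 4)) {
  p <- sweep(counts + pseudocount * bg, 2, colSums(counts) + pseudocount, "/")
  lo <- log2(p / bg)
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- ncol(counts)
  out <- NULL
  score1 <- function(win) {
    tot <- 0
    for (k in seq_len(L)) {
      r <- match(win[k], c("A", "C", "G", "T"))
      if (is.na(r)) return(NA_real_)
      tot <- tot + lo[r, k]
    }
    tot
  }
  for (off in 0:(length(s) - L)) {
    win <- s[(off + 1):(off + L)]
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rev(unname(rc[win]))
      sc <- score1(w)
      if (is.na(sc)) next
      rel <- if (smax == smin) 1.0 else (sc - smin) / (smax - smin)
      out <- rbind(out, data.frame(offset = off, strand = strand,
                                   score = sc, rel = rel))
    }
  }
  out
}

# greedy interval merge (0-based half-open), merges when gap <= max_gap
naive_merge <- function(starts, ends, max_gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- NULL
  for (k in seq_along(starts)[-1]) {
    if (starts[k] - me <= max_gap) {
      me <- max(me, ends[k])
    } else {
      out <- rbind(out, data.frame(start = ms, end = me))
      ms <- starts[k]; me <- ends[k]
    }
  }
  rbind(out, data.frame(start = ms, end = me))
}

# per-base mean conservation oracle
naive_mean_conservation <- function(int_start, int_end, track) {
  vals <- numeric(int_end - int_start)
  for (b in int_start:(int_end - 1)) {
    hit <- which(track$start <= b & track$end > b)
    vals[b - int_start + 1] <- if (length(hit)) track$score[hit[1]] else 0
  }
  mean(vals)
}

revcomp_chr <- function(s) {
  rc <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
          R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
          B = "V", V = "B", D = "H", H = "D")
  paste(rev(unname(rc[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

# simulate a binned truth matrix directly at the bin level (no reads):
# the same multinomial draw simulate_pairs performs, for fast recovery tests
draw_truth_matrix <- function(spec) {
  P <- contact_probabilities(spec)
  n <- nrow(P)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  cnt <- as.vector(stats::rmultinom(1, spec$n_pairs, P[ut]))
  m <- matrix(0, n, n)
  m[ut] <- cnt
  m <- m + t(m)
  contact_matrix_from_dense(
    m, genomic_interval(spec$chrom, 0, spec$region_length), spec$resolution)
}

.gi_df <- function(gi) {
  data.frame(chrom = gi$chrom, start = gi$start, end = gi$end)
}
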