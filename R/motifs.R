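#' Position weight matrices from count profiles
#'
#' A `pwm` holds a 4 x L count matrix (rows A, C, G, T), a pseudocount and
#' background base frequencies. Scoring uses the log2-odds matrix
#' `log2(p / bg)` with `p = (count + pseudocount * bg) / (colsum +
#' pseudocount)` — the pseudocount (default 0.8) is split across bases in
#' proportion to the background, the convention used by standard
#' motif-database tooling.
#'
#' @param name motif name.
#' @param counts 4 x L numeric matrix of non-negative counts; rows in order
#'   A, C, G, T (rownames, if present, are checked).
#' @param pseudocount total pseudocount added per column (default 0.8).
#' @param background base frequencies A, C, G, T summing to 1 (default
#'   uniform).
#' @return a `pwm` object.
#' @export
pwm <- function(name, counts, pseudocount = 0.8,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), c("A", "C", "G", "T")))
    stop("count matrix rows must be in order A, C, G, T")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be non-negative and finite")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 positive frequencies summing to 1")
  if (any(colSums(counts) + pseudocount <= 0))
    stop("every column must have positive total after pseudocount")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts, pseudocount = pseudocount,
                 background = background),
            class = "pwm")
}

#' @exportS3Method base::print
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  length %d  consensus %s\n",
              x$name, ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' Log2-odds scoring matrix of a PWM
#'
#' @param x a [pwm()].
#' @return 4 x L numeric matrix.
#' @export
pwm_log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  cs <- colSums(x$counts)
  p <- sweep(x$counts + x$pseudocount * x$background, 2,
             cs + x$pseudocount, "/")
  log2(p / x$background)
}

#' Consensus sequence (maximal-count base per column) of a PWM
#'
#' @param x a [pwm()].
#' @return character string of length L.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read motif count profiles in JASPAR PFM text format
#'
#' Accepts the standard format: a `>ID name` header followed by four rows
#' `A [ n1 n2 ... ]` (brackets and row labels optional). Rows of unequal
#' length abort with the offending record name.
#'
#' @param path file path, or a character vector of lines via `text =`.
#' @param text optional character vector of lines instead of a file.
#' @param pseudocount,background passed to [pwm()].
#' @return list of [pwm()] objects, named by motif name.
#' @export
read_jaspar <- function(path = NULL, text = NULL, pseudocount = 0.8,
                        background = rep(0.25, 4)) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("no '>' record headers found")
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    header <- sub("^>\\s*", "", lines[hdr[k]])
    toks <- strsplit(header, "\\s+")[[1]]
    mname <- if (length(toks) >= 2L) toks[2] else toks[1]
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L)
      stop(sprintf("record '%s': expected 4 count rows, found %d",
                   mname, length(body)))
    rows <- lapply(body, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(v)))
        stop(sprintf("record '%s': non-numeric count value", mname))
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop(sprintf("record '%s': ragged count rows (lengths %s)",
                   mname, paste(lengths(rows), collapse = ", ")))
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[mname]] <- pwm(mname, m, pseudocount = pseudocount,
                        background = background)
  }
  out
}

#' Write motif profiles in JASPAR PFM text format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (x in pwms) {
    writeLines(sprintf(">%s %s", x$name, x$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(x$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

# relative score of raw log-odds scores given the per-column attainable
# extremes; when max == min every window scores 1.0 (degenerate flat PWM)
.relative_score <- function(raw, lo) {
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  if (smax == smin) return(rep(1.0, length(raw)))
  (raw - smin) / (smax - smin)
}

.base_codes <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  match(v, c("A", "C", "G", "T"))  # NA for N / other ambiguity codes
}

# score every window of `codes` (base indices, NA = ambiguous) against a
# 4 x L log-odds matrix; windows containing NA score NA
.score_windows <- function(codes, lo) {
  L <- ncol(lo)
  W <- length(codes) - L + 1L
  if (W < 1L) return(numeric(0))
  s <- numeric(W)
  ok <- rep(TRUE, W)
  for (k in seq_len(L)) {
    b <- codes[k:(k + W - 1L)]
    na <- is.na(b)
    ok <- ok & !na
    b[na] <- 1L
    s <- s + lo[cbind(b, k)]
  }
  s[!ok] <- NA_real_
  s
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Every window on both strands is scored with the log2-odds matrix; the
#' raw score is rescaled to a relative score in `[0, 1]` between the
#' minimal and maximal attainable scores (motif-database "profile score"
#' convention, where a ">90% confidence" scan means threshold 0.90).
#' Minus-strand hits score the reverse complement of the window; the
#' reported offset is always the window start on the given sequence.
#' Windows containing `N` are skipped. For a degenerate PWM whose columns
#' are flat (max == min attainable score) every window scores 1.0.
#'
#' @param sequence nucleotide string.
#' @param x a [pwm()].
#' @param threshold minimum relative score in `[0, 1]` (default 0.90).
#' @param seq_name sequence name recorded on the hits.
#' @return data.frame `seq_name`, `motif`, `offset` (0-based), `strand`,
#'   `score` (log2-odds), `relative`, ordered by (offset, strand `+` before
#'   `-`). A sequence shorter than the motif yields an empty result with a
#'   warning.
#' @export
scan_pwm <- function(sequence, x, threshold = 0.90, seq_name = "seq") {
  stopifnot(inherits(x, "pwm"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  L <- ncol(x$counts)
  empty <- data.frame(seq_name = character(), motif = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), relative = numeric())
  if (nchar(sequence) < L) {
    warning(sprintf("sequence '%s' (%d bp) shorter than motif %s (%d bp)",
                    seq_name, nchar(sequence), x$name, L))
    return(empty)
  }
  lo <- pwm_log_odds(x)
  # minus strand: scoring revcomp(window) against lo == scoring the window
  # against lo with rows complemented and columns reversed
  lo_rc <- lo[4:1, L:1, drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  codes <- .base_codes(sequence)
  res <- list()
  for (strand in c("+", "-")) {
    raw <- .score_windows(codes, if (strand == "+") lo else lo_rc)
    rel <- .relative_score(raw, lo)
    hit <- which(!is.na(raw) & rel >= threshold)
    if (length(hit))
      res[[strand]] <- data.frame(seq_name = seq_name, motif = x$name,
                                  offset = hit - 1L, strand = strand,
                                  score = raw[hit], relative = rel[hit])
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan enhancer candidates with a set of motif profiles
#'
#' Extracts each candidate's sequence from the capture-region sequence and
#' scans it with every profile at the given relative-score threshold.
#' Offsets in the result are relative to the candidate start.
#'
#' @param candidates data.frame from [call_enhancer_candidates()] (needs
#'   `name`, `chrom`, `start`, `end`).
#' @param sequence capture-region nucleotide string.
#' @param region the [genomic_interval()] the sequence covers.
#' @param pwms list of [pwm()] objects.
#' @param threshold relative-score threshold (default 0.90).
#' @return data.frame `candidate`, `motif`, `offset`, `strand`, `score`,
#'   `relative`, ordered by (candidate, offset, strand `+` before `-`,
#'   motif name).
#' @export
annotate_enhancers <- function(candidates, sequence, region, pwms,
                               threshold = 0.90) {
  stopifnot(inherits(region, "genomic_interval"))
  empty <- data.frame(candidate = character(), motif = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), relative = numeric())
  if (is.null(candidates) || !nrow(candidates)) return(empty)
  res <- list()
  for (k in seq_len(nrow(candidates))) {
    cs <- candidates$start[k]
    ce <- candidates$end[k]
    if (candidates$chrom[k] != region$chrom ||
        cs < region$start || ce > region$end)
      stop(sprintf("candidate '%s' lies outside the sequence region",
                   candidates$name[k]))
    sub <- substr(sequence, cs - region$start + 1, ce - region$start)
    for (x in pwms) {
      h <- suppressWarnings(scan_pwm(sub, x, threshold = threshold,
                                     seq_name = candidates$name[k]))
      if (nrow(h)) res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  names(out)[names(out) == "seq_name"] <- "candidate"
  out <- out[order(out$candidate, out$offset, out$strand, out$motif), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as TSV
#'
#' @param hits data.frame from [annotate_enhancers()] or [scan_pwm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
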