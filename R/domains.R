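#' Insulation profile of a binned contact matrix
#'
#' The insulation value of bin `i` is the mean contact count in the `w x w`
#' square of pixels connecting the `w` bins up to and including `i` with the
#' `w` bins immediately following it — the amount of signal crossing the
#' bin's position along the diagonal. Bins inside a domain see high values;
#' bins at domain boundaries see a dip. The normalized score is
#' `log2(value / mean(values))`, so 0 means average insulation and negative
#' scores mark candidate boundaries.
#'
#' The first and last `window_bins` bins lack a full window and are flagged
#' undefined. A matrix whose defined values are all zero yields an
#' all-undefined profile.
#'
#' @param bm a binned `contact_matrix`.
#' @param window_bins window half-size `w` in bins (default 5, i.e. 100 kb
#'   at 20-kb resolution).
#' @return an `insulation_profile`: data.frame with `bin` (0-based),
#'   `start`, `end`, `raw`, `score`, `defined`; window size in
#'   `attr(, "window_bins")`.
#' @export
insulation_profile <- function(bm, window_bins = 5L) {
  stopifnot(inherits(bm, "contact_matrix"))
  w <- as.integer(window_bins)
  if (w < 1L) stop("window_bins must be >= 1")
  m <- as_dense_matrix(bm)
  n <- nrow(m)
  if (n <= 2L * w)
    stop(sprintf("matrix too small for insulation window: %d bins <= 2 x %d",
                 n, w))
  raw <- rep(NA_real_, n)
  # defined for 0-based bins w .. n-1-w; 1-based i in (w+1) .. (n-w)
  for (i in (w + 1L):(n - w)) {
    raw[i] <- mean(m[(i - w + 1L):i, (i + 1L):(i + w)])
  }
  defined <- !is.na(raw)
  mu <- mean(raw[defined])
  score <- rep(NA_real_, n)
  if (mu > 0) {
    score[defined] <- log2(raw[defined] / mu)
    # zero-count windows inside an otherwise signalful matrix: -Inf is not a
    # usable score; flag those bins undefined as well
    score[!is.finite(score)] <- NA_real_
    defined <- !is.na(score)
  } else {
    defined <- rep(FALSE, n)
  }
  out <- data.frame(bin = seq_len(n) - 1L,
                    start = bm$axis$start,
                    end = bm$axis$end,
                    raw = raw, score = score, defined = defined)
  attr(out, "window_bins") <- w
  attr(out, "chrom") <- bm$region$chrom
  class(out) <- c("insulation_profile", "data.frame")
  out
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundaries are strict local minima of the normalized insulation score
#' among defined bins, at depth `score <= -delta`. A flat run of equal
#' minimal values counts once, attributed to its leftmost bin. The reported
#' genomic `position` is the end edge of the boundary bin — the coordinate
#' separating the two domains.
#'
#' @param profile an [insulation_profile()].
#' @param delta minimum boundary depth on the log2 score (default 0.5, i.e.
#'   the window must hold less than ~71% of the region-average signal).
#' @return data.frame `bin` (0-based), `position`, `depth`, sorted by bin.
#' @export
call_boundaries <- function(profile, delta = 0.5) {
  stopifnot(inherits(profile, "insulation_profile"))
  if (delta <= 0) stop("delta must be > 0")
  idx <- which(profile$defined)
  s <- profile$score[idx]
  if (length(s) < 3L)
    return(data.frame(bin = integer(), position = numeric(),
                      depth = numeric()))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_min <- logical(k)
  if (k >= 3L)
    is_min[2:(k - 1L)] <- r$values[2:(k - 1L)] < r$values[1:(k - 2L)] &
      r$values[2:(k - 1L)] < r$values[3:k]
  hit <- which(is_min & r$values <= -delta)
  bins <- idx[starts[hit]]  # leftmost bin of a flat minimum
  data.frame(bin = profile$bin[bins],
             position = profile$end[bins],
             depth = profile$score[bins])
}

#' Mean contact count as a function of bin separation
#'
#' For each separation `d` (in bins) the mean over all `n - d` pixels at
#' that separation, zeros included — the distance-decay background that
#' loop calling compares against.
#'
#' @param bm a binned `contact_matrix`.
#' @return data.frame `distance` (0-based separation), `expected`.
#' @export
expected_by_distance <- function(bm) {
  stopifnot(inherits(bm, "contact_matrix"))
  m <- as_dense_matrix(bm)
  n <- nrow(m)
  expected <- vapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d)
    mean(m[cbind(i, i + d)])
  }, numeric(1))
  data.frame(distance = 0:(n - 1L), expected = expected)
}

#' Call point loops on a binned contact matrix
#'
#' A pixel `(i, j)` with separation `j - i >= min_separation_bins` is a loop
#' candidate when its observed count reaches `min_count`, exceeds the
#' distance-decay expectation at its separation by `enrichment_threshold`,
#' and exceeds the mean of its surrounding neighborhood (the 8 pixels at
#' Chebyshev distance 1 by default) by the same factor — the local test
#' rejects ridges such as domain corners that are broadly, not focally,
#' enriched. Clusters of adjacent candidates are merged to the
#' maximal-enrichment pixel.
#'
#' Separations 0 and 1 are never considered: they are dominated by
#' self-ligation and adjacent re-ligation products.
#'
#' @param bm a binned `contact_matrix`.
#' @param min_separation_bins minimum anchor separation in bins (default 3).
#' @param enrichment_threshold observed/expected ratio required both
#'   globally and locally (default 3).
#' @param min_count minimum observed count (default 5).
#' @param neighborhood Chebyshev radius of the local background ring
#'   (default 1 = the 8-neighborhood).
#' @return data.frame with 0-based `bin_i`, `bin_j`, anchor coordinates
#'   (`chrom`, `start1`, `end1`, `start2`, `end2`), `observed`, `expected`,
#'   `enrichment` and `span` (anchor start-to-start distance in bp), sorted
#'   by decreasing enrichment.
#' @export
call_loops <- function(bm, min_separation_bins = 3L,
                       enrichment_threshold = 3,
                       min_count = 5,
                       neighborhood = 1L) {
  stopifnot(inherits(bm, "contact_matrix"))
  if (min_separation_bins < 2L)
    stop("min_separation_bins must be >= 2 (d <= 1 is excluded)")
  if (enrichment_threshold <= 0 || min_count <= 0 || neighborhood < 1L)
    stop("thresholds must be positive")
  m <- as_dense_matrix(bm)
  n <- nrow(m)
  exp_d <- expected_by_distance(bm)$expected
  r <- as.integer(neighborhood)
  cand <- list()
  for (i in seq_len(n)) {
    jmin <- i + min_separation_bins
    if (jmin > n) break
    for (j in jmin:n) {
      obs <- m[i, j]
      if (obs < min_count) next
      e <- exp_d[j - i + 1L]
      if (e <= 0 || obs / e < enrichment_threshold) next
      ri <- max(1L, i - r):min(n, i + r)
      rj <- max(1L, j - r):min(n, j + r)
      nb <- m[ri, rj, drop = FALSE]
      local_mean <- (sum(nb) - obs) / (length(nb) - 1L)
      if (local_mean > 0 && obs / local_mean < enrichment_threshold) next
      if (local_mean <= 0 && obs <= 0) next
      cand[[length(cand) + 1L]] <- c(i = i, j = j, obs = obs, exp = e,
                                     enr = obs / e)
    }
  }
  empty <- data.frame(bin_i = integer(), bin_j = integer(),
                      chrom = character(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(), end2 = numeric(),
                      observed = numeric(), expected = numeric(),
                      enrichment = numeric(), span = numeric())
  if (!length(cand)) return(empty)
  cd <- as.data.frame(do.call(rbind, cand))
  # non-maximum suppression: keep the strongest pixel of each adjacent
  # cluster (Chebyshev distance <= neighborhood in both axes)
  cd <- cd[order(-cd$enr, cd$i, cd$j), , drop = FALSE]
  kept <- logical(0)
  keep_rows <- integer(0)
  for (k in seq_len(nrow(cd))) {
    ok <- TRUE
    for (q in keep_rows) {
      if (abs(cd$i[k] - cd$i[q]) <= r && abs(cd$j[k] - cd$j[q]) <= r) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep_rows <- c(keep_rows, k)
  }
  cd <- cd[keep_rows, , drop = FALSE]
  ax <- bm$axis
  out <- data.frame(bin_i = as.integer(cd$i) - 1L,
                    bin_j = as.integer(cd$j) - 1L,
                    chrom = bm$region$chrom,
                    start1 = ax$start[cd$i], end1 = ax$end[cd$i],
                    start2 = ax$start[cd$j], end2 = ax$end[cd$j],
                    observed = cd$obs, expected = cd$exp,
                    enrichment = cd$enr)
  out$span <- out$start2 - out$start1
  out[order(-out$enrichment, out$bin_i, out$bin_j), , drop = FALSE]
}

#' Write an insulation profile as bedGraph
#'
#' Undefined bins are omitted.
#'
#' @param profile an [insulation_profile()].
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_insulation_bedgraph <- function(profile, path) {
  d <- profile[profile$defined, , drop = FALSE]
  write_bedgraph(data.frame(chrom = attr(profile, "chrom"),
                            start = d$start, end = d$end, score = d$score),
                 path)
}

#' Write boundary calls as BED
#'
#' Each boundary is a 1-bp feature at the domain-separating edge; the score
#' column carries the boundary depth.
#'
#' @param boundaries result of [call_boundaries()].
#' @param chrom chromosome name.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_boundaries_bed <- function(boundaries, chrom, path) {
  if (!nrow(boundaries)) {
    file.create(path)
    return(invisible(path))
  }
  write_bed(data.frame(chrom = chrom,
                       start = boundaries$position,
                       end = boundaries$position + 1,
                       name = sprintf("boundary_%d", seq_len(nrow(boundaries))),
                       score = round(-boundaries$depth * 100)),
            path)
}

#' Write loop calls as BEDPE
#'
#' Columns: anchor1 (chrom/start/end), anchor2, name, observed, expected,
#' enrichment.
#'
#' @param loops result of [call_loops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops_bedpe <- function(loops, path) {
  df <- data.frame(chrom1 = loops$chrom, start1 = loops$start1,
                   end1 = loops$end1, chrom2 = loops$chrom,
                   start2 = loops$start2, end2 = loops$end2,
                   name = if (nrow(loops))
                     sprintf("loop_%d", seq_len(nrow(loops))) else character(),
                   observed = loops$observed, expected = loops$expected,
                   enrichment = loops$enrichment)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
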