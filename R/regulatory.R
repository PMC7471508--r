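#' Length-weighted mean conservation over an interval
#'
#' Averages a step-interval (bedGraph-style) conservation track over a query
#' interval. Bases the track does not cover contribute score 0, so the mean
#' is always taken over the full interval length.
#'
#' @param interval a [genomic_interval()].
#' @param cons conservation track: data.frame `chrom`, `start`, `end`,
#'   `score`, sorted and non-overlapping (as from [read_bedgraph()]).
#' @return mean score over the interval.
#' @export
mean_conservation <- function(interval, cons) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (!nrow(cons)) return(0)
  cons <- cons[cons$chrom == interval$chrom, , drop = FALSE]
  if (!nrow(cons)) return(0)
  if (is.unsorted(cons$start)) cons <- cons[order(cons$start), , drop = FALSE]
  if (any(cons$start[-1] < cons$end[-nrow(cons)]))
    stop("conservation track intervals overlap")
  ov_start <- pmax(cons$start, interval$start)
  ov_end <- pmin(cons$end, interval$end)
  w <- pmax(0, ov_end - ov_start)
  sum(w * cons$score) / interval_length(interval)
}

#' Call enhancer candidates inside a loop anchor
#'
#' Implements peak-cluster enhancer candidate calling: H3K27ac peaks with
#' any overlap of the anchor interval are selected (a peak extending past
#' the anchor edge is retained whole unless `truncate = TRUE`), nearby peaks
#' are merged into clusters when the gap between them is at most
#' `merge_gap`, clusters are annotated with their supporting peak count and
#' mean conservation, filtered at `min_cons`, and named `Enh1`, `Enh2`, ...
#' left to right. Naming is stable under permutation of the peak input.
#'
#' @param anchor the anchor interval (a [genomic_interval()]), typically the
#'   distal anchor of a promoter-contacting loop.
#' @param peaks data.frame `chrom`, `start`, `end` (0-based half-open),
#'   optional `score`.
#' @param cons conservation track as in [mean_conservation()]; may be an
#'   empty data.frame, in which case conservation is reported as 0.
#' @param merge_gap merge peaks separated by at most this many bp
#'   (default 2000).
#' @param min_cons minimum mean conservation of a reported candidate
#'   (default 0: conservation is reported, not filtered).
#' @param truncate clip candidates to the anchor edges (default `FALSE`).
#' @return data.frame `name`, `chrom`, `start`, `end`, `n_peaks`,
#'   `mean_conservation`, sorted and non-overlapping.
#' @export
call_enhancer_candidates <- function(anchor, peaks,
                                     cons = NULL,
                                     merge_gap = 2000,
                                     min_cons = 0,
                                     truncate = FALSE) {
  stopifnot(inherits(anchor, "genomic_interval"))
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  if (is.null(cons))
    cons <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), score = numeric())
  empty <- data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_peaks = integer(), mean_conservation = numeric())
  if (is.null(peaks) || !nrow(peaks)) return(empty)
  sel <- peaks$chrom == anchor$chrom &
    peaks$start < anchor$end & peaks$end > anchor$start
  peaks <- peaks[sel, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  peaks <- peaks[order(peaks$start, peaks$end), , drop = FALSE]
  ir <- IRanges::IRanges(start = peaks$start + 1, end = peaks$end)
  merged <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1,
                            with.revmap = TRUE)
  out <- data.frame(
    chrom = anchor$chrom,
    start = IRanges::start(merged) - 1,
    end = IRanges::end(merged),
    n_peaks = lengths(S4Vectors::mcols(merged)$revmap))
  if (truncate) {
    out$start <- pmax(out$start, anchor$start)
    out$end <- pmin(out$end, anchor$end)
  }
  out$mean_conservation <- vapply(seq_len(nrow(out)), function(k) {
    mean_conservation(genomic_interval(out$chrom[k], out$start[k], out$end[k]),
                      cons)
  }, numeric(1))
  out <- out[out$mean_conservation >= min_cons, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(name = sprintf("Enh%d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Write enhancer candidates as BED plus a JSON report
#'
#' @param candidates result of [call_enhancer_candidates()].
#' @param out_prefix path prefix; writes `<prefix>.bed` and
#'   `<prefix>.json`.
#' @return named vector of written paths, invisibly.
#' @export
write_enhancer_candidates <- function(candidates, out_prefix) {
  bed <- paste0(out_prefix, ".bed")
  js <- paste0(out_prefix, ".json")
  if (nrow(candidates)) {
    write_bed(data.frame(chrom = candidates$chrom,
                         start = candidates$start,
                         end = candidates$end,
                         name = candidates$name,
                         score = pmin(1000, pmax(0, round(candidates$mean_conservation * 1000)))),
              bed)
  } else {
    file.create(bed)
  }
  jsonlite::write_json(candidates, js, auto_unbox = FALSE, digits = NA)
  invisible(c(bed = bed, json = js))
}
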