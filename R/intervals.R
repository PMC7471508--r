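#' Genomic intervals with 0-based half-open coordinates
#'
#' All coordinates inside the package are 0-based half-open (`[start, end)`),
#' the native BED convention: the length of an interval is `end - start` and
#' adjacent intervals share a single coordinate. Printed 1-based coordinates
#' from genome browsers or publications are converted at the boundary by
#' [parse_genome_coordinate()].
#'
#' @param chrom chromosome / sequence name.
#' @param start 0-based start (inclusive).
#' @param end end (exclusive); must be strictly greater than `start`.
#' @return an object of class `genomic_interval` (a named list with
#'   `chrom`, `start`, `end`).
#' @examples
#' gi <- genomic_interval("chr2", 100, 106)
#' interval_length(gi)  # 6
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing numbers")
  if (start < 0) stop("start must be >= 0")
  if (start >= end)
    stop(sprintf("empty or inverted interval: [%s, %s)",
                 format(start, scientific = FALSE),
                 format(end, scientific = FALSE)))
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @exportS3Method base::print
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:[%s, %s)  length %s bp\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(interval_length(x), scientific = FALSE)))
  invisible(x)
}

#' @rdname genomic_interval
#' @param x a `genomic_interval`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' Parse a printed genome coordinate string
#'
#' Publications and genome browsers print coordinates in two conventions that
#' differ by one base. Gene/feature annotations ("chr2:145141942-145277958")
#' are 1-based fully inclusive, so the feature length is `end - start + 1`.
#' Round-number map coordinates (bin edges, e.g. "chr2:145260000-145280000")
#' are edge positions of a half-open interval of length `end - start`. The
#' caller states which convention applies; both are converted to the internal
#' 0-based half-open representation.
#'
#' En dashes, spaces after the colon and thousands-separator commas are
#' accepted.
#'
#' @param text coordinate string `chrom:start-end`.
#' @param convention `"bin-edge"` (half-open edges, default) or
#'   `"inclusive"` (1-based inclusive).
#' @return a [genomic_interval()].
#' @examples
#' interval_length(parse_genome_coordinate("chr2:145260000-145280000"))  # 20000
#' gi <- parse_genome_coordinate("chr2:143270465-150642631", "inclusive")
#' round(interval_length(gi) / 1e6, 1)  # 7.4
#' @export
parse_genome_coordinate <- function(text,
                                    convention = c("bin-edge", "inclusive")) {
  convention <- match.arg(convention)
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub(",", "", trimws(text))
  clean <- gsub("–", "-", clean)  # en dash as printed in papers
  m <- regmatches(clean,
                  regexec("^([^:[:space:]]+):[[:space:]]*([0-9]+)[[:space:]]*-[[:space:]]*([0-9]+)$",
                          clean))[[1]]
  if (length(m) != 4L)
    stop(sprintf("cannot parse coordinate string: '%s'", text))
  chrom <- m[2]
  start <- as.numeric(m[3])
  end <- as.numeric(m[4])
  if (convention == "inclusive") {
    start <- start - 1  # 1-based inclusive start -> 0-based
  }
  if (start >= end)
    stop(sprintf("empty or inverted coordinate range in '%s'", text))
  genomic_interval(chrom, start, end)
}

#' Gap between two intervals on the same chromosome
#'
#' Returns the number of bases strictly between two intervals, 0 when they
#' overlap or touch. Symmetric in its arguments.
#'
#' @param a,b `genomic_interval` objects on the same chromosome.
#' @return gap in bp.
#' @export
interval_distance <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$chrom != b$chrom)
    stop(sprintf("intervals on different chromosomes: %s vs %s",
                 a$chrom, b$chrom))
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  max(0, b$start - a$end)
}

#' Do two intervals overlap?
#' @inheritParams interval_distance
#' @return logical.
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

## ---- internal data.frame <-> GRanges bridges (BED/bedGraph I/O) ----------

# interval data.frame: columns chrom, start, end (0-based half-open),
# optional name / score.
.df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

.granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path BED file (3+ columns).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and,
#'   when present, `name` and `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- .granges_to_df(gr)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) df$name <- as.character(md$name)
  if (!is.null(md$score)) df$score <- as.numeric(md$score)
  df
}

#' Write intervals to a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- .df_to_granges(df)
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file.
#' @return data.frame `chrom`, `start`, `end`, `score`, sorted, 0-based
#'   half-open.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- .granges_to_df(gr)
  df$score <- as.numeric(gr$score)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write a bedGraph track
#'
#' @param df data.frame with `chrom`, `start`, `end`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  gr <- .df_to_granges(df)
  gr$score <- df$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
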