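#' Pair filtering configuration
#'
#' Controls which ligation pairs enter the proximity matrix. Same-fragment
#' pairs are self-circles/undigested products and carry no proximity
#' information, so they are dropped by default. Adjacent-fragment dropping is
#' off by default: re-ligation of neighbouring fragments is partly
#' informative and there is no community consensus for capture data.
#'
#' @param min_mapq minimum mapping quality required of both mates.
#' @param drop_same_fragment drop pairs whose mates fall in one fragment.
#' @param drop_adjacent_fragments drop pairs in directly adjacent fragments.
#' @param restrict_to_region if `TRUE` (default) pairs with a mate outside
#'   the capture region are dropped and tallied; if `FALSE` such a pair is a
#'   hard error (strict mode for data expected to be pre-filtered).
#' @return a `filter_config` object.
#' @export
filter_config <- function(min_mapq = 30L,
                          drop_same_fragment = TRUE,
                          drop_adjacent_fragments = FALSE,
                          restrict_to_region = TRUE) {
  min_mapq <- as.integer(min_mapq)
  if (is.na(min_mapq) || min_mapq < 0L) stop("min_mapq must be >= 0")
  structure(list(min_mapq = min_mapq,
                 drop_same_fragment = isTRUE(drop_same_fragment),
                 drop_adjacent_fragments = isTRUE(drop_adjacent_fragments),
                 restrict_to_region = isTRUE(restrict_to_region)),
            class = "filter_config")
}

.pairs_columns <- c("read_id", "chrom1", "pos1", "strand1",
                    "chrom2", "pos2", "strand2", "mapq1", "mapq2")

#' Read positioned ligation pairs from a TSV file
#'
#' The pairs format is a plain tab-separated table, one ligation product per
#' line, with columns `read_id chrom1 pos1 strand1 chrom2 pos2 strand2
#' mapq1 mapq2`. `pos` is the 1-based 5' mapped position of the mate.
#' Lines starting with `#` are headers/comments. Malformed lines (wrong
#' column count, non-numeric position or mapq, bad strand) abort with the
#' offending line number.
#'
#' @param path pairs TSV path.
#' @return data.frame with the columns above, in file order.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(read_id = character(), chrom1 = character(),
                      pos1 = numeric(), strand1 = character(),
                      chrom2 = character(), pos2 = numeric(),
                      strand2 = character(), mapq1 = integer(),
                      mapq2 = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 9L)) {
    i <- which(nc != 9L)[1]
    stop(sprintf("pairs parse error at line %d: expected 9 tab-separated columns, found %d",
                 lineno[i], nc[i]))
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  df <- data.frame(read_id = m[, 1], chrom1 = m[, 2],
                   pos1 = suppressWarnings(as.numeric(m[, 3])),
                   strand1 = m[, 4], chrom2 = m[, 5],
                   pos2 = suppressWarnings(as.numeric(m[, 6])),
                   strand2 = m[, 7],
                   mapq1 = suppressWarnings(as.integer(m[, 8])),
                   mapq2 = suppressWarnings(as.integer(m[, 9])),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$pos1) | is.na(df$pos2) | df$pos1 < 1 | df$pos2 < 1 |
                 is.na(df$mapq1) | is.na(df$mapq2) |
                 !(df$strand1 %in% c("+", "-")) |
                 !(df$strand2 %in% c("+", "-")))
  if (length(bad))
    stop(sprintf("pairs parse error at line %d: invalid field value",
                 lineno[bad[1]]))
  df
}

#' Write ligation pairs to a TSV file
#'
#' @param pairs data.frame as returned by [read_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.pairs_columns, collapse = "\t")), con)
  if (nrow(pairs)) {
    body <- do.call(paste, c(lapply(.pairs_columns, function(cl) {
      v <- pairs[[cl]]
      if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

.new_contact_matrix <- function(level, axis, region, counts, metadata,
                                resolution = NULL) {
  structure(list(level = level, axis = axis, region = region,
                 resolution = resolution,
                 counts = Matrix::forceSymmetric(counts, uplo = "U"),
                 metadata = metadata),
            class = "contact_matrix")
}

#' @exportS3Method base::print
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s-level, %d x %d, %s contacts (%s)\n",
              x$level, nrow(x$axis), nrow(x$axis),
              format(contact_total(x), scientific = FALSE),
              if (is.null(x$resolution)) "fragment resolution"
              else paste0(format(x$resolution, scientific = FALSE), " bp bins")))
  invisible(x)
}

#' Total contact count of a matrix
#'
#' Sum over the upper triangle plus the diagonal; equals the number of kept
#' pairs.
#'
#' @param cm a `contact_matrix`.
#' @return numeric count.
#' @export
contact_total <- function(cm) {
  m <- as.matrix(cm$counts)
  sum(m[upper.tri(m, diag = TRUE)])
}

#' Assign ligation pairs to restriction fragments and build the proximity matrix
#'
#' Each mate is assigned to the fragment containing its 5' mapped position;
#' the unordered fragment pair is incremented. Pairs failing the filters are
#' dropped and tallied by reason, with precedence trans > off-region >
#' low-mapq > same-fragment > adjacent, so every input pair is accounted for
#' exactly once: `input == kept + sum(dropped)`.
#'
#' @param pairs data.frame from [read_pairs()].
#' @param fm a `fragment_map` covering the capture region.
#' @param filters a [filter_config()].
#' @return a fragment-level `contact_matrix` with drop tallies in
#'   `metadata$totals`.
#' @export
assign_pairs <- function(pairs, fm, filters = filter_config()) {
  stopifnot(inherits(fm, "fragment_map"), inherits(filters, "filter_config"))
  region <- fm$region
  n_frag <- nrow(fm$fragments)
  n_in <- nrow(pairs)
  drop <- c(trans = 0, off_region = 0, low_mapq = 0,
            same_fragment = 0, adjacent = 0)
  keep <- rep(TRUE, n_in)
  fi <- fj <- integer(0)
  if (n_in) {
    p1 <- pairs$pos1 - 1  # 0-based
    p2 <- pairs$pos2 - 1
    is_trans <- pairs$chrom1 != region$chrom | pairs$chrom2 != region$chrom
    off <- !is_trans & (p1 < region$start | p1 >= region$end |
                          p2 < region$start | p2 >= region$end)
    if (any(off) && !filters$restrict_to_region)
      stop(sprintf("pair '%s' maps outside the capture region (strict mode)",
                   pairs$read_id[which(off)[1]]))
    lowq <- !is_trans & !off &
      (pairs$mapq1 < filters$min_mapq | pairs$mapq2 < filters$min_mapq)
    keep <- !(is_trans | off | lowq)
    # fragment index (1-based) by 5' position; fragments tile the region
    starts <- fm$fragments$start
    fi <- findInterval(p1[keep], starts)
    fj <- findInterval(p2[keep], starts)
    same <- fi == fj
    adj <- abs(fi - fj) == 1L
    drop_same <- filters$drop_same_fragment & same
    drop_adj <- filters$drop_adjacent_fragments & adj
    drop["trans"] <- sum(is_trans)
    drop["off_region"] <- sum(off)
    drop["low_mapq"] <- sum(lowq)
    drop["same_fragment"] <- sum(drop_same)
    drop["adjacent"] <- sum(drop_adj)
    ok <- !(drop_same | drop_adj)
    fi <- fi[ok]
    fj <- fj[ok]
  }
  lo <- pmin(fi, fj)
  hi <- pmax(fi, fj)
  counts <- Matrix::sparseMatrix(i = lo, j = hi, x = rep(1, length(lo)),
                                 dims = c(n_frag, n_frag))
  metadata <- list(enzyme = fm$enzyme, filters = unclass(filters),
                   totals = list(input = n_in, kept = length(fi),
                                 dropped = as.list(drop)))
  .new_contact_matrix("fragment", fm$fragments[, c("chrom", "start", "end", "name")],
                      region, counts, metadata)
}

.make_bins <- function(region, resolution) {
  resolution <- as.numeric(resolution)
  if (resolution < 1) stop("resolution must be >= 1 bp")
  starts <- seq(region$start, region$end - 1, by = resolution)
  data.frame(chrom = region$chrom,
             start = starts,
             end = pmin(starts + resolution, region$end),
             name = sprintf("bin_%d", seq_along(starts) - 1L),
             stringsAsFactors = FALSE)
}

#' Bin a fragment-level matrix to fixed genomic resolution
#'
#' Each fragment is assigned to the bin containing its midpoint (a
#' deterministic rule that conserves integer counts, unlike split-weighting);
#' counts are summed. The last bin may be shorter than `resolution`. A
#' resolution at least as large as the region yields a single 1x1 bin.
#'
#' @param cm a fragment-level `contact_matrix`.
#' @param resolution bin width in bp (e.g. `20000` for 20-kb maps).
#' @return a binned `contact_matrix`; total count is conserved.
#' @export
bin_matrix <- function(cm, resolution) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$level != "fragment")
    stop("bin_matrix expects a fragment-level matrix")
  region <- cm$region
  bins <- .make_bins(region, resolution)
  mid <- (cm$axis$start + cm$axis$end) / 2
  b <- pmin(floor((mid - region$start) / resolution) + 1L, nrow(bins))
  tr <- Matrix::summary(Matrix::triu(cm$counts))
  bi <- b[tr$i]
  bj <- b[tr$j]
  counts <- Matrix::sparseMatrix(i = pmin(bi, bj), j = pmax(bi, bj),
                                 x = tr$x, dims = c(nrow(bins), nrow(bins)))
  md <- cm$metadata
  md$binned_from <- "fragment midpoints"
  .new_contact_matrix("bin", bins, region, counts, md,
                      resolution = resolution)
}

#' Serialize / restore a contact matrix
#'
#' The on-disk form is a sparse triplet TSV (`bin_i`, `bin_j`, `count`, with
#' 0-based indices and `i <= j` only) plus a JSON sidecar holding the axis,
#' region, resolution and metadata, including the entry count and total used
#' as an integrity check on read.
#'
#' @param cm a `contact_matrix`.
#' @param out_prefix path prefix; writes `<prefix>.triplets.tsv` and
#'   `<prefix>.json`.
#' @return named vector of written paths, invisibly.
#' @export
write_matrix <- function(cm, out_prefix) {
  stopifnot(inherits(cm, "contact_matrix"))
  tsv <- paste0(out_prefix, ".triplets.tsv")
  js <- paste0(out_prefix, ".json")
  tr <- Matrix::summary(Matrix::triu(cm$counts))
  tr <- tr[order(tr$i, tr$j), , drop = FALSE]
  utils::write.table(
    data.frame(bin_i = tr$i - 1L, bin_j = tr$j - 1L, count = tr$x),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    level = cm$level,
    region = cm$region[c("chrom", "start", "end")],
    resolution = cm$resolution,
    axis = as.list(cm$axis),
    n_axis = nrow(cm$axis),
    n_entries = nrow(tr),
    total = contact_total(cm),
    metadata = cm$metadata)
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(triplets = tsv, sidecar = js))
}

#' @rdname write_matrix
#' @param prefix the prefix the matrix was written under.
#' @return `read_matrix`: the restored `contact_matrix`;
#'   `write_matrix %>% read_matrix` is the identity.
#' @export
read_matrix <- function(prefix) {
  tsv <- paste0(prefix, ".triplets.tsv")
  js <- paste0(prefix, ".json")
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  trip <- utils::read.table(tsv, header = TRUE, sep = "\t")
  n <- side$n_axis
  if (nrow(trip) != side$n_entries)
    stop(sprintf("matrix integrity error: sidecar records %d entries, triplet file has %d",
                 side$n_entries, nrow(trip)))
  if (nrow(trip) && (max(trip$bin_i, trip$bin_j) >= n || min(trip$bin_i, trip$bin_j) < 0))
    stop("matrix integrity error: triplet index beyond axis")
  if (any(trip$bin_i > trip$bin_j))
    stop("matrix integrity error: lower-triangle entry in triplet file")
  counts <- Matrix::sparseMatrix(i = trip$bin_i + 1L, j = trip$bin_j + 1L,
                                 x = trip$count, dims = c(n, n))
  axis <- as.data.frame(side$axis, stringsAsFactors = FALSE)
  region <- genomic_interval(side$region$chrom, side$region$start,
                             side$region$end)
  cm <- .new_contact_matrix(side$level, axis, region, counts,
                            side$metadata, resolution = side$resolution)
  if (abs(contact_total(cm) - side$total) > 1e-6)
    stop("matrix integrity error: total count mismatch between sidecar and triplets")
  cm
}

#' Dense export of a contact matrix
#'
#' @param cm a `contact_matrix`.
#' @return a base symmetric dense matrix.
#' @export
as_dense_matrix <- function(cm) {
  as.matrix(cm$counts)
}

#' Build a contact matrix from a dense symmetric matrix (mainly for tests
#' and simulations)
#'
#' @param m symmetric numeric matrix.
#' @param region a [genomic_interval()].
#' @param resolution bin width used to lay out the axis.
#' @param metadata optional metadata list.
#' @return a binned `contact_matrix`.
#' @export
contact_matrix_from_dense <- function(m, region, resolution,
                                      metadata = list()) {
  if (!isSymmetric(unname(m))) stop("matrix must be symmetric")
  bins <- .make_bins(region, resolution)
  if (nrow(bins) != nrow(m))
    stop(sprintf("matrix has %d bins but region/resolution imply %d",
                 nrow(m), nrow(bins)))
  .new_contact_matrix("bin", bins, region,
                      methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                      metadata, resolution = resolution)
}
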