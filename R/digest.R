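#' Restriction enzyme specifications
#'
#' An enzyme is described by its IUPAC recognition pattern and the 0-based
#' offset of the top-strand cut inside a pattern match. Two enzymes relevant
#' to capture-based conformation assays ship as built-ins: ApoI
#' (`R^AATTY`, a 6-cutter with two-fold degeneracy on both flanks) and DpnII
#' (`^GATC`, a blunt frequent 4-cutter). Both are palindromic under IUPAC
#' reverse complement, which [find_cut_sites()] requires: for palindromic
#' sites a top-strand scan finds every site on either strand.
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition pattern (characters from
#'   `ACGTRYSWKMBDHVN`).
#' @param cut_offset 0-based offset of the top-strand cut within the match;
#'   must lie in `[0, nchar(recognition)]`.
#' @return a `restriction_enzyme` object.
#' @examples
#' apoi <- restriction_enzyme("ApoI")
#' apoi$recognition  # "RAATTY"
#' @export
restriction_enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  builtins <- list(
    ApoI  = list(recognition = "RAATTY", cut_offset = 1L),
    DpnII = list(recognition = "GATC",   cut_offset = 0L))
  if (is.null(recognition)) {
    if (!name %in% names(builtins))
      stop(sprintf("unknown built-in enzyme '%s' (built-ins: %s)",
                   name, paste(names(builtins), collapse = ", ")))
    recognition <- builtins[[name]]$recognition
    cut_offset <- builtins[[name]]$cut_offset
  }
  recognition <- toupper(recognition)
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(recognition, "")[[1]], iupac)
  if (length(bad))
    stop(sprintf("non-IUPAC symbol(s) in recognition pattern: %s",
                 paste(bad, collapse = ", ")))
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within [0, length(recognition)]")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @exportS3Method base::print
print.restriction_enzyme <- function(x, ...) {
  pat <- x$recognition
  marked <- paste0(substr(pat, 1, x$cut_offset), "^",
                   substr(pat, x$cut_offset + 1, nchar(pat)))
  cat(sprintf("<restriction_enzyme> %s  %s\n", x$name, marked))
  invisible(x)
}

#' Is an enzyme's recognition site palindromic under IUPAC reverse complement?
#'
#' @param enzyme a [restriction_enzyme()].
#' @return logical.
#' @export
is_palindromic <- function(enzyme) {
  pat <- Biostrings::DNAString(enzyme$recognition)
  as.character(Biostrings::reverseComplement(pat)) == enzyme$recognition
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  if (nchar(sequence) == 0L)
    stop("empty sequence")
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", sequence)
  if (bad > 0)
    stop(sprintf("invalid character '%s' in sequence at offset %d",
                 substr(sequence, bad, bad), as.integer(bad) - 1L))
  sequence
}

#' Find restriction cut sites on a sequence
#'
#' Scans the top strand for IUPAC-expanded matches of the enzyme's
#' recognition pattern and returns one 0-based cut position per match
#' (`match_start + cut_offset`). Only palindromic enzymes are accepted, so a
#' top-strand scan is complete; `N` bases in the sequence never satisfy a
#' non-N pattern symbol. Lowercase (soft-masked) bases are treated as their
#' uppercase equivalents; a warning is emitted when more than 1% of the
#' sequence is `N`, since N runs silently lengthen fragments.
#'
#' @param sequence nucleotide string (IUPAC characters, `N` allowed).
#' @param enzyme a [restriction_enzyme()].
#' @return sorted integer-valued vector of 0-based cut positions.
#' @examples
#' find_cut_sites("GAATTC", restriction_enzyme("ApoI"))   # 1
#' find_cut_sites("AAGATCTTGATCAA", restriction_enzyme("DpnII"))  # 2 8
#' @export
find_cut_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (!is_palindromic(enzyme))
    stop(sprintf(
      "enzyme %s (%s) is not palindromic under IUPAC reverse complement; %s",
      enzyme$name, enzyme$recognition,
      "a top-strand-only scan would miss bottom-strand sites"))
  sequence <- .check_sequence(sequence)
  n_frac <- lengths(regmatches(sequence, gregexpr("N", sequence))) /
    nchar(sequence)
  if (n_frac > 0.01)
    warning(sprintf("sequence is %.1f%% N; fragments spanning N runs are inflated",
                    100 * n_frac))
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enzyme$recognition)
  # fixed = c(pattern = FALSE, subject = TRUE): IUPAC codes in the pattern
  # are expanded, while subject ambiguities (N) stay literal and never match.
  hits <- Biostrings::matchPattern(pat, subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  sort(Biostrings::start(hits) - 1L + enzyme$cut_offset)
}

#' In-silico digestion of a capture region
#'
#' Converts cut sites into the ordered fragment map that downstream contact
#' assignment is annotated against. Fragment boundaries are the region edges
#' plus every cut site; fragments tile the region exactly. Cuts falling on a
#' region edge (offset 0 or region length) produce no zero-length fragment
#' and are dropped.
#'
#' @param sequence nucleotide string covering exactly `region`.
#' @param enzyme a [restriction_enzyme()].
#' @param region a [genomic_interval()] with
#'   `interval_length(region) == nchar(sequence)`.
#' @return a `fragment_map`: list with `region`, `cut_positions` (0-based,
#'   region-relative) and `fragments` (data.frame `chrom`, `start`, `end`,
#'   `name`, absolute coordinates).
#' @export
digest_region <- function(sequence, enzyme, region) {
  stopifnot(inherits(region, "genomic_interval"))
  if (nchar(sequence) != interval_length(region))
    stop(sprintf("sequence length (%d) does not match region length (%s)",
                 nchar(sequence),
                 format(interval_length(region), scientific = FALSE)))
  cuts <- find_cut_sites(sequence, enzyme)
  cuts <- cuts[cuts > 0 & cuts < interval_length(region)]
  bounds <- c(region$start, region$start + cuts, region$end)
  n <- length(bounds) - 1L
  fragments <- data.frame(
    chrom = region$chrom,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    name = sprintf("frag_%d", seq_len(n) - 1L),
    stringsAsFactors = FALSE)
  structure(list(region = region, cut_positions = cuts, fragments = fragments,
                 enzyme = enzyme$name),
            class = "fragment_map")
}

#' @exportS3Method base::print
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map> %s:[%s, %s)  %d fragments (%s)\n",
              x$region$chrom,
              format(x$region$start, scientific = FALSE),
              format(x$region$end, scientific = FALSE),
              nrow(x$fragments), x$enzyme))
  invisible(x)
}

#' Fragment-size statistics of a digest
#'
#' @param fm a `fragment_map` from [digest_region()].
#' @param breaks histogram bin edges in bp (passed to [hist()]); default
#'   200-bp bins up to the maximum fragment.
#' @return list with `count`, `mean`, `median`, and `histogram`
#'   (data.frame `from`, `to`, `n`). The mean equals region length divided
#'   by fragment count because fragments tile the region.
#' @export
fragment_stats <- function(fm, breaks = NULL) {
  stopifnot(inherits(fm, "fragment_map"))
  len <- fm$fragments$end - fm$fragments$start
  if (!length(len)) stop("empty fragment map")
  if (is.null(breaks))
    breaks <- seq(0, 200 * ceiling(max(len) / 200), by = 200)
  h <- graphics::hist(len, breaks = breaks, plot = FALSE)
  list(count = length(len),
       mean = interval_length(fm$region) / length(len),
       median = stats::median(len),
       histogram = data.frame(from = h$breaks[-length(h$breaks)],
                              to = h$breaks[-1],
                              n = h$counts))
}

#' Write fragment statistics as a TSV histogram plus a JSON summary
#'
#' @param stats result of [fragment_stats()].
#' @param out_prefix path prefix; writes `<prefix>.hist.tsv` and
#'   `<prefix>.stats.json`.
#' @return named vector of written paths, invisibly.
#' @export
write_fragment_stats <- function(stats, out_prefix) {
  tsv <- paste0(out_prefix, ".hist.tsv")
  js <- paste0(out_prefix, ".stats.json")
  utils::write.table(stats$histogram, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(stats[c("count", "mean", "median")], js,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(hist = tsv, json = js))
}

#' Write a fragment map as BED
#'
#' @param fm a `fragment_map`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(fm, path) {
  write_bed(fm$fragments, path)
}

#' Read a fragment map from BED
#'
#' The fragments must tile a single contiguous region on one chromosome.
#'
#' @param path BED path as written by [write_fragment_bed()].
#' @param enzyme_name optional enzyme label stored on the map.
#' @return a `fragment_map`.
#' @export
read_fragment_bed <- function(path, enzyme_name = NA_character_) {
  df <- read_bed(path)
  df <- df[order(df$start), , drop = FALSE]
  if (length(unique(df$chrom)) != 1L)
    stop("fragment map must cover a single chromosome")
  if (any(df$start[-1] != df$end[-nrow(df)]))
    stop("fragments do not tile a contiguous region")
  region <- genomic_interval(df$chrom[1], df$start[1], df$end[nrow(df)])
  if (is.null(df$name)) df$name <- sprintf("frag_%d", seq_len(nrow(df)) - 1L)
  structure(list(region = region,
                 cut_positions = df$start[-1] - region$start,
                 fragments = df[, c("chrom", "start", "end", "name")],
                 enzyme = enzyme_name),
            class = "fragment_map")
}

#' Extract one record from a (multi-)FASTA file
#'
#' @param path FASTA file.
#' @param name record name; default: the first record. Matching is on the
#'   first whitespace-delimited token of the header.
#' @return the sequence as an uppercase character string.
#' @export
read_fasta_sequence <- function(path, name = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(name)) {
    i <- 1L
  } else {
    i <- match(name, ids)
    if (is.na(i))
      stop(sprintf("record '%s' not found in %s (records: %s)",
                   name, path, paste(utils::head(ids, 5), collapse = ", ")))
  }
  toupper(as.character(set[[i]]))
}
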