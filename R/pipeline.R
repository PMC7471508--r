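#' Pipeline run configuration
#'
#' One plain-text (YAML) configuration drives the whole chain:
#' digest -> contacts -> bin -> domains/loops -> enhancers -> motifs.
#' Every stage parameter lives here so a run is reproducible from the
#' config alone; unknown keys are rejected at load time rather than
#' silently ignored.
#'
#' @param fasta path to the capture-region FASTA.
#' @param pairs path to the ligation pairs TSV ([read_pairs()] layout).
#' @param peaks path to an H3K27ac peak BED (optional; `NULL` skips the
#'   enhancer and motif stages).
#' @param conservation path to a conservation bedGraph (optional).
#' @param motifs path to a JASPAR PFM file (optional; `NULL` skips the
#'   motif stage).
#' @param out_dir output directory.
#' @param region capture region as `chrom:start-end` (bin-edge convention);
#'   `NULL` uses the full first FASTA record.
#' @param fasta_record FASTA record name (`NULL`: first record).
#' @param enzyme restriction enzyme name (`"ApoI"` or `"DpnII"`).
#' @param min_mapq,drop_same_fragment,drop_adjacent_fragments pair filters,
#'   see [filter_config()].
#' @param resolution bin width in bp.
#' @param window_bins,delta insulation window and boundary depth, see
#'   [insulation_profile()] and [call_boundaries()].
#' @param loop_min_separation,loop_enrichment,loop_min_count loop-calling
#'   thresholds, see [call_loops()].
#' @param anchor enhancer anchor as `chrom:start-end`, or `"auto"` to use
#'   the distal anchor of the strongest called loop.
#' @param merge_gap,min_cons enhancer clustering parameters, see
#'   [call_enhancer_candidates()].
#' @param motif_threshold relative-score threshold for motif scanning.
#' @param seed seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters when the config is used to drive a
#'   simulation).
#' @return a `run_config` object.
#' @export
run_config <- function(fasta, pairs, out_dir,
                       peaks = NULL, conservation = NULL, motifs = NULL,
                       region = NULL, fasta_record = NULL,
                       enzyme = "ApoI",
                       min_mapq = 30L, drop_same_fragment = TRUE,
                       drop_adjacent_fragments = FALSE,
                       resolution = 20000,
                       window_bins = 5L, delta = 0.5,
                       loop_min_separation = 3L, loop_enrichment = 3,
                       loop_min_count = 5,
                       anchor = "auto", merge_gap = 2000, min_cons = 0,
                       motif_threshold = 0.90,
                       seed = 1L) {
  cfg <- list(fasta = fasta, pairs = pairs, out_dir = out_dir,
              peaks = peaks, conservation = conservation, motifs = motifs,
              region = region, fasta_record = fasta_record,
              enzyme = enzyme, min_mapq = as.integer(min_mapq),
              drop_same_fragment = isTRUE(drop_same_fragment),
              drop_adjacent_fragments = isTRUE(drop_adjacent_fragments),
              resolution = resolution,
              window_bins = as.integer(window_bins), delta = delta,
              loop_min_separation = as.integer(loop_min_separation),
              loop_enrichment = loop_enrichment,
              loop_min_count = loop_min_count,
              anchor = anchor, merge_gap = merge_gap, min_cons = min_cons,
              motif_threshold = motif_threshold, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

.run_config_keys <- function() names(formals(run_config))

#' Read / write a pipeline configuration (YAML)
#'
#' `read_run_config` rejects unknown keys; the round trip through
#' `write_run_config` is lossless.
#'
#' @param path YAML file path.
#' @return `read_run_config`: a [run_config()];
#'   `write_run_config`: `path` invisibly.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), .run_config_keys())
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  required <- c("fasta", "pairs", "out_dir")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("missing required configuration key(s): %s",
                 paste(miss, collapse = ", ")))
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), path)
  invisible(path)
}

.stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes digest -> contacts -> bin -> domains -> loops -> enhancers ->
#' motifs from a single [run_config()], writing every stage output plus a
#' JSON manifest (`manifest.json`) that records the package version, the
#' full configuration, each stage's outputs with md5 checksums, and the
#' pair-filter tallies. Any stage failure aborts with the stage name. When
#' `force = FALSE` and a manifest from an identical configuration exists,
#' stages whose outputs still match their recorded checksums are loaded
#' from disk instead of recomputed.
#'
#' @param cfg a [run_config()] or a path to a YAML config.
#' @param force recompute everything, ignoring existing outputs.
#' @return the manifest, invisibly, with the main results attached as
#'   attributes (`binned_matrix`, `boundaries`, `loops`, `enhancers`,
#'   `motif_hits`).
#' @export
run_t2c_pipeline <- function(cfg, force = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("fasta", "pairs", "peaks", "conservation", "motifs")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("input file for '%s' not found: %s", f, cfg[[f]]))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)

  cfg_digest <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                 null = "null")
  prev <- NULL
  manifest_path <- out("manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
    if (!is.null(old) && identical(old$config_json, as.character(cfg_digest)))
      prev <- old
  }
  fresh <- function(paths) {
    if (is.null(prev)) return(FALSE)
    rec <- unlist(lapply(prev$stages, function(s) unlist(s$md5)))
    all(file.exists(paths)) &&
      all(vapply(paths, function(p) {
        isTRUE(unname(rec[basename(p)]) == unname(tools::md5sum(p)))
      }, logical(1)))
  }

  stages <- list()
  add_stage <- function(name, paths, params = list()) {
    stages[[name]] <<- list(
      name = name,
      outputs = as.list(unname(paths)),
      md5 = as.list(stats::setNames(as.character(tools::md5sum(paths)),
                                    basename(paths))),
      params = params)
  }

  ## digest ----------------------------------------------------------------
  frag_bed <- out("fragments.bed")
  stats_prefix <- out("fragments")
  stats_paths <- c(frag_bed, paste0(stats_prefix, ".hist.tsv"),
                   paste0(stats_prefix, ".stats.json"))
  enzyme <- restriction_enzyme(cfg$enzyme)
  sequence <- .stage_error("digest", read_fasta_sequence(cfg$fasta,
                                                         cfg$fasta_record))
  region <- .stage_error("digest", {
    if (is.null(cfg$region)) {
      chrom <- if (is.null(cfg$fasta_record)) {
        set <- Biostrings::readDNAStringSet(cfg$fasta)
        sub("\\s.*$", "", names(set)[1])
      } else cfg$fasta_record
      genomic_interval(chrom, 0, nchar(sequence))
    } else parse_genome_coordinate(cfg$region)
  })
  if (fresh(stats_paths)) {
    fm <- read_fragment_bed(frag_bed, enzyme_name = cfg$enzyme)
  } else {
    fm <- .stage_error("digest", digest_region(sequence, enzyme, region))
    .stage_error("digest", {
      write_fragment_bed(fm, frag_bed)
      write_fragment_stats(fragment_stats(fm), stats_prefix)
    })
  }
  add_stage("digest", stats_paths, list(enzyme = cfg$enzyme,
                                        region = unclass(region)))

  ## contacts --------------------------------------------------------------
  filt <- filter_config(cfg$min_mapq, cfg$drop_same_fragment,
                        cfg$drop_adjacent_fragments)
  frag_prefix <- out("matrix_fragment")
  frag_paths <- paste0(frag_prefix, c(".triplets.tsv", ".json"))
  if (fresh(frag_paths)) {
    cm <- read_matrix(frag_prefix)
  } else {
    cm <- .stage_error("contacts", {
      pairs <- read_pairs(cfg$pairs)
      assign_pairs(pairs, fm, filt)
    })
    write_matrix(cm, frag_prefix)
  }
  add_stage("contacts", frag_paths,
            list(filters = unclass(filt),
                 totals = cm$metadata$totals))

  ## bin -------------------------------------------------------------------
  bin_prefix <- out("matrix_binned")
  bin_paths <- paste0(bin_prefix, c(".triplets.tsv", ".json"))
  if (fresh(bin_paths)) {
    bm <- read_matrix(bin_prefix)
  } else {
    bm <- .stage_error("bin", bin_matrix(cm, cfg$resolution))
    write_matrix(bm, bin_prefix)
  }
  add_stage("bin", bin_paths, list(resolution = cfg$resolution))

  ## domains ---------------------------------------------------------------
  ins_path <- out("insulation.bedGraph")
  bnd_path <- out("boundaries.bed")
  profile <- .stage_error("domains",
                          insulation_profile(bm, cfg$window_bins))
  boundaries <- .stage_error("domains", call_boundaries(profile, cfg$delta))
  .stage_error("domains", {
    write_insulation_bedgraph(profile, ins_path)
    write_boundaries_bed(boundaries, region$chrom, bnd_path)
  })
  add_stage("domains", c(ins_path, bnd_path),
            list(window_bins = cfg$window_bins, delta = cfg$delta,
                 n_boundaries = nrow(boundaries)))

  ## loops -----------------------------------------------------------------
  loop_path <- out("loops.bedpe")
  loops <- .stage_error("loops",
                        call_loops(bm, cfg$loop_min_separation,
                                   cfg$loop_enrichment, cfg$loop_min_count))
  .stage_error("loops", write_loops_bedpe(loops, loop_path))
  add_stage("loops", loop_path,
            list(min_separation = cfg$loop_min_separation,
                 enrichment = cfg$loop_enrichment,
                 min_count = cfg$loop_min_count, n_loops = nrow(loops)))

  ## enhancers -------------------------------------------------------------
  candidates <- NULL
  if (!is.null(cfg$peaks)) {
    enh_prefix <- out("enhancers")
    candidates <- .stage_error("enhancers", {
      anchor <- if (identical(cfg$anchor, "auto")) {
        if (!nrow(loops))
          stop("anchor 'auto' requested but no loops were called")
        genomic_interval(loops$chrom[1], loops$start2[1], loops$end2[1])
      } else parse_genome_coordinate(cfg$anchor)
      peaks <- read_bed(cfg$peaks)
      cons <- if (is.null(cfg$conservation)) NULL
        else read_bedgraph(cfg$conservation)
      call_enhancer_candidates(anchor, peaks, cons,
                               merge_gap = cfg$merge_gap,
                               min_cons = cfg$min_cons)
    })
    .stage_error("enhancers", write_enhancer_candidates(candidates, enh_prefix))
    add_stage("enhancers", paste0(enh_prefix, c(".bed", ".json")),
              list(anchor = cfg$anchor, merge_gap = cfg$merge_gap,
                   min_cons = cfg$min_cons,
                   n_candidates = nrow(candidates)))
  }

  ## motifs ----------------------------------------------------------------
  hits <- NULL
  if (!is.null(cfg$motifs) && !is.null(candidates)) {
    hits_path <- out("motif_hits.tsv")
    hits <- .stage_error("motifs", {
      pwms <- read_jaspar(cfg$motifs)
      annotate_enhancers(candidates, sequence, region, pwms,
                         threshold = cfg$motif_threshold)
    })
    .stage_error("motifs", write_motif_hits(hits, hits_path))
    add_stage("motifs", hits_path,
              list(threshold = cfg$motif_threshold, n_hits = nrow(hits)))
  }

  manifest <- list(
    tool = "t2ctools",
    version = as.character(utils::packageVersion("t2ctools")),
    seed = cfg$seed,
    config = Filter(Negate(is.null), unclass(cfg)),
    config_json = as.character(cfg_digest),
    stages = stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  attr(manifest, "binned_matrix") <- bm
  attr(manifest, "boundaries") <- boundaries
  attr(manifest, "loops") <- loops
  attr(manifest, "enhancers") <- candidates
  attr(manifest, "motif_hits") <- hits
  invisible(manifest)
}
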