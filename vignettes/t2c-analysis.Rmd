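---
title: "Targeted chromatin capture analysis with t2ctools: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted chromatin capture analysis with t2ctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2ctools)
```

## The problem

Targeted chromatin capture (T2C) is a capture-enriched 3C-family assay:
chromatin is cross-linked, digested with a restriction enzyme, re-ligated,
and the ligation products of a probe-tiled region of interest are enriched
and sequenced. Each sequenced pair witnesses the spatial proximity of two
restriction fragments. At a locus such as human *ZEB2* — a developmental
transcription factor gene flanked by a multi-megabase gene desert harboring
its distal regulatory elements — a capture design of a few megabases yields
fragment-resolution in-cis proximity maps at a fraction of the sequencing
cost of genome-wide methods.

`t2ctools` implements the computational chain downstream of read alignment:

1. **digest** — in-silico restriction digestion of the capture region;
2. **contacts** — assignment of positioned read pairs to fragments,
   filtering, and construction of the symmetric proximity matrix;
3. **bin** — aggregation to a fixed genomic resolution;
4. **domains / loops** — insulation-score TAD boundary detection and
   observed/expected point-loop calling;
5. **enhancers** — candidate-enhancer calling inside a distal loop anchor
   from H3K27ac peaks with conservation support;
6. **motifs** — PWM scanning of the candidates at a relative-score
   threshold.

A synthetic-data generator produces every input with planted ground truth,
so the full chain is testable without any external download.

## Coordinate conventions

All internal coordinates are 0-based half-open (BED convention): interval
length is `end - start` and adjacent intervals share an edge. Published
coordinates come in two flavors and differ by one base, which matters when
a printed number like "20 kb" or "295 kb" should be reproduced exactly:

* gene/feature annotations (e.g. `chr2:145141942-145277958`) are 1-based
  fully inclusive — length `end - start + 1`;
* round-number map coordinates (bin edges, e.g.
  `chr2:145260000-145280000`) are half-open edge positions — length
  `end - start`.

`parse_genome_coordinate()` makes the choice explicit per call. One
consequence worth stating: *ZEB2* is transcribed from the minus strand, so
its TSS-side coordinate is the *larger* printed gene coordinate; distances
"upstream of the TSS" are measured from that edge.

```{r coordinates}
cap <- parse_genome_coordinate("chr2:143270465-150642631", "inclusive")
round(interval_length(cap) / 1e6, 1)   # capture design length in Mb

zeb2 <- parse_genome_coordinate("chr2:145141942-145277958", "inclusive")
region_b <- parse_genome_coordinate("chr2:145760000-145780000")
interval_distance(zeb2, region_b)      # distal-anchor distance in bp
```

## In-silico digestion

Enzymes are described by an IUPAC pattern and a cut offset; ApoI
(`R^AATTY`) and DpnII (`^GATC`) are built in. Matching is IUPAC-expanded on
the pattern side only: an `N` in the *sequence* never satisfies a non-N
pattern symbol, so assembly gaps lengthen fragments rather than fabricating
sites (a warning fires when the N fraction exceeds 1%). Only the top strand
is scanned, which is complete for palindromic sites; non-palindromic
enzymes are rejected outright rather than silently half-digested.
Soft-masked lowercase bases are uppercased: capture probe design does not
respect repeat masking, so neither does the digest.

Under uniform base composition, 4 of the 4096 hexamers match `RAATTY`, so
random sequence averages one ApoI site per 1024 bp; the ~500 bp mean
fragment size of a real capture region reflects its base composition.
`fragment_stats()` reports count, mean (identically region length /
fragment count, since fragments tile the region) and a histogram.

## Proximity matrix construction

Each mate of a pair is assigned to the fragment containing its 5' mapped
position. This is deliberately simpler than the fragment-end walking of
full Hi-C pair tools; for capture data with short fragments the two rules
agree for the overwhelming majority of mates, and the simple rule is exact
to state and reproduce. Filters, each with its drop reason tallied so that
`input = kept + sum(dropped)` always holds:

| parameter | default | rationale |
|---|---|---|
| `min_mapq` | 30 | standard uniqueness threshold for BWA-style aligners |
| `drop_same_fragment` | `TRUE` | self-circles/undigested products carry no proximity signal |
| `drop_adjacent_fragments` | `FALSE` | adjacent re-ligation is partly informative; no community consensus, so off but available |
| `restrict_to_region` | `TRUE` | off-target pairs are tallied, not analyzed; `FALSE` makes them a hard error |

Trans-chromosomal pairs are always excluded from the (in-cis) matrix and
counted in metadata. No balancing (ICE or similar) is applied — the maps
are raw binned counts, and balancing a capture region with its enrichment
edge effects is a research question of its own, out of scope here.

Binning assigns each fragment to the bin containing its midpoint. The
alternative — splitting a fragment's count across the bins it overlaps —
conserves mass only in expectation and produces non-integer matrices; the
midpoint rule is deterministic and conserves integer counts exactly, which
is also what makes the simulator's truth matrices exactly reproducible by
the pipeline. 20 kb is the default resolution, the scale at which TAD
structure in a ~2 Mb window is typically read.

## Insulation score and boundaries

The insulation value of bin *i* with window *w* is the mean count in the
*w* × *w* square of pixels linking the *w* bins ending at *i* to the *w*
bins following it. The normalized score is `log2(value / mean(value))`
over the region. Boundaries are strict local minima with score
`<= -delta`; a flat run of equal minima is reported once, at its leftmost
bin, and the reported genomic position is the boundary bin's end edge.

Defaults: `window_bins = 5` (100 kb at 20-kb bins) and `delta = 0.5`
(the window must hold less than ~71% of the average crossing signal). The
insulation-square method was chosen over directionality-index or arrowhead
approaches because it has the fewest parameters and directly formalizes
the "sharpness of domain edges" a human reader uses on a heatmap.

Numerical edge cases: the first and last `w` bins lack a full window and
are undefined; a window with zero counts would give `log2(0) = -Inf`, so
such bins are also flagged undefined rather than propagating infinities
(in a noise-free block-diagonal toy matrix this can shift the reported
minimum one bin off the exact junction; with realistic distance decay the
crossing window is never empty). An all-zero matrix yields an all-undefined
profile and no boundaries.

## Loop calling

The expected count at bin separation *d* is the mean over all pixels at
that separation, zeros included. A pixel (*i*, *j*) is a loop when

* `j - i >= min_separation_bins` (default 3; separations 0–1 are dominated
  by self- and adjacent-ligation and are never considered),
* observed `>= min_count` (default 5),
* observed/expected(*d*) `>= enrichment_threshold` (default 3), and
* observed exceeds the mean of its surrounding ring (Chebyshev radius 1,
  the 8-neighborhood) by the same factor — the local test rejects broad
  ridges such as domain corners.

Adjacent candidate pixels are merged by non-maximum suppression, keeping
the maximal-enrichment pixel of each cluster. With count thresholds this
low, isolated Poisson spikes at large separations can and do qualify in
sparse data; the calls are therefore ranked by enrichment, and significance
testing (negative-binomial models etc.) is deliberately out of scope. On
the default synthetic experiment the planted loop is the top-ranked call.

## Enhancer candidates

Given a distal loop anchor, H3K27ac peaks with *any* overlap of the anchor
are selected — a peak straddling the anchor edge is biologically one
element and is kept whole (truncation is available but off by default).
Peaks separated by at most `merge_gap` (default 2000 bp, the scale of a
nucleosome-depleted gap between adjacent enhancer modules) are merged into
clusters; clusters are annotated with supporting-peak count and
length-weighted mean conservation (uncovered bases count 0) and named
`Enh1..n` left to right. `min_cons` defaults to 0: conservation is
reported, not filtered, because no principled universal threshold exists —
the ranking is left to the analyst.

## Motif scanning

Count profiles (JASPAR PFM text) are converted to log2-odds with a total
pseudocount of 0.8 split by the background frequencies (uniform by
default), the convention of standard motif-database tooling. The score of
a window is rescaled between the minimal and maximal attainable scores to
a relative score in [0, 1]; "confidence > 90%" means relative score
`>= 0.90`. Both strands are scanned (the minus strand by scoring against
the column-reversed, row-complemented matrix); windows containing `N` are
skipped; a degenerate all-flat profile (max = min) scores every window 1.0
by convention. Ties in output ordering break by (offset, strand `+` before
`-`, motif name).

The shipped profile file (`inst/extdata/motifs_synthetic.jaspar`) contains
five *synthetic* near-deterministic profiles named after factors commonly
examined in enhancer analyses (ETS1, FOXD2, HOXB2, SOX10, YY1). They are
built in code, are not database entries, and exist so the planted-motif
recovery chain has a self-contained fixture; their consensi avoid the ApoI
core `AATT` so planting them does not systematically add restriction
sites.

## The synthetic experiment

The generator emulates the structures a capture experiment of a ZEB2-like
locus reports, with every planted fact recorded as truth:

* **genome**: i.i.d. uniform bases over 2 Mb with concrete `RAATTY`
  instances planted at exponential spacing. The planted rate is corrected
  for the background rate of uniform sequence (1/1024 per bp) so the
  overall mean fragment size hits the 500 bp target; the truth fragment
  map is simply the digest of the emitted sequence, so background sites
  are included by construction.
* **contact model** (bin level): pixel weight
  `(d + 1)^(-alpha) * exp(tau * same_TAD) * gamma_loop` for `d >= 2`,
  normalized over the upper triangle. Defaults: `alpha = 1` (the classic
  in-cis decay exponent), `tau = 1` (e-fold within-TAD enrichment, enough
  to make domains visually and computationally crisp without swamping the
  decay), three TADs (boundaries at bins 15 and 75 of 100), and one loop
  at bins (30, 55) with `gamma = 8` — a 25-bin (500 kb) span standing in
  for a promoter contacting a distal regulatory cluster. Separations 0–1
  carry zero probability, mirroring their exclusion from loop calling.
* **reads**: `n_pairs = 1e5` bin pairs drawn multinomially, each endpoint
  placed uniformly within a uniformly chosen fragment whose midpoint lies
  in the bin — the same midpoint rule `bin_matrix()` uses, which is what
  makes pipeline-recomputed matrices equal the truth matrix *exactly*, not
  just statistically.
* **tracks**: one peak per planted enhancer; conservation 1.0 over
  enhancers on a 0.1 baseline; the named motif's consensus written at the
  enhancer's center and its offset recorded. Editing the sequence can
  create or destroy restriction sites, so the fragment map is re-digested
  after planting.

What the generator does **not** emulate: sequencing error, PCR duplicates,
capture-efficiency bias along the region, trans contacts, fragment-level
decay structure within bins, and the correlated noise of real Hi-C-family
data. Passing the recovery tests therefore demonstrates the correctness of
the pipeline's bookkeeping and the detectability of planted structure
under clean Poisson-like sampling — not performance on real libraries.

```{r generator, eval = FALSE}
spec <- simulation_spec()                        # the "zeb2-like" defaults
sim <- simulate_t2c_experiment(spec, "sim-out")  # writes all pipeline inputs
```

## The orchestrated pipeline

`run_t2c_pipeline()` executes all stages from one YAML configuration,
writes a JSON manifest recording the package version, every parameter
actually used, pair-filter tallies and per-output md5 checksums, and
aborts with the stage name on any failure. Unknown configuration keys are
rejected before anything runs. Reruns under an unchanged configuration are
byte-identical; with `force = FALSE`, stages whose outputs still match
their recorded checksums are loaded from disk rather than recomputed. The
enhancer anchor defaults to `"auto"`: the distal anchor of the strongest
called loop, which is how a promoter-to-desert loop would be followed up
in practice.

## Problem sizes used by the test suite

The suite validates against brute-force oracles (1,000 random digests up
to 5 kb, 50 random PWM scans, per-base conservation means, naive window
means on 30 × 30 matrices) and runs 20 seeded replicates of the default
synthetic spec for boundary/loop recovery at the bin level, plus one full
read-level experiment (1e5 pairs over 2 Mb) through the complete pipeline.
These sizes keep the whole suite in the low minutes on one CPU while
leaving every statistical check comfortably powered.

## Known limitations

* Mate-to-fragment assignment by 5' position only; no fragment-end
  walking, no duplicate marking, no BAM parsing (positioned pairs are the
  input contract).
* Raw counts only; no matrix balancing or between-condition statistics.
* Loop calls are threshold-based and unranked by significance; treat the
  enrichment ordering as the confidence ordering.
* TAD calls are single-scale (one window); no nested-domain tree.
* Peak calling is out of scope — H3K27ac peaks are consumed, not called.
* The hg19-scale digest of a real capture region is supported by the same
  code paths but is not exercised in the default suite, which is fully
  synthetic by design.
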