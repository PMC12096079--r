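---
title: "Methods: POM/POI peak calling, persistent-A detection and the synthetic truth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: POM/POI peak calling, persistent-A detection and the synthetic truth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochm6a)
```

This vignette documents the models, parameter choices and numerical
policies behind `stochm6a`, in the order data flows through the pipeline.

## Coordinate conventions

All internal coordinates are 0-based, half-open `[start, end)` and
transcript-oriented (5'→3' on the coding strand). GFF3 input (1-based
closed) is converted on read; BED output stays 0-based half-open; GFF3
output converts back. Minus-strand coverage vectors are reversed at load
time, so every downstream operation is strand-agnostic. A site at
position `p` lies in a peak iff `start <= p < end`; a motif lies in a
peak only if its *entire* extent does. Using one convention everywhere
removes a notorious class of off-by-one disagreements between
transcript-space and genome-space reports, and both projections are
emitted (TSV in transcript space, BED in genome space) because published
peak tables are ambiguous about which space they use.

## The windowed enrichment model

Enrichment is scored per transcript, not per genome position, because
bacterial operons put genes of very different expression on one
chromosome; the transcript median is the natural within-unit background.

* **Windows.** Width 50 nt, step 25 nt, starting at position 0. A new
  window opens only while the previous one has not reached the
  transcript end, so a 60-nt transcript yields `[0,50)` and `[25,60)` —
  the terminal window is truncated rather than followed by a sliver.
  Windows shorter than 10 nt are never scored, and transcripts shorter
  than the 25-nt step are skipped entirely.
* **POM** = window mean coverage / transcript median coverage, zeros
  included in the median. The window *mean* is also the "coverage" used
  by the depth filter, since the window is the unit of the whole
  procedure.
* **Filter.** A window survives only if mean coverage ≥ 10 *and*
  POM ≥ 3. The alternative reading — discard only windows failing both —
  would keep an 8× window with POM 50, defeating the depth filter's
  purpose, and does not match standard MeRIP practice. Thresholds are
  inclusive: coverage 10.0 and POM 3.0 survive.
* **Shared regions.** A candidate IP window that also passes the filter
  in the matched input sample is background enriched in both libraries
  (rRNA residue, mappability artefacts) and is discarded before POI is
  computed. This is the only reading under which the subsequent POI step
  is not vacuous.
* **POI** = POM_IP / POM_input on the surviving windows, using the raw
  input POM whatever its magnitude. Input POM of exactly 0 would give an
  infinite POI from a single stray read; such windows are dropped with a
  warning instead. Retention requires POI strictly greater than 3, so a
  window at exactly 3.0 is rejected.
* **Zero-median transcripts** have no defined POM. The default policy
  (`zero_median_policy = "drop"`) excludes them — conservative, since a
  mostly-uncovered transcript cannot support a credible enrichment
  ratio. The `"pseudo"` policy substitutes the smallest positive
  per-base depth, for exploratory use on sparse data.
* **Peaks** are maximal runs of overlapping-or-adjacent retained
  windows, scored by their maximum window POI. Counting coalesced peaks
  rather than windows is what makes peak counts comparable across
  transcripts of different lengths.

Replicate merging is a coalescing union: intervals from different
replicates that touch are fused, provenance is kept as the union of
replicate ids, and the merged score is the maximum POI. Motif
restriction (exact matching of GCCAU, UGCCAG, CAGAUC on the transcript
sense strand, overlap-tolerant) is applied *after* merging; the
pre-restriction set is retained as the "unfiltered" set, which is the
one used for cross-method concordance. The variant spelling UGGCAG that
circulates for the second motif is not the default but the motif set is
an argument everywhere.

## The persistent-A model

Deamination converts unmethylated A to inosine, read as G, so
methylation (or protective structure) shows up as reads that stay A. A
reference adenosine is called persistent when depth ≥ 20 and A-fraction
≥ 0.5, both inclusive ("at least"). The persistence denominator defaults
to A+G reads — conversion is the only signal axis, and other bases at a
reference-A position are sequencing noise — with `denominator = "total"`
available since published workflows are not explicit about this choice.
Zero-depth rows are excluded, never divided. Because no
demethylase-treated control branch exists for bacterial samples, the
caller's output is explicitly the union of m⁶A and structured
(conversion-resistant) adenosines; `check_control_sites()` verifies
designated always-persistent positions (the analogue of the two 23S rRNA
m⁶A sites at 1-based 1618/2030 used as internal controls) and can fail
the run under `strict = TRUE`.

## Comparative statistics

* **Percent shared** = 100·|A∩B|/denominator, with the union as default
  denominator because it gives a symmetric statistic; `first`/`second`
  denominators are kept for reproducing asymmetric published numbers.
  "Methylated transcript" means ≥ 1 peak anywhere on the transcript —
  antibody-based peak positions are too imprecise for positional
  identity.
* **Metagene profile.** Each transcript is rescaled to unit length and
  cut into 10 bins; a motif at relative position `p` falls in bin
  `floor(10p)+1`, and the profile is the pooled ratio of peak-contained
  ("modified") motifs to all motifs per bin. Pooling is additive over
  transcripts. Empty bins give `NA`, not 0.
* **Rank-sum testing** between conditions uses the per-motif relative
  positions of modified motifs as the sampling unit by default (the
  10 bin ratios are available via `unit = "bins"`, since either unit is
  defensible). The test is `stats::wilcox.test`, two-sided: exact for
  small tie-free samples, normal approximation with tie correction
  otherwise. Samples with fewer than two observations return `NA` with a
  warning.
* **Expression.** RPKM = count/((length/1000)·(libsize/10⁶)); log2 with
  a +0.01 RPKM pseudocount before fold changes (published analyses are
  silent on the pseudocount; 0.01 is small against the ~1 RPKM detection
  floor). DE flag at |log2FC| ≥ 1, Pearson r on log2 RPKM. Expression
  groups sort ascending with gene-id tie-breaks, split into k groups
  with sizes differing by ≤ 1 and the remainder assigned to the lowest
  group — fully deterministic even with tied values.

## The synthetic truth model

The generator emulates the *data model* the two assays imply, not the
assays themselves:

* **Transcriptome.** `n_transcripts` (default 200) random-sequence
  transcripts of 300–1500 nt, random strand, laid on one synthetic
  chromosome with 100-nt spacers — enough to exercise both strand
  projections and GFF/bedGraph round trips. Motifs occur by chance in
  the random background *and* are planted at peak centres, so motif
  restriction is a real filter, not a tautology.
* **Coverage.** Per-base depths are i.i.d. negative binomial
  (size = `nb_dispersion`, default 10; `Inf` gives the Poisson limit)
  around an expression-scaled mean: log2-expression is normal
  (sd 1.5 ≈ the spread of a bacterial transcriptome), scaled so the
  typical transcript sits at `base_depth` (default 20×, a realistic
  bacterial RNA-seq working depth). IP means are multiplied by
  `enrichment` (default ρ = 8) inside planted windows. Planted peaks are
  exactly one 50-nt window on the 25-nt grid (default), making
  truth-to-call matching unambiguous; a call is a true positive iff it
  overlaps a truth interval by ≥ 1 nt — a rule stated here because peak
  callers in this family are published without a scoring rule.
  Real coverage is autocorrelated along transcripts (fragmentation,
  GC); i.i.d. noise is a deliberate simplification, so passing recovery
  tests demonstrates correctness of the calling arithmetic, not
  robustness to correlated artefacts.
* **Pileups.** Per-A depth is Poisson(`pileup_depth_mean` = 100 — a
  stand-in; real eTAM depth distributions vary by protocol). A-counts
  are Binomial(depth, 1 − conversion) at background sites
  (conversion 0.99) and Binomial(depth, 0.95) at planted and control
  sites. Under these defaults the closed-form chance that a background
  site reaches 50% persistence is ~10⁻⁴⁰ per site, so essentially all
  false positives in practice must come from *biology* (structure), not
  from the calling statistic — which is the point of the control.
* **Determinism.** The transcriptome is drawn at `seed`, coverage at
  `seed+1`, pileups at `seed+2`; a fixed config reproduces every output
  file byte-for-byte (checksums in the run manifest).

## Problem sizes used in the shipped evaluation

The test suite and `scripts/acceptance.R` run the reference scenario
(200 transcripts, 50 planted peaks, 2 replicates), a null scenario
(ρ = 1), an exact-equivalence sweep of 1000 random ≤ 200-nt transcripts
against a brute-force window enumerator, a 10,000-site background panel
for the persistent-A false-positive check, and 10,000 null draws for the
rank-sum size check — sizes chosen to make Monte-Carlo error small
against every margin being tested while keeping a full run in well under
a minute per scenario.

## Known limitations

* Single-nucleotide truth is only meaningful for the deamination branch;
  windowed peaks have ~50–100 nt resolution by construction.
* No FDR machinery: the procedure is hard-threshold, faithful to the
  published analysis it implements.
* No antibody bias, fragment-length or GC models in the simulator; no
  correlated noise along transcripts.
* The expression module normalises and flags; it is not a differential
  expression test (use DESeq2/edgeR for that).
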