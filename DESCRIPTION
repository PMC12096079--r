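Package: stochm6a
Title: Peak-Over-Input m6A Peak Calling, Persistent-A Site Calling and
    Concordance Statistics for Bacterial Epitranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to locate N6-methyladenosine (m6A) signal in bacterial
    mRNA and to quantify how reproducible that signal is. Implements a
    sliding-window MeRIP-style peak caller based on peak-over-median (POM)
    and peak-over-input (POI) enrichment scores, a base-resolution
    persistent-adenosine caller for deamination (eTAM-style) pileups, and
    the comparative statistics used to judge stochasticity: replicate
    overlap, motif-restricted selection, metagene motif-ratio profiles with
    rank-sum testing, RPKM expression grouping, and cross-method
    concordance. A fully deterministic synthetic-data generator plants
    ground-truth enrichment peaks and persistent sites so that every stage
    can be exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
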