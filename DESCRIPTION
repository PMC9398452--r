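Package: tespread
Title: Quantifying Transposable-Element-Mediated Spreading of Repressive Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the local enrichment of repressive histone marks
    (H3K9me2) that spreads from epigenetically silenced transposable elements (TEs)
    into adjacent euchromatic sequence. Computes spike-in-normalized histone
    modification density (HMD) in 25-bp bins, per-TE magnitude and extent of
    enrichment relative to the local background, TE-to-gene associations and allele
    z-scores, presence/absence calls of TE insertions in population samples from
    contig alignment evidence, exact small-sample nonparametric tests, phylogenetic
    generalized least squares, and k-mer-based quantification of heterochromatic
    repeats. Includes a synthetic-data generator with known ground truth for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    nlme,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
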