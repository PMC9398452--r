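---
title: "Quantifying TE-mediated spreading of repressive chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TE-mediated spreading of repressive chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tespread)
```

## The model

Epigenetically silenced transposable elements (TEs) nucleate repressive
chromatin, and the H3K9me2 deposited on a silenced TE spreads outward into
the flanking euchromatic sequence. `tespread` quantifies this per-insertion
"epigenetic effect" from spike-in-normalized ChIP-seq coverage and carries
the estimates through the downstream comparative and population-genetic
analyses.

The measurement chain is:

1. **HMD.** For each 25-bp bin, histone modification density is
   $\mathrm{HMD} = (E_\mathrm{locus}) / (E_\mathrm{si})$, where
   $E_\mathrm{locus}$ is the ChIP/input fragment-coverage ratio of the bin
   and $E_\mathrm{si}$ the ChIP/input ratio of spike-in barcode fragments.
   Bins with input coverage below 5 fragments are missing data: the ratio is
   too unstable to interpret there.
2. **Local background.** Each TE's flanking signal is normalized by the
   median HMD over the regions 20-40 kb up- and downstream, pooled. Spreading
   in these flies decays within roughly 10 kb, so this band sits outside the
   TE's own signal while still tracking regional chromatin state.
3. **m-HMD.** The 20 kb on each side of the TE is cut into 1-kb windows of
   40 units; a window's m-HMD is the median of its non-missing
   background-normalized units, requiring at least 10 units.
4. **Magnitude** is the m-HMD of the two windows immediately adjacent to the
   TE, averaged over sides (one side alone if the other is missing). A
   magnitude of 1 means no excess over the local background.
5. **Extent** is the count of consecutive windows, outward from the TE,
   with m-HMD above 1, averaged over sides and capped at 20 kb. Window 1
   missing makes the side unestimable; a later missing window terminates the
   run, since continuity above background cannot be confirmed across it.
6. Per-TE estimates are computed per replicate and then averaged; a TE
   missing in one replicate uses the other.

Two-genome estimates (`two_genome_effect`) standardize the focal strain's
flank by the homologous, TE-free flank of a second strain instead of the
local background; TEs inside shared enrichment peaks, with unmappable
homologous sequence, or with an alternative-strain TE within 1 kb of the
homologous site are excluded with a recorded reason. The extent cap of 20 kb
is kept for symmetry with the single-genome estimate.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| bin size | 25 | bp | resolution of the HMD track |
| missing-data cutoff | 5 | input fragments | below this the ratio is noise |
| background band | 20-40 | kb | outside the spreading range, inside the regional chromatin context |
| window width | 1 | kb | per-window medians of 40 units are robust to single-bin outliers |
| minimum units/window | 10 | bins | below this the median is unstable |
| extent threshold | 1 | m-HMD | "above local background"; the extent estimate is robust across 0.75/1/1.25 (tested) |
| flank | 20 | windows | beyond 20 kb no spreading is expected |

## What the synthetic generator emulates

`sim_config()` / `sim_annotations()` / `sim_coverage()` /
`sim_population()` produce genomes with known ground truth:

* a flat HMD background of 1 with Poisson fragment-count noise in ChIP and
  input (negative binomial when `noise_dispersion > 0`) — the simplest model
  consistent with fragment-count data;
* exponential-decay enrichment $A_i e^{-d/\lambda}$ outward from each TE
  boundary. The functional form of the decay is a modeling choice of this
  package: metaprofiles constrain the shape only loosely, and the exponential
  is the simplest monotone decay with a single length scale;
* per-TE amplitudes that are Gamma-distributed around `spread_amplitude`
  with coefficient of variation `amplitude_cv` (default 0.5). Real
  insertions vary widely in effect size; without between-TE variance a rank
  correlation between estimated and true magnitude would be undefined;
* restrained spreading — $\lambda$ multiplied by `genic_restraint_factor`
  (default 0.5, a moderate restraint) — on the side of a TE whose nearest
  gene within 20 kb has a true expression of at least 10 RPKM, emulating the
  antagonism between active transcription and heterochromatin assembly near
  promoters;
* spike-in barcode counts as two Poisson scalars per sample around
  `spikein_mean_input` and `spikein_mean_input * spikein_ratio` (panel
  composition is not simulated);
* population presence/absence evidence with the exact contig geometries the
  caller tests for, including a configurable fraction of degraded evidence
  sets exercising the "missing" path.

What it does **not** emulate: mappability structure, GC and amplification
biases, read-level errors, nested/fragmented insertions, chromatin-state
heterogeneity between cells, or peak-shaped enrichment unrelated to TEs.
Passing recovery tests therefore demonstrate that the estimators invert the
generative model they assume, not that they are unbiased on arbitrary real
libraries.

The ground-truth extent is itself a random quantity (a run of noisy window
medians), so `expected_extent_mc()` computes the expected run length
directly from the noise model — per window, the probability that the median
of 40 count-ratio units exceeds the threshold — independently of the
estimation code. Recovery runs use 200 TEs spaced at least 100 kb apart at
input coverage 50 so each TE's windows and background band are unconfounded
by neighbours; those problem sizes keep a full recovery experiment under a
minute while leaving the Monte-Carlo error of the comparison far below the
1-kb agreement margin.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere; bin $i$ covers
  $[25(i-1), 25i)$. Windows are anchored at the (merged) TE boundary in
  exact 1-kb steps, and a bin belongs to the window containing its center.
  Partial terminal windows at chromosome ends are dropped.
* **"Fragment coverage"** of a bin is its mean per-base fragment depth —
  standard coverage semantics.
* **Replicates** are kept as separate tracks; per-TE estimates are averaged,
  not the tracks, so replicate-specific missingness cannot leak between
  samples.
* **LOESS** in `te_metaprofile` is local linear (degree 1) with tricube
  weights at span 0.15.
* **Merging rules** (`merge_te_records`): same-family records within 500 bp
  merge into their span; different-family records within 500 bp are both
  removed; chains resolve left-to-right after sorting (deterministic and
  order-independent); records with *unassigned* family are neither merged
  nor removed, since family identity cannot be compared. DINE-1 and the
  telomeric HeT-A/TART/TAHRE families are dropped after merging.
* **Family assignment** (`assign_families`): a TE is assigned when at least
  80% of its *covered query bases* — the union of aligned query intervals,
  the natural denominator when hits overlap — fall in a single family.
  The reference set grows **between** rounds (four rounds total), not
  within a round, so results do not depend on the processing order of TEs.
  Assignment precedes merging.
* **Side z-scores** divide by the sample SD of the per-TE side differences;
  when every difference is exactly 0 the z-scores are all 0, while a zero SD
  with non-zero differences is an error. The allele z for expression ranks
  divides by the sample SD of the four per-replicate rank values; the
  gene-body allele z pools the per-bin values of both strains before taking
  the SD (the literal reading of "SD of both strains"; per-strain SDs
  averaged would be the alternative, flagged for sensitivity analyses).
* **Nearest-gene ties** break toward the smaller gene id; orientation is NA
  for gene-overlapping TEs.
* **Flanking windows overlapping another TE** are retained but flagged
  (`flank_overlaps_te`) for sensitivity analyses.
* **Close/far gene binning** for interaction regressions defaults to the
  median TE-gene distance and is configurable.
* **Population caller**: evidence satisfying both the absence and a
  presence rule is contradictory and yields "missing" (verified mutually
  exclusive by exhaustive small-geometry enumeration). No minimum length is
  imposed on wholly-internal contigs beyond what the aligner emits.
  Boundary refinement from deletion SV calls is consumed, when available,
  as updated TE coordinates; the default is unrefined coordinates.
* **Exact tests**: the Mann-Whitney two-sided p is
  $2\,P(U' \le \min(U, n_1 n_2 - U))$ from the fully enumerated null;
  the binomial sign test doubles the smaller tail at $p_0 = 0.5$; the
  Spearman p is exact by full permutation for untied data with $n \le 9$
  and otherwise uses the t approximation. The exact route is the default
  for $n = 8$ because at these sample sizes the approximation can move a
  p-value across conventional thresholds.
* **PGLS** uses `nlme::gls` with `ape::corBrownian`; with an
  identity-proportional covariance (star tree) it reproduces OLS to
  numerical precision, which the tests assert.
* **k-mers** are counted in canonical (strand-collapsed) form; the
  threefold enrichment threshold is inclusive, computed by cross
  multiplication to avoid floating-point edge effects; k-mers absent from
  the input but present in the IP count as infinitely enriched. Abundance
  normalizers (uniquely mapped MAPQ >= 30 read counts, or total read
  counts for PCR-free libraries) are externally supplied scalars, since
  alignment is outside this package's scope.

## Worked example

```{r example}
cfg <- sim_config(genome_length = 4e6, n_chromosomes = 2, n_tes = 30,
                  n_genes = 30, spread_amplitude = 2, decay_length = 2000,
                  mean_input_coverage = 50, min_te_spacing = 100000,
                  seed = 7)
ann <- sim_annotations(cfg)
cov <- sim_coverage(ann, cfg)
hmd <- lapply(cov$replicates, function(r)
  compute_hmd_track(r$chip, r$input,
                    spikein_enrichment(r$spikein_chip, r$spikein_input)))
eff <- average_te_effects(te_effect_table(hmd, ann$tes))
m <- merge(eff, cov$truth, by = "te_id")
cor(m$magnitude, m$true_magnitude, method = "spearman")
mean(m$extent, na.rm = TRUE)
```

```{r stats}
# the analytically determined small-sample statistics
sign_test_binom(18, 23)$p_value
mwu_test(c(1.1, 1.2, 1.3, 1.4), c(2.0, 2.2, 2.4, 2.6))$p_value
```

## Known limitations

* The estimators assume an additive, locally flat background; steep regional
  HMD gradients inside the 20-40 kb band will bias magnitude slightly.
* Medians of count ratios at low coverage are biased; the missing-data
  cutoff mitigates but does not remove this, which is why recovery claims
  are stated at input coverage around 50.
* Family assignment consumes externally produced alignment hit tables;
  aligner sensitivity, not this package, bounds what can be assigned.
* The population caller trusts the supplied contig alignments; chimeric
  contigs that are not contradictory under its rules can still mislead it.
* `suvar_screen` treats genomes as exchangeable given the species complex;
  with more structured phylogenies the PGLS layer should be used instead.
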