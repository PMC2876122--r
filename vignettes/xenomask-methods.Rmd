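---
title: "Masking cross-species hybridisation in xenograft expression profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masking cross-species hybridisation in xenograft expression profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenomask)
```

## The problem

Human tumour cells engrafted in an immunodeficient mouse are usually profiled
on human-designed arrays without separating out residual mouse cells. Mouse
RNA can hybridise to human probes wherever the two genomes are locally
similar, adding spurious signal to the affected transcript clusters. On
whole-transcript designs, where probes tile the full transcript rather than
the divergent 3' UTR, this risk is larger. `xenomask` implements two
complementary ways of identifying the susceptible transcript clusters, the
machinery to combine and apply the resulting masks, and the concordance
statistics used to judge whether a mixture of human and mouse material still
yields a species-specific profile.

## The in silico mask

A probe is called a **hit** when it matches the host genome with 100%
identity or with a single base mismatch, on either strand, ungapped. The hit
criterion admits no indels, so the comparison is a pure Hamming distance over
25-mer windows.

`find_hits()` implements this natively with a seed-and-extend search:
`build_seed_index()` stores genome 12-mers in a hash, and each query is
seeded with the two 12-mers at its ends (offsets 0 and 13 of a 25-mer).
Because those two tiles are disjoint, a single mismatch can dirty at most one
of them, so looking both up in an every-position (step 1) index finds every
qualifying placement — a pigeonhole guarantee rather than a heuristic. The
index also accepts the classic seeding parameterisation of tile 12 / step 7;
we default to step 1 because a stepped tiling provably misses some
single-mismatch placements (the two stepped tiles that fall inside a 25-mer
window overlap in 5 positions, and a mismatch there dirties both). For probes
shorter than twice the tile the ends overlap, the guarantee fails, and
`find_hits()` falls back to the exhaustive scan. `brute_force_hits()` is a
deliberately simple full-window scan kept as an independent oracle; the test
suite asserts exact set equality between the two on more than a thousand
random and planted instances.

Hits are propagated up the three-tier hierarchy by `derive_insilico_mask()`:

1. every hit probe is removed from **every** probeset containing it;
2. a probeset is removed when **strictly fewer than 50%** of its original
   probes remain;
3. a transcript cluster is masked when **at least 50%** of its original
   probesets have been removed.

The boundary semantics are deliberate and tested: a probeset with exactly
half its probes remaining is kept, a cluster with exactly half its probesets
removed is masked. Denominators are the design-time association counts, never
post-removal counts.

## The experimental mask

Pure host tissue hybridised to the human array measures cross-species
hybridisation directly. `derive_experimental_mask()` ranks transcript
clusters by mean log2 signal across the host-only replicates and selects the
top `ceiling(top_fraction * N)`, extending the selection across any tie at
the cutoff. The recorded threshold is the minimum selected mean — the
realised intensity cutoff on that data set. We define the mask by rank rather
than by a fixed intensity because the published cutoff value for any one
experiment (7.56 on a log2 scale for the original data) is a consequence of
the rank rule, not its definition. Means are arithmetic on the log2 scale,
matching how normalised signals are reported throughout.

The two masks are combined by set union (`combine_masks()`), and
`apply_mask()` removes the masked rows from a cluster-level matrix, because
downstream statistics operate on the reduced cluster set.

## Preprocessing

`preprocess_pipeline()` chains four steps:

* **Quantile normalisation** (via `limma::normalizeQuantiles`, ties receiving
  the mean of the target values they span) on the linear scale.
* **Low-intensity floor at 16 then log2** (`rma16_log()`). The floored
  variant of RMA popularised by desktop analysis suites is characterised by
  low-end thresholding; the exact proprietary formula is unpublished, so the
  package models precisely the floor-then-log behaviour and documents it as
  such. The floor also gives degenerate (zero-signal) probes a finite log
  value.
* **Median-polish summarisation** (`median_polish_summarise()`, rows first,
  tolerance 1e-4, at most 10 sweeps; `stats::medpolish` does the sweeps). The
  cluster signal is `overall + sample effect`. Ten sweeps is part of the
  contract: hitting the cap on noisy clusters is expected and silent.
  Single-probe clusters pass through unchanged; probes shared across clusters
  contribute to each polish independently.
* Optional **mean batch adjustment**: each batch is shifted additively so its
  grand mean equals the global grand mean, leaving within-batch variances
  untouched.

Host-only arrays are normalised separately from the mixture arrays. Quantile
normalisation forces identical marginal distributions within a run, so
normalising host arrays jointly with human arrays would erase exactly the
distributional difference (the depressed high-intensity tail of host-only
hybridisations) that the experimental mask and the signal histograms rely on.

## Concordance statistics

* `pearson_summary()` computes the full sample-by-sample correlation matrix
  and summarises per group pair: within a group of *k* samples the
  *k(k−1)/2* unordered pairs, across groups the full *k₁·k₂* product (4 vs 4
  arrays therefore give 6, 6 and 16 comparisons; 3 vs 8 give 24), with
  SE = SD/√n.
* `mva()` reports per-cluster `M = meanA − meanB` and `A = (meanA + meanB)/2`;
  a cluster is a 2-fold outlier when `|M| ≥ 1` (inclusive — the lines drawn
  at log2 = ±1 on MvA plots).
* `msd_ranked()` orders clusters by descending reference mean and returns the
  mean squared distance over the identity pairing; the ordering fixes the
  plotting order and leaves the value unchanged.
* `moderated_t_test()` implements the empirical-Bayes moderated t: per-cluster
  residual variances on `d` degrees of freedom are shrunk toward a prior
  `s0²` with weight `d0`, estimated by the method of moments on `log s²`
  (matching the mean and excess spread of the log variances against a
  scaled-F model, with a Newton inversion of the trigamma function). The
  moderated statistic is referred to a t distribution on `d0 + d` degrees of
  freedom; when the observed log variances show no excess spread the prior
  dominates (`d0 = Inf`) and every cluster shares `s0²`. Clusters with zero
  residual variance are excluded from hyperparameter estimation but still
  moderated. The test suite cross-checks the hyperparameters, statistics and
  p-values against an independent reference implementation of the same
  model. P-values are adjusted by Benjamini–Hochberg step-up
  (`bh_adjust()`, a validated wrapper over `stats::p.adjust`).

## The synthetic mixing study

`simulation_config()` defines the study conditions; its defaults are the
conditions all package-level validation runs under, chosen once:

* **Design:** clusters of 4 probesets × 4 probes of 25-mers, mirroring the
  hierarchy of whole-transcript designs at miniature scale.
* **Mixtures:** human fractions 1.0, 0.95 and 0.90 in triplicate, plus
  host-only (NES) arrays in triplicate — the graded mixtures used to test
  whether ≤10% host material skews the profile.
* **Contamination:** a configured fraction of clusters is planted from the
  host genome. `ceiling(0.75 × probesets)` of a contaminated cluster's
  probesets are copied verbatim (or with exactly one substitution) from
  genome windows. Planting 75% rather than the minimal 50% keeps the
  cluster-level contamination shift close to the probe-level shift: the
  median polish takes a median over probes, and with only half the probes
  planted the summary lands halfway between contaminated and clean probes.
  Every planted cluster satisfies the in silico rule by construction; every
  other probe is rejection-sampled (via the indexed matcher, whose exactness
  the oracle suite establishes) to have **no** placement within one mismatch,
  giving a clean negative set. Mask recovery on this design is therefore an
  exact sensitivity/specificity-1 check, not a statistical one.
* **Signal model:** linear-scale probe intensity
  `f·H(cluster) + (1−f)·(A(probe) + B)` with multiplicative log-normal noise
  (SD 0.1 on the log2 scale) — the standard microarray error model, keeping
  linear-scale positivity. `H` is log2-normal (mean 8, SD 1.5), `B = 30` is a
  small constant optical background so host-only arrays sit at background
  rather than zero, and `A = host_affinity_fold × H` for planted probes, zero
  otherwise. The default fold of 20 reflects that planted probes are
  essentially perfect host probes: at a 90% human mixture the probe-level
  shift is `log2(0.9 + 0.1·fold)`, so 20 makes contamination a clear 2-fold
  effect (≈1.5 log2), matching the visible MvA outliers that masking removes
  on real mixtures; a fold of 10 sits just below the 2-fold line and is used
  where a 10× condition is explicitly studied. No sequence-thermodynamic
  model is attempted — the hybridisation strength of a partial homolog is not
  predictable from mismatch count alone, so affinity is an explicit parameter
  rather than a derived quantity.
* **Experimental-mask recovery** is evaluated at `top_fraction` equal to the
  planted contamination fraction (0.05): a rank-based top-1% rule cannot, by
  construction, contain 5% of clusters, so matching the fraction is the
  meaningful recovery condition.

What the generator does **not** emulate: real probe-affinity heterogeneity
within a cluster, partial homology (planted probes are all-or-nothing
cross-hybridisers), correlated biological replicates, batch structure, or
array-spatial artefacts. Passing the recovery tests therefore shows the mask
logic is correct under the stated model, not that any particular real
xenograft data set is contamination-free.

## Problem sizes and numerical choices

Package-level validation uses 1,000-cluster designs (16,000 probes) against
a 50 kb host genome, with matcher oracle-equivalence sweeps over 50 random
2 kb genomes × 20 probes each, and a 1,000-cluster null for the moderated-t
calibration; these sizes give exact recovery checks and stable Monte-Carlo
properties while keeping a full run in the order of a minute. Ties in
medians use the midpoint convention of the polish; quantile-normalisation
ties receive the mean of the values they span; the experimental-mask tie
rule extends the selection rather than truncating it, so the selection size
is `≥ ceiling(top_fraction·N)` with equality in the absence of ties.
Ambiguity codes (`N`) in probes never match anything and are reported as
zero hits with a warning. Coordinates are 0-based half-open on the plus
strand; a minus-strand hit is reported at the plus-strand coordinates of the
matched window, and hits are deduplicated and sorted by (target, start,
strand).

## Known limitations

* The mask operates at transcript-cluster granularity; probe-level masking
  followed by re-summarisation is deliberately out of scope.
* The in silico route needs the host genome and the array's mapping table as
  inputs; it re-implements the hit criterion natively and does not parse
  alignment-tool output.
* Whether a probe hits once or many times is collapsed to a boolean before
  masking, which is exactly what the removal rules consume.
* Absolute MSD values depend on the scale convention of the profiles being
  compared; only relative statements (masked < unmasked) are meaningful
  across conventions.
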