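# xenomask

Species-specific expression profiling of human tumour xenografts grown in
mouse hosts.

## The problem

Xenograft tissue harvested from an engrafted mouse contains residual mouse
cells. On human whole-transcript arrays, mouse RNA cross-hybridises to any
probe that closely matches the mouse genome, inflating the signal of the
affected transcript clusters and potentially skewing the profile — a real
concern whenever engraftment is below ~90% human cells, and a measurable one
even above it. `xenomask` is for researchers profiling xenografts (or any
mixed-species sample) on single-species arrays who need to identify and
remove the susceptible transcript clusters.

## The method

Two complementary masks over the array's three-tier hierarchy (probes →
probesets → transcript clusters):

**In silico mask.** A probe is a *hit* if it matches the host genome with
100% identity or a single base mismatch (ungapped Hamming comparison, both
strands). Hits are found with a native seed-and-extend matcher: 12-mer
genome tiles are indexed, each probe is seeded from the exact 12-mers at its
two ends, and since one mismatch can dirty at most one of two disjoint
tiles, an every-position index misses nothing (a brute-force oracle verifies
exact equivalence in the test suite). Hits propagate upward:

1. each hit probe is removed from every probeset containing it;
2. a probeset is removed when < 50% of its original probes remain;
3. a cluster is masked when ≥ 50% of its original probesets are removed.

**Experimental mask.** Pure host tissue is hybridised to the human array;
after quantile normalisation, flooring at 16, log2, and median-polish
summarisation ("RMA-16"-style preprocessing), the top 1% (configurable) of
clusters by mean log2 signal — extended across ties — form the mask, and the
minimum selected mean is the realised intensity threshold.

The masks are combined by union and applied by row removal. Concordance
before/after masking is quantified by Pearson correlation summaries
(within-group pairs and cross-group products), MvA records with the 2-fold
outlier count (|M| ≥ 1), ranked-profile mean squared distance (MSD), signal
histograms, and an empirical-Bayes moderated t-test with Benjamini–Hochberg
correction.

A synthetic data generator (`simulation_config()`,
`simulate_mixture_study()`) builds a miniature mixed-species world — host
genome, array design with planted host-homologous probes, graded
human/host mixtures (100%, 95%, 90% human) and host-only arrays — with known
ground truth, so mask recovery is testable exactly.

## Worked example

```r
library(xenomask)

cfg <- simulation_config(n_clusters = 200, frac_homologous_clusters = 0.05,
                         genome_length = 10000, seed = 11)
st <- simulate_mixture_study(cfg)

# in silico mask from probe-vs-host-genome hits
hits  <- match_probes(st$probes, st$genome)
insil <- derive_insilico_mask(unique(hits$probe_id), st$mapping)

# experimental mask from host-only (NES) arrays
nes_cols <- names(st$groups)[st$groups == "NES"]
nes_cl   <- preprocess_pipeline(st$intensities[, nes_cols], st$mapping)
exper    <- derive_experimental_mask(nes_cl, top_fraction = 0.05)

comb <- combine_masks(insil, exper)

# concordance of 100% vs 90% human mixtures, before and after masking
mix_cols <- names(st$groups)[st$groups %in% c("ALL.100", "ALL.90")]
mix_cl   <- preprocess_pipeline(st$intensities[, mix_cols], st$mapping)
grp <- st$groups[mix_cols]
a <- rowMeans(mix_cl[, grp == "ALL.100"]); b <- rowMeans(mix_cl[, grp == "ALL.90"])
masked <- apply_mask(mix_cl, comb)
am <- rowMeans(masked[, grp == "ALL.100"]); bm <- rowMeans(masked[, grp == "ALL.90"])
```

Output of the run above:

```
hit probes: 120 of 3200
mask_set (insilico): 10 transcript clusters
mask_set (experimental): 10 transcript clusters
experimental threshold: 9.188
mask_set (combined): 10 transcript clusters
2-fold outliers before mask: 10
MSD before mask: 0.1203
2-fold outliers after mask: 0
MSD after mask: 0.00457
recovered truth exactly: TRUE
```

Reading it: 120 of 3,200 probes hit the host genome — exactly the probes of
the 10 planted clusters (5% of 200). Both masks independently recover those
10 clusters; the in silico mask matches the ground truth exactly. Before
masking, the 100%-vs-90% human comparison shows 10 transcript clusters with
a ≥2-fold difference (every contaminated cluster); after applying the
combined mask no outliers remain and the ranked-profile MSD drops ~26-fold —
the mixture profiles become concordant once the cross-hybridising clusters
are removed.

A command-line interface over the same functions is in `inst/cli/xenomask.R`
(subcommands `simulate`, `match`, `mask-insilico`, `preprocess`,
`mask-experimental`, `mask-combine`, `apply-mask`, `qc-concordance`,
`de-test`).

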