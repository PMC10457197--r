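---
title: "methenh: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methenh: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methenh` implements the integrative epigenomic analysis used to
characterize IDH2-mutant acute myeloid leukemia models: the neomorphic
IDH2 R140Q enzyme produces 2-hydroxyglutarate, which inhibits TET
dioxygenases, depletes 5-hydroxymethylcytosine (5hmC), hypermethylates the
genome — including the HLA class I cluster, whose silencing sensitizes the
cells to natural-killer-cell killing — and is partially reversed by mutant-IDH2
inhibition. The package covers: 5mC/5hmC estimation from paired
bisulfite (BS) / oxidative-bisulfite (oxBS) beta matrices; delta-beta
differential calling; genomic- and CpG-context enrichment; enhancer-RNA
(eRNA) annotation from strand-specific nascent-transcription coverage;
negative-binomial differential expression; enhancer-promoter pairing,
overlap tests, preranked GSEA and methylation-retention analysis; and a
truth-tracked synthetic-data generator on which every step is validated.

# 5mC / 5hmC estimation

BS conversion reads 5mC + 5hmC; oxBS reads 5mC alone. Per probe and
sample:

* `h_raw = beta_BS - beta_oxBS` (kept unmodified, may be negative under
  noise), `m = beta_oxBS`;
* for state reporting, `h = max(h_raw, 0)`, and cells with `m + h > 1` are
  jointly rescaled by `1/(m + h)` (counted and reported; impossible for
  mathematically valid beta pairs, rare under noise).

Delta-beta contrasts and the 5hmC/5mC anti-correlation are computed on the
**unclipped** `h_raw`: clipping at zero censors the left tail of the noise
distribution and would bias delta-beta toward positive values at low-5hmC
probes. The clipped estimates are used only when absolute state levels are
displayed.

# Differential methylation calling

`delta_beta()` computes per-probe group-mean differences (alternative
minus reference) per mark; `call_differential()` applies the field's
|delta-beta| > 0.05 convention with **strict** inequality (a probe exactly
at the threshold is not called). For replicated designs a per-probe Welch
t-test with BH adjustment can be attached and combined with the threshold
(`alpha`); with biological duplicates — the design the package emulates —
threshold-only calling is the only workable option, and its error
properties are fully determined by the noise scale: a null probe is called
at rate `2 * pnorm(-T / sigma_delta)` where `T` is the threshold and
`sigma_delta = sqrt(2) * beta_noise_sd` for the 5hmC mark (two assays, two
replicates per group). At the default noise (`beta_noise_sd = 0.03`) this
noise floor is ~24% per null probe, so threshold-only 5hmC calls carry a
substantial false-discovery fraction even though sensitivity for the
planted 0.2 effects is essentially 1; the acceptance report exposes both
numbers rather than hiding the trade-off. Missing values are handled
pairwise-complete per probe; a probe with no observed value in a group is
dropped from that contrast.

Z-score standardization (`standardize_profiles()`) uses the sample
(n - 1) standard deviation row-wise; constant rows become zeros and are
flagged.

# Genomic and CpG context

Each probe receives one feature class, resolving overlaps by the priority
promoter > enhancer > gene_body > intergenic (promoters are the most
specific annotation; 3'/5' UTR classes are merged into the gene body), and
one CpG class from the bp distance `d` to the nearest island edge: island
(`d = 0`), shore (`0 < d <= 2000`), shelf (`2000 < d <= 4000`), open sea
(`d > 4000`), with inclusive upper bounds so boundary probes fall into the
nearer-island class. Promoters are TSS -1000/+500 bp, strand-aware,
half-open — a conventional window, fixed here because no single standard
exists. Enrichment uses the exact one-sided hypergeometric tail (the
one-sided Fisher exact test) in both directions, BH-adjusted within each
direction across classes; both directions are reported because enrichment
and depletion are both of interest (changed 5hmC concentrates in enhancers
and open sea, and avoids promoters and islands).

# eRNA annotation from nascent coverage

Coverage is binned (10 bp default) per strand and sample. Units are
segmented on coverage **pooled across all samples** — segmenting per
condition would bias the annotation toward whichever condition is more
active — and then quantified per sample. Segmentation takes maximal runs of
bins `>= tau`, merges runs separated by at most `gap = 200` bp of
sub-threshold signal, and discards merged runs shorter than
`min_len = 200` bp.

The default threshold is `tau = max(3, ceiling(0.75 * n_tracks))` on the
pooled track. Two alternatives were considered and rejected:

* a quantile rule ("90th percentile of nonzero bins") couples the
  threshold to the genic fraction of the genome — whenever transcribed bins
  exceed ~10% of nonzero bins the quantile lands *inside* the signal range
  and recall collapses; with sparse background it lands at 1-2 and admits
  noise. It remains available as `tau = "q90"` but is not the default;
* lower fixed thresholds interact badly with the merge step: two isolated
  background bins 19-20 bins apart already span `>= 200` bp and pass the
  length filter, so the background above-threshold density must be pushed
  below ~1e-4 per bin. At 0.75 per pooled track the Poisson background
  (mean ~0.8 at the default simulation depth) is at ~1e-5 while the weakest
  transcribed unit sits near 18 reads/bin.

Intergenic segments on opposite strands within `d_pair = 1000` bp are
merged into one bidirectional eRNA spanning their union (greedy
nearest-pair matching, each segment used once, coordinate-ordered
tie-break; unit ids are `eRNA.<chrom>:<start>-<end>` on 0-based half-open
coordinates, so the annotation is deterministic). Segments overlapping a
gene extended by `d_ex = 1000` bp are genic and never eRNA. Genic units
are quantified on their own strand; eRNA units sum both strands.

# Differential expression

* **Size factors**: median-of-ratios over features nonzero in all samples,
  rescaled to unit median (so an exactly doubled sample reports factor 2
  against 1; only ratios matter downstream), with a positive-counts
  pseudo-reference fallback when no feature is everywhere nonzero.
* **Dispersion**: per-feature method of moments on normalized counts within
  conditions, `alpha = max((var - mean)/mean^2, 1e-8)`, then shrunk halfway
  in log space toward a log-linear mean-dispersion trend and **floored at
  the trend**. The floor is the estimator's small-sample calibration: with
  2-3 replicates, a per-feature estimate below the trend is far more likely
  underestimation than signal, and using it directly inflates the Wald
  type-I error to ~0.10 at 3 vs 3; with the floor the null rejection rate
  at nominal 0.05 sits within [0.04, 0.06] across dispersion regimes (the
  acceptance suite measures this). Features with zero pooled variance get
  the floor value `alpha_min`.
* **Wald test**: natural-log ratio of normalized group means with
  delta-method SE `sqrt((1/mu1 + alpha)/n1 + (1/mu2 + alpha)/n2)`, normal
  reference, two-sided. Group means are floored at 0.25 inside the
  statistic so single-group expression yields a large finite z rather than
  infinity; all-zero features are flagged with p = 1. The reported log2FC
  adds a 0.5 pseudo-count for display only.
* **Thresholds**: BH-adjusted p < 0.05 for genes and < 0.1 for eRNAs, the
  conventions this analysis type uses for the two feature kinds.
* `bh_adjust()` is the plain step-up with monotonicity enforcement; the
  rank-m factor is applied as `m/rank` first so the largest adjusted
  p-value equals its raw p-value bit for bit.

The default NB dispersion of the simulator is 0.01 — tight cell-line
biological duplicates (replicate rank correlations above 0.98 in the
emulated assays), a regime where a 2-fold change at mean 100 is
comfortably detectable at 3 vs 3.

# Integration analyses

* **Enhancer-promoter pairing**: all (enhancer, gene) pairs with the
  enhancer midpoint within 500 kb of the strand-aware TSS, among features
  significant in their respective DE tables; the anchor points (midpoint to
  TSS) are a fixed package convention. Concordance (same direction) is a
  flag and, by default, a filter; one enhancer may pair with many genes and
  vice versa, so the pair count exceeds the planted count on a compact
  genome — recovery of planted pairs is the scored quantity.
* **Overlap test**: upper-tail hypergeometric `P(X >= k)`; the universe is
  a required explicit argument (defaulting it invisibly changes p-values by
  orders of magnitude). `P(X >= 0) = 1` by convention.
* **Preranked GSEA**: weighted running sum (hit increments proportional to
  |score|^1, miss decrements `1/(N - n_set)`), ES at maximal |deviation|;
  significance from gene-label permutations (the ranking is precomputed, so
  phenotype permutation is unavailable); NES divides by the mean |ES| of
  same-sign permutations and p is the +1-smoothed same-sign exceedance
  fraction, so the minimal p at 1000 permutations is ~1/(n_same + 1).
  Ties in the ranking are broken by gene name for determinism.
* **Methylation retention**: per-probe group-mean delta (treated minus
  baseline) over a probe set, "retained" when |delta| < 0.05 (the same
  delta-beta convention). The pipeline computes retention on the **5mC
  (oxBS) scale**: BS total methylation is blind to exactly the
  anti-correlated sites where a 5mC gain compensates a 5hmC loss. Both
  treated time points are pooled as the treated group (four samples against
  two), which halves the retention-delta variance. The HLA-like retention
  set is the cluster probes called hypermethylated; the global comparator is
  every called differential 5mC probe.

# Motif analysis

PWM scanning computes log2-odds window scores on both strands
(`(p + pseudocount)/(1 + 4 * pseudocount)` against the background
frequencies; N bases contribute 0, i.e. background); a window is a hit at
`score >= score_fraction * max_score` with `score_fraction = 0.8` by
default and a 1e-9 absolute slack so exact-consensus windows survive
floating-point summation order at `score_fraction = 1`. Enrichment uses
sequence-level presence (the "% of target sequences with motif"
convention), one-sided Fisher against the background set (a seeded
mononucleotide shuffle of the targets when no background is supplied), BH
across motifs. Because the synthetic genome carries no nucleotide sequence,
the pipeline's motif stage generates i.i.d. sequences with a planted
AP-1-like 8-mer at configured fractions; motif analysis of real enhancer
sequences uses the same functions on user FASTA and PWM files.

# The synthetic-data generator

The generator writes truth first and observes it second, so every
downstream estimate can be scored exactly. Defaults are the study
conditions the package emulates:

* four conditions (reference, mutant, two treated time points), biological
  duplicates;
* 3000 hyper- vs 1400 hypomethylated 5mC sites (the published genome-wide
  ~2.15:1 skew scaled to the ~19,000-probe desk genome) and 2156
  5hmC-loss vs 664 5hmC-gain sites (the published counts, used as-is),
  with |delta-beta| 0.2;
* anti-correlated construction: every 5hmC change carries a compensating
  opposite 5mC change at the same probe, the TET-pathway signature;
* differential sites planted into enhancers at 3x the relative rate,
  depleted from promoters and islands, favouring open sea;
* treatment reverses 80% (day 4) and 90% (day 7) of every planted effect —
  except the HLA-like cluster (12 contiguous genes, ~120-150 probes, the
  scale of the published 116-site HLA class I set), which stays
  hypermethylated and repressed: the non-responder pattern;
* observation noise: zero-mean truncated normal, sd 0.03 per beta value;
* transcription: every gene transcribed on its own strand, 200 of 300
  enhancers expressed (50 bidirectional), Poisson per-bin coverage at
  1.5-6 (genes) / 3-6 (eRNA strands) reads/bin plus 0.1 reads/bin
  background, NB counts at dispersion 0.01 with log-uniform means in
  [50, 500]; 20 planted enhancer-promoter pairs within 500 kb.

A single seed expands into named per-stage substreams (order: genome,
methylome, transcription, motifs, gsea), so stages can be regenerated
independently and the whole pipeline is byte-reproducible.

What the generator does **not** model — and what passing tests therefore do
not demonstrate about real data: array heteroscedasticity (beta-value noise
on EPIC arrays shrinks near 0 and 1; the truncated-normal noise is
homoscedastic), probe cross-reactivity and detection failures, batch
structure, CpG-density-driven probe placement, sequence-dependent coverage
biases, spliced or unstable transcripts, spike-in normalization (equal
depth up to size factors is assumed), and clinical covariates.

# Validation scale and numerical conventions

The test and acceptance suites run the full pipeline at the default desk
scale (three 10 Mb chromosomes, ~19,000 probes, 1,000 genes, 300
enhancers, 8 samples) and the DE calibration on 5,000-feature 3 vs 3
simulations, sizes chosen so the complete validation executes in a few
minutes on one core while every planted-set count keeps its published
magnitude. Oracle comparisons use explicit enumeration (`choose()` ratios
for hypergeometric tails, single-pass scans for segmentation, literal
step-up for BH, all-pairs filters for E-P links) at 1e-10/1e-12
tolerances; DESeq2 and fgsea serve as independent cross-checks for size
factors, fold changes and the GSEA statistic. Coordinates are 0-based
half-open on disk (BED/bedGraph/TSV) and 1-based closed in memory
(GRanges); all randomness flows through the seed machinery and restores
the caller's RNG state.

# Known limitations

* Threshold-only delta-beta calling with duplicates has the noise-floor
  false-discovery behaviour quantified above; it is the emulated study's
  design, not a recommendation.
* The eRNA caller is a threshold/gap/length segmenter, not an HMM; its
  parameters are explicit and validated on planted truth, and no claim of
  equivalence with any published enhancer catalog is made.
* The Wald DE test assumes the NB mean-variance relation with a common
  per-feature dispersion across conditions; multi-factor designs, batch
  covariates and independent filtering are out of scope.
* Motif enrichment depends on the supplied PWMs; no de novo discovery.
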