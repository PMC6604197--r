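---
title: "Methods: promoter-resolved BET displacement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-resolved BET displacement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betshift)
```

## The scientific question

BET-family bromodomain proteins (BRD2, BRD3, BRD4) read histone acetylation
at active promoters and enhancers. Their occupancy around a transcription
start site is bimodal: a strong mode at the +1 nucleosome, roughly 150–180 bp
downstream of the TSS where RNA Pol II pauses, and a weaker mode near −300 bp.
Bromodomain inhibitors displace these proteins from chromatin in a
dose-dependent way, but not uniformly: some promoters lose occupancy mostly
downstream (the pause site), some mostly upstream (the core promoter), some
at both, and most not at all. The downstream pool is the transcriptionally
critical one — BRD4 recruits P-TEFb there, releasing paused Pol II into
elongation — so pause-site displacement predicts both an increase in the
Pol II traveling ratio and loss of expression. `betshift` implements the
analysis chain that resolves displacement spatially into the two 1-Kb
windows flanking each TSS, classifies promoters into four sensitivity
categories, and connects those categories to pausing and expression.

All coordinates are 0-based half-open (BED convention). Windows are
strand-oriented: "upstream" always means 5′ of the transcription direction.
For a plus-strand TSS at t, the core promoter is [t−1000, t) and the pause
site [t, t+1000); minus-strand windows mirror these. Overlap anywhere in the
package means ≥ 1 shared base.

## Differential binding model

Fragments are counted into every window they overlap (a 300-bp fragment
spanning the TSS legitimately counts in both windows). Size factors are
median-of-ratios: the median across rows with an all-positive geometric mean
of count/geomean, rescaled to geometric mean 1. This estimator assumes most
windows are unchanged between conditions — which holds in the emulated world,
where ~11% of TSSs are affected (see below); a world where half the windows
lose signal would bias the factors and attenuate every fold change.

Each dose is tested against vehicle independently, per window, with a
negative-binomial Wald test. The dispersion is a per-row moment estimate from
the pooled within-group variance of normalized counts, shrunk 50% toward a
trend `a + b/mean` fitted across rows. With two replicates per group the
moment estimate has only 2 residual degrees of freedom, and a plain normal
(z) reference is anti-conservative (empirical type-I error ≈ 0.072 at
α = 0.05). Because only half the dispersion weight is row-specific, we use a
Wald *t* with a Satterthwaite-style effective df of
`residual_df / (1 − shrink)²` — 8 for the 2 vs 2 design — which restores
calibration (≈ 0.035 empirically) without hurting power against the 4-fold
displacements the test is sized for. Rows below a total normalized count of
10 are reported untested rather than given unstable estimates. Multiple
testing is Benjamini–Hochberg within each contrast. A TSS is "affected" at a
window if any dose has adjusted p < 0.05 with LFC < 0; displacement is a
loss, so significance is directional by default (a `two_sided_affected` flag
removes the sign condition).

## Sensitivity clustering and naming

Affected TSSs are described by six LFCs — (50, 500, 5000 nM) × (core,
pause) — and clustered with k-means, k = 4, best of 25 restarts, on the raw
unscaled matrix: the signature lives in signed magnitudes, and row scaling
would erase the distinction between moderate and strong displacement. A Ward
hierarchical alternative (cut at 4) is provided behind `method = "ward"`
because the two conventions coexist in practice for this kind of heatmap;
k-means is the default. Cluster names are assigned from the strongest-dose
centroid coordinates (mean core LFC c̄, mean pause LFC p̄): the cluster
maximizing c̄ − p̄ is *highly-sensitive-pause*, then the remaining cluster
maximizing p̄ − c̄ is *highly-sensitive-core*, and of the last two the lower
c̄ + p̄ is *highly-sensitive-both*, the other *sensitive-both*. The rule is
deterministic given centroids, breaks ties by cluster index, and is invariant
to cluster re-indexing. Untested LFC entries are imputed as 0 and counted in
an `n_imputed` attribute rather than dropped, keeping the matrix complete.

## Traveling ratio

TR = (mean per-base coverage over [TSS−100, TSS+300], 401 bp inclusive,
mapped to the half-open [t−100, t+301)) divided by (mean coverage from 301 bp
past the TSS to the TES). Genes with zero body coverage or bodies shorter
than 200 bp past the promoter region are excluded and flagged, never assigned
infinite TR. "Gained in TR" defaults to fold change > 2 (TR_treated /
TR_vehicle), with `gain_mode = "absolute"` switching to post-treatment
TR > 2 — the phrase is ambiguous in common usage and the word "gain" argues
for the fold reading. Cluster-level gain fractions are compared with a
two-sample proportion test (chi-square with Yates correction, matching R's
`prop.test`; an uncorrected z-test sits behind `correct = FALSE`).

## Expression integration

Differential expression reuses the NB Wald machinery with the dual
significance rule (FDR < 0.05 and |LFC| > 1). Cluster-wise cross-model
comparisons pair each gene's LFC in the two models and use a Wilcoxon
signed-rank test with Pratt handling of zero differences (zeros are ranked,
then discarded from the statistic) under a normal approximation with tie
correction; all-zero pairings are flagged untested. Pre-ranked GSEA ranks
genes by LFC (ties broken by gene id for determinism), scores each set with
the weighted running sum (hit increments |metric|^weight normalized to the
set total, default weight 1; miss decrements 1/(N−n)), and normalizes against
a gene-label permutation null: NES = ES / mean(|ES*|) over sign-matched
permutations, permutation p from the same pool, and FDR q from the pooled
normalized permutation scores. Significance is |NES| > 1 at q < 0.10.

## qPCR and dose-response models

Relative abundance is X = (1+Eff_R)^CtR / (1+Eff_X)^CtX with efficiencies as
fractions in (0, 1] — the "(1+Eff)" form fixes the scale convention, and
Eff = 1 recovers the classic 2^(CtR−CtX). Displayed values divide by the
DMSO-group mean; paired t-tests annotate `**` below p = 0.005 and `*` below
0.05. Reference-gene candidates are screened from DE results exactly as a
bench scientist would: non-significant at every dose up to 500 nM in both
models, expressed above the 0.8 quantile in both, ranked by largest absolute
LFC. The proliferation response area is the trapezoidal integral of
1 − viability over log₁₀ concentration divided by the log-range, so 0 means
fully viable everywhere and 1 fully killed everywhere; the exact quadrature
of the original AUC tooling is not reproduced, and the substitute is
validated by its limit cases and grid-refinement invariance.

## The synthetic world

The generator emulates the study design the pipeline is meant for: one
sensitive and one resistant cell model, doses 0/50/500/5000 nM, two
replicates, ~2×10⁵ fragments per sample on a 2 × 5 Mb genome with 2000 TSSs.
Displacement follows a Hill law r(d) = 1/(1+(d/EC₅₀)^h) per window, scaled by
a class-specific maximal depth: *unaffected* (depth 0), *sensitive-both*
(depth 0.75, EC₅₀ 500 nM), *highly-sensitive-both* (0.95, 100 nM),
*highly-sensitive-pause* (0.95 at the pause window only), and
*highly-sensitive-core* (0.95 at the core window only). Class proportions
follow the affected-TSS structure of the sensitive model in the motivating
design: 11% affected, split 36/13/21/30% across the four categories. The
resistant model raises EC₅₀ 50-fold and lowers the downstream/upstream
amplitude ratio from 2.0 to 1.2, emulating globally weaker binding and fewer
affected TSSs. Counts are Gamma-Poisson: dispersion 0.02 for ChIP window
counts between replicates and 0.05 for expression counts — ChIP replicates
of this quality are less dispersed than RNA-seq libraries, and with 0.05
everywhere the Wald SE floor (√disp/ln 2 ≈ 0.33) would make the
core-promoter-only category undetectable at its ~1.2 LFC.

Fragment centers are Gaussian around the two modes (−300 and +165 bp,
sd 25 bp). Two geometric facts constrained these defaults and are worth
recording. First, 300-bp fragments centered 165 bp downstream of the TSS
overlap the core window whenever their center falls below +150, so a wide
mode (sd ≥ 40) sends 35–40% of pause-mode counts across the TSS, halving the
apparent core-only displacement; sd 25 (a well-phased +1 nucleosome) keeps
this bleed near 25%, and the remaining cross-talk is real and intended — a
fragment spanning the TSS belongs in both windows. Second, with 50-bp bins
and anchor phases uniform within bins, the metaprofile's reported mode is
effectively floor((offset+25)/50)·50, so a true mode at +180 reports at
+200; +165 reports at +150, inside the expected 150–180 band.

Pol II coverage is generated noiseless at base resolution: promoter density
1 + c·(1 − r_pause) and body density max(r_pause, 0.1) with coupling c = 1,
so the true TR fold change is (1 + c·(1−r_pause))/max(r_pause, 0.1) in
closed form and the TR estimator can be tested for exact equality.
Expression means are loguniform on [50, 2000] with true
LFC = −β·(1 − r_pause), β = 2: expression loss is driven by pause-site
displacement only, which is the hypothesis the pipeline is designed to
detect.

What a green test establishes — and what it does not: the generator has
no mappability or GC structure, no enhancer looping, no fragment-length
variation, non-overlapping gene bodies, and its displacement kinetics are an
assumed Hill form; recovery results (adjusted Rand index > 0.8 against
ground-truth classes, ≥ 80% correct labeling of the pause-only category)
validate the pipeline's statistics and bookkeeping on a world shaped like
the motivating design, not any cell-line-specific biology, which would
require the original sequencing data.

## Numerical and degenerate-input choices

- Peak calling uses raw p ≤ 10⁻³ per bin (no q-value step): confidence comes
  from the three-way pseudo-replicate consensus, and the broad-merge gap is
  500 bp. An empty control falls back to the treatment's genome-wide rate
  with a warning.
- RPGC scaling is effective-genome-size / (fragments × extension); bin
  values are mean per-base depth within the bin, so the normalized
  genome-wide mean is exactly 1. Negative values after input subtraction are
  preserved; counting always works from fragments, never subtracted tracks.
- Metaprofile anchors use floor(pos/bin) indexing; minus-strand anchors use
  floor((pos−1)/bin) so oriented offsets align to the same grid from both
  strands. Mode detection smooths with a 3-bin moving average (a choice made
  for mode detection only); monotone or constant profiles are flagged
  unimodal.
- k-means is seeded and takes the best of 25 restarts; clustering is skipped
  (with a message) when fewer than 8 affected TSSs or fewer than 4 distinct
  signatures exist.
- All randomness derives from one global seed expanded into fixed per-stage
  offsets, so stages are independently reproducible and every derived seed
  stays below 2³¹.

## Known limitations

Pairwise dose-versus-vehicle contrasts only (no joint dose-response GLM); no
LFC shrinkage or outlier (Cook's-distance-style) handling; the peak caller is
a transparent Poisson scan, not a port of production callers, and absolute
peak counts are not comparable to theirs; GSEA FDR uses the pooled-permutation
approximation, which is coarse below ~1000 permutations; bigWig output is not
supported (bedGraph only).
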