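# betshift

Spatially resolved analysis of dose-dependent displacement of chromatin-bound
BET proteins (BRD2/3/4) around transcription start sites, for epigenomics
groups studying bromodomain-inhibitor (I-BET/JQ1-class) sensitivity in ChIP-seq
dose-response designs.

BET bromodomain readers occupy active promoters in a bimodal pattern: a strong
mode ~150–180 bp downstream of the TSS (the RNA Pol II pause site) and a weaker
mode ~300 bp upstream (the core promoter). Bromodomain inhibitors displace
these proteins dose-dependently, and *where* around the TSS the displacement
happens — upstream, downstream, or both — predicts whether a gene's
transcription collapses. `betshift` implements the full analysis chain for
this question:

- **Consensus peak calling** — Poisson broad-domain bin scan
  (p ≤ 10⁻³ against a local λ = max(genome-wide, 10 Kb window) control rate)
  on the merged replicates and on a random equal split into two
  pseudo-replicates; a peak is kept iff it overlaps a peak in all three runs,
  then ENCODE-blacklist filtered.
- **Coverage** — fragment extension (300 bp) and 50-bp binning, RPGC (1×)
  normalization so mean genome coverage = 1, input subtraction, and
  strand-oriented TSS ±4 Kb metaprofiles with bimodal mode detection.
- **Differential binding** — fragment counts in the core-promoter
  (TSS −1 Kb) and pause-site (TSS +1 Kb) windows; median-of-ratios size
  factors; per-window negative-binomial Wald test of each dose against
  vehicle (moment dispersion shrunk 50% toward a fitted mean–dispersion
  trend), Benjamini–Hochberg corrected.
- **Sensitivity clustering** — the 6-column log₂ fold-change signature
  (3 doses × 2 windows) per affected TSS, k-means with k = 4 (Ward
  hierarchical alternative available), and canonical naming of the clusters:
  *sensitive-both*, *highly-sensitive-both*, *highly-sensitive-pause*,
  *highly-sensitive-core*.
- **Pol II pausing** — traveling ratio TR = mean coverage over
  [TSS−100, TSS+300] divided by mean coverage over [TSS+301, TES]; TR-gain
  calls (fold > 2) and a two-sample proportion test between clusters.
- **Expression integration** — NB differential expression (FDR < 0.05 and
  |LFC| > 1), overlap of differentially bound and downregulated genes,
  cluster-wise paired Wilcoxon signed-rank comparisons, and pre-ranked GSEA
  (weighted running-sum ES, gene-label permutation NES/FDR).
- **Assay models** — efficiency-corrected qPCR quantification
  X = (1+Eff_R)^CtR / (1+Eff_X)^CtX with DMSO-mean normalization and paired
  t-tests; dose-response area = normalized ∫(1 − viability) d log₁₀(conc).
- **Synthetic data** — a generator with known ground truth emulating the
  two-cell-model (sensitive/resistant), four-dose (0/50/500/5000 nM),
  two-replicate design: bimodal TSS occupancy displaced under a Hill law
  per sensitivity class, Pol II coverage coupled to pause-site displacement,
  NB expression counts, qPCR Ct tables.

## Worked example

```r
library(betshift)
run <- run_pipeline(sim_config(seed = 1))
```

```
[simulate] 2000 TSSs, 9 samples, model=sensitive
[coverage] modes: upstream -300 bp, downstream 150 bp, ratio 2.23
[peaks] 1970 consensus peaks (vehicle)
[diffbind] 160/2000 TSSs affected (8.0%)
[cluster] sizes: highly-sensitive-both=29, highly-sensitive-core=19,
          highly-sensitive-pause=37, sensitive-both=75
[pausing] 155/2000 genes gained in TR at 500 nM
[expression] 65 DE genes at top dose; DB/DE overlap 63/65 (96.9%)
```

Reading the output: the vehicle metaprofile is bimodal with the downstream
mode at +150 bp about 2.2× the upstream mode — the expected promoter
signature. 8% of TSSs show significant BRD4-like displacement at one or both
windows; their 6-column LFC signatures split into the four canonical
sensitivity categories. Genes losing pause-site occupancy gain in traveling
ratio (Pol II accumulates at the promoter relative to the body) and dominate
the downregulated, differentially bound set (63 of 65 downregulated genes are
also differentially bound). Comparing the clustering with the generator's
ground-truth classes:

```r
truth <- run$sim$truth$classes
idx <- match(run$clusters$transcript_id, truth$transcript_id)
adjusted_rand_index(truth$class[idx], run$clusters$label)
#> [1] 1
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the default
synthetic world — simulation, coverage and metaprofile modes, consensus
peaks, per-dose differential binding, four-way sensitivity clustering against
ground truth, traveling-ratio shifts, and expression integration — and writes
the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

`R/` implementation; `tests/testthat/` unit, property and acceptance suites
(fixtures are generated in code); `vignettes/betshift-methods.Rmd` the
methods vignette describing the model, the generator's stated world, and the
numerical design choices.
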