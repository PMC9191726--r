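# sehet — super-enhancer-mediated transcriptional heterogeneity

`sehet` is an R package plus analysis workflow for the quantitative
questions that arise when NF-kB activates B cells through
super-enhancers (SEs): how cooperatively do nuclear NF-kB foci form
across a stimulus titration, which genes respond as a discrete
activated cell state, how much cell-to-cell heterogeneity does each
gene gain with dose, which stitched enhancer regions are super versus
typical and which gain or lose accessibility upon stimulation, how
motif density differs between those groups, and whether gained
cis-regulatory contacts (co-accessibility) track expression amplitude
and heterogeneity. It is written for computational biologists who want
each of those steps as a tested, seedable function rather than a
one-off script.

Because the original sequencing data are not deposited, the package
ships a first-class synthetic-data module that generates every input
with planted ground truth — activation states, gene classes, enhancer
architectures, gained peak pairs, Hill parameters — so every stage is
testable end-to-end.

## The models at the core

* **Hill dose-response**: `y(d) = a + k·dᴺ / (Kmᴺ + dᴺ)`, fitted by
  deterministic multi-start least squares; `N` is the Hill coefficient
  (cooperativity), `Km` the half-maximal dose (ug/mL), `k` the
  amplitude, `a` the basal term (removed for gene fold-change fits).
  Fits are categorised high (`5 ≤ N`), medium (`1 < N < 5`), low
  (`N ≤ 1`), with `N > 9` / `N < 0.3` excluded.
* **Fano factor**: `F = σ²/μ` per gene per dose group (1 under Poisson
  noise); the heterogeneity index, with its 10-vs-0 ug/mL ratio and
  Ward (`ward.D2`) clustering of per-gene dynamics.
* **ROSE-style SE calling**: peaks stitched within 5 kb, regions ranked
  by total normalized signal, the SE/TE cutoff at the slope-1 tangent
  of the min-max-rescaled rank curve; gained/lost/unchanged assigned by
  class-wise quartiles of accessibility log2 fold-change.
* **PWM motif scanning**: log-odds scores with exact DP-derived
  thresholds (p ≤ 1e-4 under background), both strands, densities per
  10⁴ bp, compared across groups with undersampled ANOVA/Welch tests.
* **Co-accessibility**: per condition, a distance-penalized graphical
  lasso (`rho ∝ (distance/s)^0.75`) over 500 kb windows of k-NN
  meta-cell profiles; partial-correlation scores, with pairs gained
  when stimulated score ≥ 0.1 and the difference to unstimulated
  ≥ 0.05; per-gene counts of gained partners within ±1 kb of the TSS
  correlated (Spearman) with expression statistics.

The methods vignette (`vignettes/nfkb-se-heterogeneity.Rmd`) documents
the assumptions, defaults, numerical choices and limitations.

## Worked example

```r
library(sehet)

cfg <- sim_config(seed = 1)

# 1. cooperativity of nuclear foci formation
med <- median_response(simulate_foci(cfg)$table, time = 20)
fit <- fit_hill(med$dose, med$median_foci, with_basal = TRUE)
print(fit)

# 2. expression: QC, two-state classification, heterogeneity
e <- simulate_expression(cfg)
sce <- normalize_depth(qc_filter(e$sce, min_total = 100, min_genes = 20, max_mito = 0.5))
states <- classify_cells(sce)
prof <- fano_profiles(sce, genes = names(e$truth$gene_class))
fr <- fano_ratio(prof)                      # Fano(10 ug/mL) / Fano(0)
cls <- e$truth$gene_class
cat(sprintf("activated cells: %d/%d\n", sum(states == "activated"), ncol(sce)))
cat(sprintf("median Fano ratio: SE-like %.1f, TE-like %.1f\n",
            median(fr[names(cls)[cls == "se_like"]], na.rm = TRUE),
            median(fr[names(cls)[cls == "te_like"]], na.rm = TRUE)))

# 3. differential co-accessibility against the planted truth
atac <- simulate_atac(cfg)
agg <- lapply(atac$counts, function(m) aggregate_cells(m, k = 10))
pairs <- differential_pairs(coaccess_scores(agg$stim$counts, atac$peaks),
                            coaccess_scores(agg$unstim$counts, atac$peaks))
counts <- gene_pair_counts(pairs, atac$peaks, atac$tss)
cat(sprintf("gained pairs: %d; Spearman(gained partners, Fano ratio) = %.2f\n",
            sum(pairs$gained), correlate_counts(counts, fr)))
```

This prints:

```
Hill fit: N = 4.253, Km = 0.1014, k = 12.04, a = 0.9205 (rss 0.2613, 14 points)
activated cells: 228/450
median Fano ratio: SE-like 16.3, TE-like 1.6
gained pairs: 113; Spearman(gained partners, Fano ratio) = 0.58
```

Reading: the median foci titration recovers the planted cooperativity
(`N = 4`, `Km = 0.1` ug/mL) with a basal level near 1 focus; half the
cells across the five doses classify as activated (the design puts the
half-maximal dose in the middle of the titration); SE-like genes gain
an order of magnitude more heterogeneity with dose than TE-like genes;
and genes with more gained promoter contacts have systematically larger
Fano-ratio gains, the central observation the pipeline exists to
quantify.

## The analysis workflow

The numbered scripts under `analysis/` run the full study over one
seeded simulation and write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | generate all inputs (MTX, BED, CSV, truth JSON) |
| `02_foci_dose_response.R` | foci medians, Hill fit, activation fractions |
| `03_expression.R` | QC, normalization, cell states, DEGs, fold-changes |
| `04_heterogeneity.R` | Fano profiles/ratios, dynamics clusters, SE-vs-TE test |
| `05_enhancers.R` | stitching, SE/TE calling, merging, gain/loss, gene assignment |
| `06_hill_expression.R` | basal-free gene Hill fits and categories |
| `07_motifs.R` | motif density over called enhancers, promoter TATA |
| `08_coaccessibility.R` | meta-cells, graphical-lasso scores, gained pairs, correlations |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

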