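# neutroflux

Analysis pipeline for two-colour, common-reference microarray studies of
LPS-induced acute lung inflammation in mice, built to ask one question:
*how much of the inflamed lung's transcriptional and genotoxic response
is driven by infiltrating neutrophils?* The design it targets contrasts
three groups of five animals — saline controls (`SHAM`), LPS-instilled
mice (`LPS_PMN`) and LPS-instilled, neutrophil-depleted mice
(`LPS_NOPMN`) — each hybridised (Cy5) against one pooled-sham Cy3
reference.

Because no raw data are publicly deposited for this design, the package
includes a first-class synthetic-data generator that emulates the study
(pooled reference, inter-animal acute-phase heterogeneity, MPO and M1dG
phenotypes coupled to response magnitude), so the whole pipeline is
testable end to end.

## What it computes

* **Four-step normalization** from raw spot intensities to a genes x
  samples natural-log matrix: ln transform, quantile normalization of
  all scans (with an invariant-spot-anchored map as pipeline default so
  strong fold changes are not compressed; classic quantile normalization
  is one flag away), common-reference correction
  `s - (r - mean_arrays(r))`, and gene-symbol averaging. PCA quality
  control flags the most heterogeneous group.
* **Median fold-change differential expression** for the contrasts
  A = LPS_PMN vs SHAM, B = LPS_NOPMN vs SHAM, C = LPS_PMN vs LPS_NOPMN:
  per-gene group medians, fold change `exp(|median difference|)` with
  direction, strict `> 1.5` threshold by default, seven-region Venn
  partition, overlap percentages, extreme genes, and the
  cross-contrast regression whose slope measures attenuation of the
  depleted response.
* **Gene-set over-representation** against any GMT collection:
  one-sided hypergeometric (Fisher) or the conservative EASE variant
  (tail at k-1), array-content universe, Benjamini-Hochberg q-values.
* **Expression-response score**: per sample, the root mean square of
  DE-gene deviations from the sham medians, correlated with phenotype
  markers (M1dG adducts, BALF MPO activity) by Spearman (exact
  permutation p at small n) or Pearson.

## Worked example

```r
library(neutroflux)
run <- tempfile()
run_pipeline(list(out_dir = run, seed = 42, n_genes = 800))
cat(summarize_run(run), sep = "\n")
```

Output (abridged):

```
## Differentially expressed genes

- contrast A: 252 genes (211 up, 41 down)
- contrast B: 187 genes (152 up, 35 down)
- contrast C: 192 genes (161 up, 31 down)

## Venn partition
...
- union: 285

- 87% of contrast-B DE genes overlap contrast A
- 95% of contrast-C DE genes fall inside the A/B union

## Top enriched sets

- acute_phase_response_up: k/K = 151/156, p = 5.62e-75, q = 5.06e-74
- neutrophil_dependent_up: k/K = 60/65, p = 2.12e-23, q = 9.55e-23
...

## Correlations

- response score vs m1dg (spearman): 0.896, p = 6.07e-06, n = 15
```

Reading this: the simulated world injects 285 affected genes; the
intact-neutrophil contrast recovers more of them (252) than the depleted
one (187), the depleted DE list sits almost entirely inside the intact
one (87 %), block-aligned gene sets dominate enrichment while decoy sets
do not, and each animal's response score tracks its M1dG adduct burden
because both are driven by the same per-animal acute-phase factor.

On a *noise-free* simulation the pipeline recovers every injected effect
exactly: Saa3 comes back at 15.0-fold (contrast A) and 7.7-fold
(contrast B), and the extreme down-regulated genes are Pon1 (2.6-fold)
and Krt1-15 (2.7-fold) — these are the deterministic acceptance checks.

A command-line front end with subcommands
`simulate / normalize / de / enrich / score / report / all` ships in
`inst/cli/neutroflux` (see `neutroflux_main()`).

## Package layout

* `R/io.R` — readers/writers with strict validation (spot tables,
  design, GMT, phenotypes, matrices)
* `R/simulate.R` — the synthetic world and its defaults
* `R/normalize.R` — four-step normalization + PCA QC
* `R/de.R` — medians, contrasts, DE calls, Venn, regression
* `R/enrich.R` — hypergeometric/EASE enrichment, BH adjustment
* `R/score.R` — response scores and correlations
* `R/pipeline.R`, `R/cli.R` — orchestration, manifests, CLI
* `vignettes/methods.Rmd` — models, parameter choices and limitations
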