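---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`neutroflux` implements the analysis chain of a two-colour,
common-reference microarray study of LPS-induced acute lung inflammation
in mice, contrasting animals with an intact neutrophil compartment
(`LPS_PMN`), antibody-depleted animals (`LPS_NOPMN`) and saline-instilled
controls (`SHAM`), five animals per group. Because no raw data are
publicly deposited, the package ships a first-class synthetic-data
generator that emulates the study design; every downstream module is
exercised and validated against that generator plus small worked
fixtures.

# The normalization model

Raw per-spot fluorescence (sample channel Cy5, pooled-sham reference
channel Cy3) is processed in four steps:

1. **Natural-log transform.** Signals are strictly positive by
   construction: values at or below zero (possible after upstream local
   background subtraction) are floored to 1 AU at read time, with a
   logged count. The floor keeps the log total without inventing a
   background model the source data do not describe.
2. **Quantile normalization of all scans.** All `2 * n_arrays` channels
   are pooled by default (`pool = "all"`), because the two dyes of a
   slide come from separate scanner passes and it is scans, not arrays,
   that share an intensity scale. Per-role pooling (`pool = "by-role"`)
   remains available for sensitivity analysis.
3. **Common-reference correction.** For spot $g$ on array $a$ with
   sample log-signal $s_{ga}$ and reference log-signal $r_{ga}$:
   $\tilde s_{ga} = s_{ga} - (r_{ga} - \bar r_{g\cdot})$. Subtracting
   the array's *deviation* from the across-array reference mean corrects
   between-array differences while preserving the intensity scale (and
   is mean-preserving per spot); the plain log-ratio $s - r$ is kept
   behind `reference_mode = "ratio"`. The verbal description this step
   formalizes does not print a formula; the deviation form is our
   documented interpretation.
4. **Gene collapse.** Spots sharing a gene symbol are averaged
   (arithmetic mean of log values per sample); unannotated spots are
   dropped with a logged count. Symbols are compared case-sensitively.

## Why the pipeline's quantile map is anchored on invariant spots

Classic quantile normalization forces every channel onto one common
value multiset. That is exactly right when channels differ only by
technical distortion, but when a non-negligible fraction of spots is
genuinely differential, the forced common distribution *compresses the
differential signal itself*: on noise-free simulated data with the
default effect blocks (~14 % of genes), the injected 15-fold change is
recovered as ~14.1-fold. No transform that equalizes value multisets can
recover an arbitrary injected effect exactly — achievable differences
are limited to gaps of the common sorted vector.

`quantile_normalize(anchor = "invariant")`, the pipeline default,
therefore estimates the map only on spots that behave consistently
across channels, in the spirit of rank-invariant-set normalization: a
one-step median polish yields per-spot consensus levels and per-channel
offsets; spots whose residuals stay within 3 robust SDs in every channel
are anchors; each channel is mapped onto the cross-channel mean level of
the anchors by monotone piecewise-linear quantile matching with slope-1
tails. Two properties follow:

* when channels differ by additive constants (the distortion the step
  exists to remove), the map removes them *exactly*;
* differential spots ride along the interpolated map and keep their
  offsets, so injected fold changes survive the pipeline unchanged
  (this is what the deterministic recovery tests assert at 1e-6).

With fewer than `max(3, 1 %)` usable anchors the function warns and
falls back to the classic map. `anchor = "all"` is the default for the
bare-matrix interface and retains textbook behaviour, including the tie
convention (tied values receive the mean of the reference values over
the ranks they span) and the identical-sorted-columns post-condition,
both of which are property-tested.

## PCA quality control

Covariance PCA on gene-centered values (no per-gene scaling: all values
already share the log-AU scale). The report carries per-sample scores on
the first two components and flags the group with the largest mean
within-group distance to its centroid; on simulated data with default
heterogeneity the flagged group is an LPS group, not SHAM, in at least
90 % of seeds.

# Differential expression

With five animals per group and visible within-group heterogeneity,
the pipeline follows a median fold-change design rather than a
variance-model test: per-gene group medians (mean-of-central-values for
even n), log-ratio contrasts A = LPS_PMN − SHAM, B = LPS_NOPMN − SHAM,
C = LPS_PMN − LPS_NOPMN, fold change $e^{|\Delta|}$ with a direction,
and a threshold call. The threshold comparison is **strict** (`> 1.5`)
by default — the methods wording ("more than 1.5-fold") wins over the
results header ("≥ 1.5-fold"); `strict = FALSE` exposes the other
reading. Moderated t / empirical-Bayes machinery is deliberately out of
scope. DE sets from the three contrasts are partitioned into the seven
Venn regions; overlap percentages use half-up integer rounding.

# Enrichment

Generic over-representation against any GMT collection: one-sided
hypergeometric tail $P(X \ge k)$ with the universe fixed to the genes on
the collapsed matrix (array content defines what could be detected, so
the genome is the wrong background). `method = "ease"` applies the
conservative EASE variant (tail at $k-1$), which is never
anti-conservative relative to Fisher — property-tested. Multiplicity is
handled by a hand-implemented Benjamini–Hochberg step-up (validated
against `stats::p.adjust`); raw p is always reported alongside q.
Default `min_set = 3` expressed members. The original study's
proprietary pathway databases are not bundled and their printed
p-values are not reproduction targets.

# Response score and phenotype correlation

The per-sample response statistic over a gene list $G$ is the root mean
square of deviations from the sham medians,
$\mathrm{score}_s = \sqrt{\tfrac1{|G|}\sum_{g\in G}(x_{gs} -
\mathrm{med}_{\mathrm{SHAM}}(x_{g\cdot}))^2}$, on natural-log
expression. $G$ defaults to the union DE list; the source description
("the 1.5-fold changed gene lists") is ambiguous between the union and a
single contrast, so `score_genes` can select either. Correlations:
Spearman with average ranks (exact permutation p for n ≤ 9 without
ties, t approximation otherwise) and Pearson with the two-sided t test.
Below-detection MPO activity enters as 0 by default (half-minimum
substitution behind a flag) so all animals can be correlated.

# The synthetic world

All defaults are the study's stated conditions; none are tuned to test
outcomes.

* **Design:** 3 groups × 5 mice; 2000 genes × 2 spots; 1 % control
  spots; baselines $b_g \sim N(7, 1)$ log-AU.
* **Heterogeneity:** one multiplicative response factor $\alpha_a$ per
  animal scales the log effect — a per-mouse acute-phase intensity that
  simultaneously drives expression, MPO and M1dG, producing the
  score–phenotype correlations by mechanism rather than by fiat.
  $\alpha_a$ is **unit-mean** log-normal (sd 0.3,
  $\mu = -\sigma^2/2$); the unit mean is chosen so the phenotype group
  means equal their configured values in expectation (a mean-1.046
  factor would silently inflate the LPS_PMN M1dG mean to 14.0).
  $\alpha \equiv 1$ for SHAM.
* **Channels:** sample spot $= \exp(b_g + \alpha_a e_{gG} +
  \text{shift}_a + \varepsilon)$, spot noise sd 0.10, per-channel array
  shifts sd 0.20; the reference shares $b_g$ on every array (one
  physical pooled-sham Cy3) with sd 0.05 noise.
* **Effects:** named genes pin the printed extremes (Saa3 +ln 15 /
  +ln 7.7; Pon1 −ln 2.6; Krt1-15 −ln 2.7; Retnlg ln 2 between the LPS
  groups only). Blocks approximate the published Venn shape: 150 up /
  40 down shared (depleted response attenuated to 0.6 — the slope the
  cross-contrast regression recovers), 60 up PMN-only, 20 up
  depleted-only, 11 further status-only genes; block magnitudes span
  1.6–3-fold, consistent with most published changes falling between
  1.5- and 2-fold. The true region composition is unknowable from the
  printed figures; these defaults are approximate by design and the
  published region counts are **not** forced.
* **Phenotypes:** printed group parameters treated as mean ± SD (the
  source never distinguishes SD from SEM): BALF MPO 81.4 ± 20.5 mU/ml
  in LPS_PMN, below detection elsewhere; M1dG 5.1 ± 0.2 / 13.6 ± 2.8 /
  10.6 ± 2.5 per 10^8 nt with coupling 1.0 to $\alpha$; lung MPO
  protein 58.18 ± 77.26 (SHAM and depleted, i.e. background) and
  145.99 ± 94.82 (LPS_PMN) ng/mg. Normals truncated at zero. The prose
  "~4-fold" M1dG multiplier conflicts with the printed means ratio
  (2.7); the printed means are used.

What the generator does *not* emulate: scanner saturation, spatial
artifacts, dye-swap designs, print-tip effects, annotation errors.
A green simulation test therefore establishes algorithmic correctness
and statistical behaviour under the stated world, not robustness to
those real-data pathologies.

# Numerical choices

* Quantile-map ties: mean of spanned reference values; anchored variant
  collapses tied anchor values to their mean target.
* Anchor threshold 3 × MAD (center 0) of polish residuals, minimum
  `max(3, 1 %)` anchors, chosen a priori from the noise scale.
* Strict DE boundary: fold change exactly equal to the threshold is not
  called (default).
* Half-up rounding for overlap percentages.
* Extreme-gene ties break lexicographically.
* Exact Spearman p by full permutation enumeration for n ≤ 9, tie-free;
  the permutation distribution of rho is symmetric, so the two-sided p
  is the doubled tail including the atom.
* Seeds: every stochastic entry point takes or derives an explicit
  integer seed; equal seeds give byte-identical artifacts (manifest
  checksums are asserted in tests).

# Known limitations

* The acceptance-grade recovery results hold for the invariant-anchored
  pipeline default; classic pooled quantile normalization attenuates
  extreme fold changes by a few percent on these designs (measured, not
  hypothetical) and is retained for comparison rather than inference.
* With DE fractions approaching half the spots the one-step median
  polish loses its null majority and anchoring degrades; the simulator
  floor of 300 genes permits such pathological worlds (281 effect
  genes), so science-grade simulations should stay at ≥ 800 genes.
* The published real-data gene counts (514/360/107/621) depend on real
  noise and are not simulation targets; only printed arithmetic and
  printed effect sizes are.
* Exact Spearman enumeration at n = 9 allocates a 362880 × 9
  permutation table; larger n switches to the t approximation
  automatically.
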