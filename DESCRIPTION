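Package: neutroflux
Title: Neutrophil-Driven Lung Inflammation Microarray Analysis Pipeline
Version: 0.1.0
Authors@R: person("Maintainer", "Neutroflux", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable analysis pipeline for a two-colour common-reference
    microarray study of LPS-induced acute lung inflammation in mice with and
    without circulating neutrophils. Implements the four-step normalization
    (natural-log transform, quantile normalization of all scans,
    common-reference correction, gene-symbol averaging), median fold-change
    differential expression across three group contrasts with Venn
    partitioning, generic hypergeometric gene-set over-representation
    (Fisher or EASE variant) against GMT collections, a per-sample
    root-mean-square expression-response score correlated with genotoxicity
    and neutrophil phenotype markers, and a synthetic-data generator
    emulating the study design (pooled-sham Cy3 reference, inter-animal
    acute-phase heterogeneity, MPO and M1dG phenotypes) so that the whole
    pipeline is testable without raw data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
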