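#' Default effect table for the simulated experiment
#'
#' Natural-log expression effects per gene for the two LPS contrasts
#' (columns \code{lps_pmn}, \code{lps_nopmn}; both relative to SHAM).
#' Named genes pin the printed extremes: Saa3 (+ln 15 with neutrophils,
#' +ln 7.7 without), Pon1 (-ln 2.6 with neutrophils), Krt1-15 (-ln 2.7
#' without neutrophils) and Retnlg (the neutrophil-status marker, ln 2
#' between the two LPS groups but below threshold against SHAM). Around
#' them sit deterministic blocks shaping the three-way Venn: 150 genes up
#' and 40 down in both LPS groups (depleted response attenuated to 0.6 of
#' the intact one, the attenuation the cross-contrast regression should
#' recover), 60 up only with neutrophils, 20 up only without, and 11
#' further genes moving oppositely in the two LPS groups. All remaining
#' genes are null.
#'
#' @param n_genes total number of simulated genes (>= 300).
#' @return data.frame with columns gene_symbol, lps_pmn, lps_nopmn.
#' @export
default_effect_table <- function(n_genes = 2000L) {
  stopifnot(n_genes >= 300L)
  symbols <- simulated_gene_symbols(n_genes)
  eA <- eB <- stats::setNames(numeric(n_genes), symbols)
  eA["Saa3"] <- log(15);      eB["Saa3"] <- log(7.7)
  eA["Pon1"] <- -log(2.6)     # B effect 0: Krt1-15 stays the depleted extreme
  eB["Krt1-15"] <- -log(2.7)
  eA["Retnlg"] <- log(2) / 2; eB["Retnlg"] <- -log(2) / 2
  blocks <- seq_len(n_genes)[-(1:4)]
  shared_up <- symbols[blocks[1:150]]
  eA[shared_up] <- seq(log(2.0), log(3.0), length.out = 150)
  eB[shared_up] <- 0.6 * eA[shared_up]
  shared_down <- symbols[blocks[151:190]]
  eA[shared_down] <- -seq(log(2.0), log(2.4), length.out = 40)
  eB[shared_down] <- 0.6 * eA[shared_down]
  pmn_only <- symbols[blocks[191:250]]
  eA[pmn_only] <- seq(log(1.7), log(2.5), length.out = 60)
  nopmn_only <- symbols[blocks[251:270]]
  eB[nopmn_only] <- seq(log(1.7), log(2.5), length.out = 20)
  status_only <- symbols[blocks[271:281]]
  d <- seq(log(1.6), log(1.9), length.out = 11) / 2
  eA[status_only] <- d; eB[status_only] <- -d
  data.frame(gene_symbol = symbols, lps_pmn = unname(eA),
             lps_nopmn = unname(eB), stringsAsFactors = FALSE)
}

simulated_gene_symbols <- function(n_genes) {
  c("Saa3", "Pon1", "Krt1-15", "Retnlg",
    sprintf("Gene%04d", seq_len(n_genes - 4L)))
}

#' Default simulation configuration
#'
#' Encodes the study design being emulated: 3 groups x \code{n_per_group}
#' mice, two-colour arrays with a pooled-sham Cy3 reference shared across
#' arrays, large inter-animal heterogeneity of the acute-phase response,
#' and phenotypes (BALF MPO activity, lung MPO protein, M1dG adducts)
#' whose group parameters are the printed study values and which are
#' coupled to each animal's response factor.
#'
#' @param n_per_group mice per group (default 5).
#' @param n_genes simulated genes (default 2000).
#' @param seed integer RNG seed.
#' @param ... overrides for any configuration field.
#' @return list of class \code{simulation_config}.
#' @export
default_config <- function(n_per_group = 5L, n_genes = 2000L, seed = 1L, ...) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_genes = as.integer(n_genes),
    spots_per_gene = 2L,
    baseline_log_mean = 7.0,
    baseline_log_sd = 1.0,
    effect_table = default_effect_table(n_genes),
    animal_heterogeneity_sd = 0.3,
    spot_noise_sd = 0.10,
    array_shift_sd = 0.20,
    reference_noise_sd = 0.05,
    control_spot_fraction = 0.01,
    mpo_balf_mean = c(SHAM = 0, LPS_PMN = 81.4, LPS_NOPMN = 0),
    mpo_balf_sd = c(SHAM = 0, LPS_PMN = 20.5, LPS_NOPMN = 0),
    mpo_balf_below_detection = c(SHAM = TRUE, LPS_PMN = FALSE, LPS_NOPMN = TRUE),
    mpo_lung_mean = c(SHAM = 58.18, LPS_PMN = 145.99, LPS_NOPMN = 58.18),
    mpo_lung_sd = c(SHAM = 77.26, LPS_PMN = 94.82, LPS_NOPMN = 77.26),
    m1dg_mean = c(SHAM = 5.1, LPS_PMN = 13.6, LPS_NOPMN = 10.6),
    m1dg_sd = c(SHAM = 0.2, LPS_PMN = 2.8, LPS_NOPMN = 2.5),
    m1dg_response_coupling = 1.0,
    seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  as_simulation_config(cfg)
}

#' @rdname default_config
#' @param x configuration list to validate.
#' @export
as_simulation_config <- function(x) {
  sds <- c(x$baseline_log_sd, x$animal_heterogeneity_sd, x$spot_noise_sd,
           x$array_shift_sd, x$reference_noise_sd,
           x$mpo_balf_sd, x$mpo_lung_sd, x$m1dg_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0", call. = FALSE)
  if (any(x$m1dg_mean <= 0)) stop("m1dg group means must be > 0", call. = FALSE)
  if (x$n_per_group < 1L || x$n_genes < 1L || x$spots_per_gene < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  symbols <- simulated_gene_symbols(x$n_genes)
  unknown <- setdiff(x$effect_table$gene_symbol, symbols)
  if (length(unknown) > 0L) {
    stop("effect_table refers to gene symbol(s) not in the simulation: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  class(x) <- "simulation_config"
  x
}

# Per-animal multiplicative response factor. Unit-mean log-normal so that
# phenotype group means equal their configured values in expectation;
# identically 1 for SHAM and whenever the heterogeneity sd is 0.
draw_response_factors <- function(groups, sd) {
  alpha <- stats::rlnorm(length(groups), meanlog = -sd^2 / 2, sdlog = sd)
  alpha[groups == "SHAM"] <- 1
  alpha
}

rnorm_trunc <- function(n, mean, sd, lower = 0, strict = FALSE) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- if (strict) x <= lower else x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- if (strict) x <= lower else x < lower
  }
  x
}

#' Simulate per-animal phenotypes
#'
#' BALF MPO activity is normal within group, truncated at zero, and below
#' the detection limit (reported 0, flagged) for SHAM and neutrophil-
#' depleted animals. M1dG adduct burden is coupled to the animal's
#' response factor: \code{sham_mean + coupling * alpha * (group_mean -
#' sham_mean) + noise}, truncated > 0, so the same acute-phase intensity
#' that scales gene expression drives genotoxicity.
#'
#' @param config \code{simulation_config}.
#' @param groups character vector of group labels, one per animal.
#' @param alpha optional response factors (defaults to fresh draws).
#' @param sample_ids optional ids (default \code{<group>_<i>}).
#' @param seed optional seed set before drawing (for standalone use).
#' @return \code{phenotype_table} with an \code{alpha} attribute.
#' @export
simulate_phenotypes <- function(config, groups, alpha = NULL,
                                sample_ids = NULL, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  bad <- setdiff(unique(groups), lung_groups())
  if (length(bad) > 0L) stop("unknown group(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(groups)
  if (is.null(alpha)) {
    alpha <- draw_response_factors(groups, config$animal_heterogeneity_sd)
  }
  stopifnot(length(alpha) == n)
  if (is.null(sample_ids)) {
    sample_ids <- stats::ave(seq_len(n), groups, FUN = seq_along)
    sample_ids <- paste(groups, sample_ids, sep = "_")
  }
  mpo <- numeric(n)
  below <- config$mpo_balf_below_detection[groups]
  detected <- !below
  mpo[detected] <- rnorm_trunc(sum(detected),
                               config$mpo_balf_mean[groups[detected]],
                               config$mpo_balf_sd[groups[detected]])
  mpo_lung <- rnorm_trunc(n, config$mpo_lung_mean[groups],
                          config$mpo_lung_sd[groups])
  sham_m1dg <- config$m1dg_mean[["SHAM"]]
  shift <- config$m1dg_response_coupling * alpha *
    (config$m1dg_mean[groups] - sham_m1dg)
  m1dg <- sham_m1dg + shift + stats::rnorm(n, 0, config$m1dg_sd[groups])
  redraw <- m1dg <= 0
  while (any(redraw)) {
    m1dg[redraw] <- sham_m1dg + shift[redraw] +
      stats::rnorm(sum(redraw), 0, config$m1dg_sd[groups[redraw]])
    redraw <- m1dg <= 0
  }
  out <- as_phenotype_table(data.frame(
    sample_id = sample_ids,
    mpo_balf_activity = mpo,
    mpo_below_detection = unname(below),
    mpo_lung_protein = mpo_lung,
    m1dg = m1dg,
    stringsAsFactors = FALSE))
  attr(out, "alpha") <- alpha
  out
}

#' Simulate a full two-colour common-reference experiment
#'
#' Generative model (all on the natural-log intensity scale):
#' per gene a baseline \code{b_g ~ N(baseline_log_mean, baseline_log_sd)};
#' per animal a response factor \code{alpha_a} (unit-mean log-normal,
#' 1 for SHAM); true expression \code{x_ga = b_g + alpha_a * effect_gG};
#' sample-channel spot signal \code{exp(x_ga + array_shift + spot_noise)}
#' with independent noise per spot replicate; reference-channel signal
#' \code{exp(b_g + ref_shift + ref_noise)} sharing \code{b_g} across all
#' arrays (one physical pooled-sham Cy3 hybridised to every slide).
#' Negative-control spots sit near the signal floor, positive controls at
#' a fixed high level.
#'
#' @param config \code{simulation_config}.
#' @return list with elements \code{spots} (spot_table), \code{design}
#'   (study_design), \code{annotation} (probe to gene table),
#'   \code{phenotypes} (phenotype_table) and \code{truth} (list of
#'   \code{animals} -- sample_id, group, alpha -- and \code{effects} --
#'   the effect table actually injected).
#' @export
simulate_experiment <- function(config = default_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  symbols <- simulated_gene_symbols(n_genes)
  groups <- rep(lung_groups(), each = config$n_per_group)
  sample_ids <- paste(groups, rep(seq_len(config$n_per_group), 3L), sep = "_")
  n_arrays <- length(sample_ids)

  b <- stats::rnorm(n_genes, config$baseline_log_mean, config$baseline_log_sd)
  alpha <- draw_response_factors(groups, config$animal_heterogeneity_sd)

  eff <- config$effect_table
  eA <- eB <- stats::setNames(numeric(n_genes), symbols)
  eA[eff$gene_symbol] <- eff$lps_pmn
  eB[eff$gene_symbol] <- eff$lps_nopmn
  effect_of <- cbind(SHAM = numeric(n_genes), LPS_PMN = unname(eA),
                     LPS_NOPMN = unname(eB))

  spg <- config$spots_per_gene
  n_gene_spots <- n_genes * spg
  probe_id <- sprintf("probe%05d_%d", rep(seq_len(n_genes), each = spg),
                      rep(seq_len(spg), n_genes))
  spot_gene <- rep(symbols, each = spg)
  n_ctrl <- max(2L, round(config$control_spot_fraction * n_gene_spots))
  n_neg <- ceiling(n_ctrl / 2); n_pos <- n_ctrl - n_neg
  ctrl_id <- c(sprintf("neg_ctrl_%03d", seq_len(n_neg)),
               sprintf("pos_ctrl_%03d", seq_len(n_pos)))
  spot_kind <- c(rep("regular", n_gene_spots),
                 rep("negative_control", n_neg), rep("positive_control", n_pos))
  spot_id <- c(probe_id, ctrl_id)
  n_spots <- length(spot_id)

  array_shift <- stats::rnorm(n_arrays, 0, config$array_shift_sd)
  ref_shift <- stats::rnorm(n_arrays, 0, config$array_shift_sd)

  recs <- vector("list", n_arrays)
  b_spot <- rep(b, each = spg)
  for (a in seq_len(n_arrays)) {
    e_spot <- rep(effect_of[, groups[[a]]], each = spg)
    x <- b_spot + alpha[[a]] * e_spot
    s_log <- x + array_shift[[a]] + stats::rnorm(n_gene_spots, 0, config$spot_noise_sd)
    r_log <- b_spot + ref_shift[[a]] + stats::rnorm(n_gene_spots, 0, config$reference_noise_sd)
    # controls: negatives hug the floor, positives a fixed bright level
    neg_s <- stats::rnorm(n_neg, 0.7, 0.3)
    neg_r <- stats::rnorm(n_neg, 0.7, 0.3)
    pos_s <- 12 + stats::rnorm(n_pos, 0, config$spot_noise_sd)
    pos_r <- 12 + stats::rnorm(n_pos, 0, config$reference_noise_sd)
    recs[[a]] <- data.frame(
      array_id = sample_ids[[a]],
      spot_id = spot_id,
      probe_id = c(probe_id, ctrl_id),
      gene_symbol = c(spot_gene, rep("", n_ctrl)),
      spot_kind = spot_kind,
      sample_signal = exp(c(s_log, neg_s, pos_s)),
      reference_signal = exp(c(r_log, neg_r, pos_r)),
      stringsAsFactors = FALSE)
  }
  spots <- as_spot_table(do.call(rbind, recs))
  design <- as_study_design(data.frame(sample_id = sample_ids, group = groups))
  annotation <- data.frame(probe_id = c(probe_id, ctrl_id),
                           gene_symbol = c(spot_gene, rep("", n_ctrl)),
                           stringsAsFactors = FALSE)
  phenotypes <- simulate_phenotypes(config, groups, alpha = alpha,
                                    sample_ids = sample_ids)
  truth <- list(
    animals = data.frame(sample_id = sample_ids, group = groups,
                         alpha = alpha, stringsAsFactors = FALSE),
    effects = data.frame(gene_symbol = symbols,
                         effect_lps_pmn = unname(eA),
                         effect_lps_nopmn = unname(eB),
                         baseline = b, stringsAsFactors = FALSE))
  list(spots = spots, design = design, annotation = annotation,
       phenotypes = phenotypes, truth = truth)
}

#' Write all artefacts of a simulated experiment to a directory
#'
#' Emits \code{spot_tables.tsv}, \code{design.tsv}, \code{annotation.tsv},
#' \code{phenotypes.tsv} and \code{truth.tsv} (long form: animal rows carry
#' alpha, gene rows carry injected effects).
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_spot_tables(sim$spots, p("spot_tables.tsv"))
  write_design(sim$design, p("design.tsv"))
  write_annotation(sim$annotation, p("annotation.tsv"))
  write_phenotypes(sim$phenotypes, p("phenotypes.tsv"))
  an <- sim$truth$animals
  ef <- sim$truth$effects
  truth <- rbind(
    data.frame(kind = "animal", id = an$sample_id, group = an$group,
               alpha = an$alpha, effect_lps_pmn = NA_real_,
               effect_lps_nopmn = NA_real_, baseline = NA_real_),
    data.frame(kind = "gene", id = ef$gene_symbol, group = "",
               alpha = NA_real_, effect_lps_pmn = ef$effect_lps_pmn,
               effect_lps_nopmn = ef$effect_lps_nopmn, baseline = ef$baseline))
  write_tsv_(truth, p("truth.tsv"))
  invisible(file.path(dir, c("spot_tables.tsv", "design.tsv", "annotation.tsv",
                             "phenotypes.tsv", "truth.tsv")))
}

#' Synthetic gene-set collection aligned with the simulated effect blocks
#'
#' Stands in for GO/pathway databases in tests and pipeline runs: one set
#' per effect block (acute-phase/shared up, shared down, neutrophil-
#' dependent up, depletion-specific up) padded with random null genes,
#' plus purely random null sets.
#'
#' @param config \code{simulation_config}.
#' @param n_null_sets number of random decoy sets.
#' @param null_set_size size of each decoy set.
#' @return \code{gene_set_collection}.
#' @export
synthetic_gmt <- function(config = default_config(), n_null_sets = 5L,
                          null_set_size = 25L) {
  stopifnot(inherits(config, "simulation_config"))
  eff <- config$effect_table
  symbols <- eff$gene_symbol
  up_both <- symbols[eff$lps_pmn > log(1.5) & eff$lps_nopmn > log(1.5)]
  down_both <- symbols[eff$lps_pmn < -log(1.5) & eff$lps_nopmn < -log(1.5)]
  pmn_dep <- symbols[eff$lps_pmn > log(1.5) & abs(eff$lps_nopmn) <= log(1.5)]
  nopmn_dep <- symbols[eff$lps_nopmn > log(1.5) & abs(eff$lps_pmn) <= log(1.5)]
  null_genes <- symbols[eff$lps_pmn == 0 & eff$lps_nopmn == 0]
  set.seed(config$seed + 7L)
  pad <- function(members, n_pad = 5L) {
    unique(c(members, sample(null_genes, min(n_pad, length(null_genes)))))
  }
  sets <- list(
    list(name = "acute_phase_response_up", description = "up in both LPS groups",
         members = pad(up_both)),
    list(name = "nonimmune_down", description = "down in both LPS groups",
         members = pad(down_both)),
    list(name = "neutrophil_dependent_up", description = "up only with PMN",
         members = pad(pmn_dep)),
    list(name = "depletion_specific_up", description = "up only without PMN",
         members = pad(nopmn_dep)))
  for (i in seq_len(n_null_sets)) {
    sets[[length(sets) + 1L]] <- list(
      name = sprintf("null_set_%02d", i), description = "random decoy",
      members = sample(symbols, null_set_size))
  }
  structure(stats::setNames(sets, vapply(sets, `[[`, "", "name")),
            class = "gene_set_collection")
}
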