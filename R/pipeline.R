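#' Resolve a pipeline configuration
#'
#' Accepts a named list or a path to a JSON (or YAML, if the yaml package
#' is installed) file. Unknown fields are rejected; the fully resolved
#' configuration is written back into the run directory for provenance.
#'
#' Fields and defaults: \code{out_dir} (required), \code{seed} 1,
#' \code{simulate} TRUE (or input paths \code{spots}, \code{design},
#' \code{annotation}, \code{phenotypes}, \code{gmt}), \code{n_per_group}
#' 5, \code{n_genes} 2000, \code{threshold} 1.5, \code{strict} TRUE,
#' \code{enrich_method} "fisher", \code{min_set} 3, \code{score_genes}
#' "union" (or "A"/"B"/"C"), \code{marker} "m1dg", \code{cor_method}
#' "spearman", \code{qn_anchor} "invariant", \code{pool} "all",
#' \code{reference_mode} "deviation".
#'
#' @param config list or file path.
#' @return validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the yaml package; use JSON instead",
             call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    out_dir = NULL, seed = 1L, simulate = TRUE,
    spots = NULL, design = NULL, annotation = NULL, phenotypes = NULL,
    gmt = NULL, n_per_group = 5L, n_genes = 2000L,
    threshold = 1.5, strict = TRUE,
    enrich_method = "fisher", min_set = 3L,
    score_genes = "union", marker = "m1dg", cor_method = "spearman",
    qn_anchor = "invariant", pool = "all", reference_mode = "deviation")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  cfg[names(config)] <- config
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 1) {
    stop("config error: threshold must be > 1 (got ", cfg$threshold, ")",
         call. = FALSE)
  }
  if (!cfg$score_genes %in% c("union", "A", "B", "C")) {
    stop("score_genes must be one of union, A, B, C", call. = FALSE)
  }
  if (!cfg$simulate) {
    for (f in c("spots", "design")) {
      if (is.null(cfg[[f]]) || !all(file.exists(cfg[[f]]))) {
        stop("config error: input path '", f, "' missing or nonexistent",
             call. = FALSE)
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> normalize -> differential expression -> Venn ->
#' enrichment -> response scores and phenotype correlations, writing every
#' stage artefact plus a manifest into one run directory. Reruns with the
#' same configuration and seed are byte-identical.
#'
#' Outputs: \code{matrix.tsv}, \code{qc.tsv}, \code{contrasts.tsv},
#' \code{venn.tsv}, \code{enrichment.tsv}, \code{scores.tsv},
#' \code{correlations.json}, \code{manifest.json} (plus the simulated
#' inputs and \code{resolved_config.json}, \code{log.txt}).
#'
#' @param config see [pipeline_config()].
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  jsonlite::write_json(unclass(cfg), p("resolved_config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  # --- inputs ---------------------------------------------------------------
  inputs <- stage("inputs", {
    if (isTRUE(cfg$simulate)) {
      sim_cfg <- default_config(n_per_group = cfg$n_per_group,
                                n_genes = cfg$n_genes, seed = cfg$seed)
      sim <- simulate_experiment(sim_cfg)
      write_simulation(sim, cfg$out_dir)
      gmt <- if (is.null(cfg$gmt)) synthetic_gmt(sim_cfg) else read_gmt(cfg$gmt)
      write_gmt(gmt, p("gene_sets.gmt"))
      note("inputs: simulated ", nrow(sim$spots), " spot records, ",
           nrow(sim$design), " arrays")
      list(spots = sim$spots, design = sim$design,
           annotation = sim$annotation, phenotypes = sim$phenotypes,
           gmt = gmt)
    } else {
      spots <- read_spot_tables(cfg$spots)
      design <- read_design(cfg$design)
      annotation <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation)
      phenotypes <- if (!is.null(cfg$phenotypes)) read_phenotypes(cfg$phenotypes)
      gmt <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt)
      note("inputs: read ", nrow(spots), " spot records, ",
           nrow(design), " arrays")
      list(spots = spots, design = design, annotation = annotation,
           phenotypes = phenotypes, gmt = gmt)
    }
  })

  # --- normalization --------------------------------------------------------
  mat <- stage("normalize", {
    m <- normalize_arrays(inputs$spots, annotation = inputs$annotation,
                          qn_anchor = cfg$qn_anchor, pool = cfg$pool,
                          reference_mode = cfg$reference_mode)
    write_matrix(m, p("matrix.tsv"))
    qc <- pca_qc(m, inputs$design)
    qc_df <- merge(qc$scores, qc$dispersion, by = "group", sort = TRUE)
    qc_df <- qc_df[order(qc_df$sample_id),
                   c("sample_id", "group", "PC1", "PC2", "mean_dist")]
    qc_df$flagged_most_heterogeneous <- qc_df$group == qc$flagged
    write_tsv_(qc_df, p("qc.tsv"))
    note("normalize: ", nrow(m), " genes x ", ncol(m),
         " samples; most heterogeneous group: ", qc$flagged)
    m
  })

  # --- differential expression ---------------------------------------------
  de <- stage("de", {
    med <- group_medians(mat, inputs$design)
    ct <- contrast_fold_changes(med)
    calls <- call_de(ct, threshold = cfg$threshold, strict = cfg$strict)
    tab <- calls$table
    tab$de <- calls$flags[cbind(match(tab$gene_symbol, rownames(calls$flags)),
                                match(tab$contrast, colnames(calls$flags)))]
    write_tsv_(tab, p("contrasts.tsv"))
    vp <- venn_partition(calls)
    venn_df <- data.frame(
      region = c(names(vp$regions), "union"),
      count = c(unname(vp$counts), vp$union_count),
      genes = c(vapply(vp$regions, paste, "", collapse = ","),
                paste(sort(unique(unlist(vp$sets))), collapse = ",")),
      stringsAsFactors = FALSE)
    write_tsv_(venn_df, p("venn.tsv"))
    note("de: ", paste(sprintf("%s=%d", calls$counts$contrast,
                               calls$counts$n_de), collapse = " "),
         " union=", vp$union_count)
    list(calls = calls, venn = vp)
  })

  # --- enrichment -----------------------------------------------------------
  stage("enrich", {
    union_genes <- sort(unique(unlist(de$venn$sets)))
    if (length(union_genes) == 0L || is.null(inputs$gmt)) {
      write_tsv_(data.frame(set_name = character(), K = integer(),
                            k = integer(), n = integer(), N = integer(),
                            p = numeric(), q = numeric(),
                            overlap = character()), p("enrichment.tsv"))
      note("enrich: skipped (no DE genes or no gene sets)")
    } else {
      er <- enrich(union_genes, rownames(mat), inputs$gmt,
                   method = cfg$enrich_method, min_set = cfg$min_set)
      write_tsv_(as.data.frame(er), p("enrichment.tsv"))
      note("enrich: ", nrow(er), " sets tested against ",
           length(union_genes), " DE genes")
    }
  })

  # --- response scores and correlations ------------------------------------
  stage("score", {
    gene_list <- if (cfg$score_genes == "union") {
      sort(unique(unlist(de$venn$sets)))
    } else {
      de$venn$sets[[cfg$score_genes]]
    }
    if (length(gene_list) == 0L) {
      write_tsv_(data.frame(sample_id = character(), group = character(),
                            score = numeric()), p("scores.tsv"))
      jsonlite::write_json(list(note = "no DE genes; scores not computed"),
                           p("correlations.json"), auto_unbox = TRUE)
      note("score: skipped (empty DE gene list)")
    } else {
      sc <- response_score(mat, gene_list, inputs$design)
      write_tsv_(as.data.frame(sc), p("scores.tsv"))
      cors <- list()
      if (!is.null(inputs$phenotypes)) {
        cors$response_vs_m1dg <- correlate_response_with_phenotype(
          sc, inputs$phenotypes, marker = cfg$marker, method = cfg$cor_method)
        ph <- inputs$phenotypes
        mpo <- ph$mpo_balf_activity
        mpo[ph$mpo_below_detection] <- 0
        cors$mpo_vs_m1dg <- c(list(method = "pearson",
                                   marker = "mpo_balf_activity vs m1dg"),
                              pearson_corr(mpo, ph$m1dg)[c("r", "p", "n")])
      }
      jsonlite::write_json(cors, p("correlations.json"), auto_unbox = TRUE,
                           digits = NA)
      note("score: ", length(gene_list), " genes; ",
           if (length(cors) > 0L) sprintf("%s %s = %.3f (p = %.3g)",
                                          cfg$cor_method, cfg$marker,
                                          cors$response_vs_m1dg$estimate,
                                          cors$response_vs_m1dg$p)
           else "no phenotypes")
    }
  })

  writeLines(log_lines, p("log.txt"))

  # --- manifest -------------------------------------------------------------
  outputs <- c("matrix.tsv", "qc.tsv", "contrasts.tsv", "venn.tsv",
               "enrichment.tsv", "scores.tsv", "correlations.json")
  checksums <- as.list(tools::md5sum(vapply(outputs, p, "")))
  names(checksums) <- outputs
  manifest <- list(
    package = "neutroflux",
    version = as.character(utils::packageVersion("neutroflux")),
    seed = cfg$seed,
    config = unclass(cfg),
    row_counts = list(
      spots = nrow(inputs$spots),
      matrix_genes = length(readLines(p("matrix.tsv"))) - 1L,
      de_union = de$venn$union_count),
    checksums = checksums)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Summarize a completed run directory
#'
#' Regenerates a human-readable report from the stage outputs alone (no
#' report-only arithmetic): per-contrast DE counts with directions, Venn
#' region counts and union, overlap percentages, top enriched sets and the
#' phenotype correlations. Deterministic for an unchanged directory.
#'
#' @param run_dir path produced by [run_pipeline()].
#' @param path optional output file (default \code{report.md} inside the
#'   run directory).
#' @return the report lines, invisibly.
#' @export
summarize_run <- function(run_dir, path = file.path(run_dir, "report.md")) {
  need <- c("contrasts.tsv", "venn.tsv", "enrichment.tsv", "scores.tsv",
            "correlations.json")
  for (f in need) {
    if (!file.exists(file.path(run_dir, f))) {
      stop("missing stage output: ", f, call. = FALSE)
    }
  }
  ct <- utils::read.delim(file.path(run_dir, "contrasts.tsv"))
  venn <- utils::read.delim(file.path(run_dir, "venn.tsv"),
                            colClasses = c("character", "integer", "character"))
  enr <- utils::read.delim(file.path(run_dir, "enrichment.tsv"))
  cors <- jsonlite::read_json(file.path(run_dir, "correlations.json"),
                              simplifyVector = TRUE)
  lines <- c("# Pipeline summary", "", "## Differentially expressed genes", "")
  for (cn in unique(ct$contrast)) {
    sub <- ct[ct$contrast == cn & ct$de, ]
    lines <- c(lines, sprintf("- contrast %s: %d genes (%d up, %d down)",
                              cn, nrow(sub), sum(sub$direction == "up"),
                              sum(sub$direction == "down")))
  }
  lines <- c(lines, "", "## Venn partition", "")
  for (i in seq_len(nrow(venn))) {
    lines <- c(lines, sprintf("- %s: %d", venn$region[i], venn$count[i]))
  }
  region <- function(lbl) {
    g <- venn$genes[venn$region == lbl]
    if (length(g) == 0L || !nzchar(g)) character() else
      strsplit(g, ",", fixed = TRUE)[[1L]]
  }
  setA <- unique(c(region("A_only"), region("AB"), region("AC"), region("ABC")))
  setB <- unique(c(region("B_only"), region("AB"), region("BC"), region("ABC")))
  setC <- unique(c(region("C_only"), region("AC"), region("BC"), region("ABC")))
  if (length(setB) > 0L) {
    lines <- c(lines, "", sprintf(
      "- %d%% of contrast-B DE genes overlap contrast A",
      overlap_percentage(setB, setA)))
  }
  if (length(setC) > 0L) {
    lines <- c(lines, sprintf(
      "- %d%% of contrast-C DE genes fall inside the A/B union",
      overlap_percentage(setC, union(setA, setB))))
  }
  if (nrow(enr) > 0L) {
    lines <- c(lines, "", "## Top enriched sets", "")
    top <- utils::head(enr[order(enr$p, enr$set_name), ], 5L)
    for (i in seq_len(nrow(top))) {
      lines <- c(lines, sprintf("- %s: k/K = %d/%d, p = %.3g, q = %.3g",
                                top$set_name[i], top$k[i], top$K[i],
                                top$p[i], top$q[i]))
    }
  }
  if (is.list(cors) && !is.null(cors$response_vs_m1dg)) {
    r <- cors$response_vs_m1dg
    lines <- c(lines, "", "## Correlations", "",
               sprintf("- response score vs %s (%s): %.3f, p = %.3g, n = %d",
                       r$marker, r$method, r$estimate, r$p, r$n))
    if (!is.null(cors$mpo_vs_m1dg)) {
      m <- cors$mpo_vs_m1dg
      lines <- c(lines, sprintf("- BALF MPO vs M1dG (pearson): %.3f, p = %.3g, n = %d",
                                m$r, m$p, m$n))
    }
  }
  writeLines(lines, path)
  invisible(lines)
}
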