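#' The three study contrasts
#'
#' Fixed orientation: A = LPS_PMN - SHAM, B = LPS_NOPMN - SHAM,
#' C = LPS_PMN - LPS_NOPMN (first group minus second on the natural-log
#' median scale).
#'
#' @return named list of length-2 character vectors (first, second group).
#' @export
lung_contrasts <- function() {
  list(A = c("LPS_PMN", "SHAM"),
       B = c("LPS_NOPMN", "SHAM"),
       C = c("LPS_PMN", "LPS_NOPMN"))
}

#' Per-gene, per-group median expression
#'
#' Medians are robust to the single-animal outliers the heterogeneous
#' acute-phase response produces; even group sizes use the mean of the two
#' central values (the usual sample-median convention).
#'
#' @param matrix genes x samples natural-log expression matrix.
#' @param design \code{study_design}; every matrix column must appear.
#' @return genes x groups numeric matrix.
#' @export
group_medians <- function(matrix, design) {
  stopifnot(is.matrix(matrix))
  missing_s <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing_s) > 0L) {
    stop("sample(s) in matrix absent from design: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  group <- design$group[match(colnames(matrix), design$sample_id)]
  groups <- intersect(lung_groups(), unique(group))
  out <- do.call(cbind, lapply(groups, function(g) {
    cols <- matrix[, group == g, drop = FALSE]
    apply(cols, 1L, stats::median)
  }))
  dimnames(out) <- list(rownames(matrix), groups)
  out
}

#' Median fold changes for the study contrasts
#'
#' Log-ratio = median(first group) - median(second group) on the natural-
#' log scale; fold change = exp(|log-ratio|), reported on the linear scale
#' with a direction (\code{none} iff the log-ratio is exactly 0).
#'
#' @param medians genes x groups matrix from [group_medians()].
#' @param contrasts subset of \code{names(lung_contrasts())} to compute.
#' @return data.frame of class \code{contrast_table}: gene_symbol,
#'   contrast, log_ratio, fold_change, direction.
#' @export
contrast_fold_changes <- function(medians, contrasts = names(lung_contrasts())) {
  defs <- lung_contrasts()
  stopifnot(all(contrasts %in% names(defs)))
  rows <- lapply(contrasts, function(cn) {
    pair <- defs[[cn]]
    if (!all(pair %in% colnames(medians))) {
      stop("contrast ", cn, " needs groups ", paste(pair, collapse = ", "),
           call. = FALSE)
    }
    lr <- medians[, pair[[1L]]] - medians[, pair[[2L]]]
    data.frame(gene_symbol = rownames(medians), contrast = cn,
               log_ratio = unname(lr), fold_change = exp(abs(unname(lr))),
               direction = ifelse(lr > 0, "up", ifelse(lr < 0, "down", "none")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Call differentially expressed genes by fold-change threshold
#'
#' @param table \code{contrast_table}.
#' @param threshold linear fold-change threshold (> 1).
#' @param strict if TRUE (default) a gene is called at fold change
#'   strictly greater than the threshold ("more than 1.5-fold"); if FALSE
#'   at \code{>=}.
#' @return list of class \code{de_calls}: \code{flags} (genes x contrasts
#'   logical matrix), \code{counts} (per contrast: n_de, n_up, n_down),
#'   \code{table}, \code{threshold}, \code{strict}.
#' @export
call_de <- function(table, threshold = 1.5, strict = TRUE) {
  stopifnot(inherits(table, "contrast_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1) {
    stop("threshold must be a single number > 1", call. = FALSE)
  }
  de <- if (strict) table$fold_change > threshold else table$fold_change >= threshold
  contrasts <- unique(table$contrast)
  genes <- unique(table$gene_symbol)
  flags <- matrix(FALSE, length(genes), length(contrasts),
                  dimnames = list(genes, contrasts))
  flags[cbind(match(table$gene_symbol, genes),
              match(table$contrast, contrasts))] <- de
  counts <- do.call(rbind, lapply(contrasts, function(cn) {
    sub <- table[table$contrast == cn & de, ]
    data.frame(contrast = cn, n_de = nrow(sub),
               n_up = sum(sub$direction == "up"),
               n_down = sum(sub$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  structure(list(flags = flags, counts = counts, table = table,
                 threshold = threshold, strict = strict),
            class = "de_calls")
}

#' Seven-region Venn partition of three DE gene sets
#'
#' @param a,b,c the three gene sets. Either three character membership
#'   vectors, or three named logical vectors over an identical gene
#'   universe, or a single \code{de_calls} object in \code{a} (contrasts
#'   A, B, C).
#' @return list of class \code{venn_partition}: \code{regions} (named
#'   list of sorted membership vectors for A_only, B_only, C_only, AB,
#'   AC, BC, ABC), \code{counts}, \code{union_count}, \code{sets}.
#' @export
venn_partition <- function(a, b = NULL, c = NULL) {
  if (inherits(a, "de_calls")) {
    flags <- a$flags
    if (!all(c("A", "B", "C") %in% colnames(flags))) {
      stop("de_calls must cover contrasts A, B and C", call. = FALSE)
    }
    g <- rownames(flags)
    a <- g[flags[, "A"]]; b <- g[flags[, "B"]]; c <- g[flags[, "C"]]
  } else if (is.logical(a)) {
    if (!is.logical(b) || !is.logical(c) ||
        !identical(names(a), names(b)) || !identical(names(a), names(c)) ||
        is.null(names(a))) {
      stop("logical flag vectors must share one named gene universe",
           call. = FALSE)
    }
    g <- names(a)
    a <- g[a]; b <- g[b]; c <- g[c]
  }
  a <- unique(as.character(a)); b <- unique(as.character(b))
  c <- unique(as.character(c))
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  regions <- list(
    A_only = sort(u[in_a & !in_b & !in_c]),
    B_only = sort(u[!in_a & in_b & !in_c]),
    C_only = sort(u[!in_a & !in_b & in_c]),
    AB = sort(u[in_a & in_b & !in_c]),
    AC = sort(u[in_a & !in_b & in_c]),
    BC = sort(u[!in_a & in_b & in_c]),
    ABC = sort(u[in_a & in_b & in_c]))
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 union_count = length(u),
                 sets = list(A = sort(a), B = sort(b), C = sort(c))),
            class = "venn_partition")
}

#' Percentage of one gene set contained in another
#'
#' \code{100 * |X intersect Y| / |X|}, rounded half-up to the nearest
#' integer (the convention behind the reported 74\% and 89\% overlaps).
#'
#' @param x,y character gene sets; \code{x} must be non-empty.
#' @return integer percentage.
#' @export
overlap_percentage <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0L) stop("overlap percentage of an empty set is undefined",
                            call. = FALSE)
  as.integer(floor(100 * length(intersect(x, y)) / length(x) + 0.5))
}

#' Most extreme fold changes of a contrast
#'
#' @param table \code{contrast_table}.
#' @param contrast one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @return list with \code{up} and \code{down}, each either NULL (no gene
#'   moved in that direction) or \code{list(gene_symbol, fold_change)};
#'   ties break to the lexicographically smallest symbol.
#' @export
extreme_changes <- function(table, contrast) {
  stopifnot(inherits(table, "contrast_table"), length(contrast) == 1L)
  sub <- table[table$contrast == contrast, ]
  if (nrow(sub) == 0L) stop("no rows for contrast ", contrast, call. = FALSE)
  pick <- function(dir) {
    d <- sub[sub$direction == dir, ]
    if (nrow(d) == 0L) return(NULL)
    d <- d[order(-d$fold_change, d$gene_symbol), ]
    list(gene_symbol = d$gene_symbol[[1L]], fold_change = d$fold_change[[1L]])
  }
  list(up = pick("up"), down = pick("down"))
}

#' Regression of one contrast's log-ratios on another's
#'
#' Ordinary least squares of contrast-B log-ratios on contrast-A
#' log-ratios over a gene list (typically the genes shared by both DE
#' lists); the slope measures how much the depleted response is
#' attenuated relative to the intact one.
#'
#' @param table \code{contrast_table} containing contrasts A and B.
#' @param genes character vector (>= 3) of genes to regress over.
#' @param x_contrast,y_contrast contrast ids (defaults A and B).
#' @return list: \code{r} (Pearson), \code{slope}, \code{intercept},
#'   \code{n}.
#' @export
cross_contrast_regression <- function(table, genes,
                                      x_contrast = "A", y_contrast = "B") {
  stopifnot(inherits(table, "contrast_table"))
  genes <- unique(genes)
  if (length(genes) < 3L) stop("need >= 3 genes for regression", call. = FALSE)
  get <- function(cn) {
    sub <- table[table$contrast == cn, ]
    v <- sub$log_ratio[match(genes, sub$gene_symbol)]
    if (anyNA(v)) stop("gene(s) missing from contrast ", cn, call. = FALSE)
    v
  }
  x <- get(x_contrast); y <- get(y_contrast)
  if (stats::var(x) == 0) stop("zero variance in predictor log-ratios", call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  list(r = stats::cor(x, y), slope = slope,
       intercept = mean(y) - slope * mean(x), n = length(genes))
}
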