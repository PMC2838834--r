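#' Per-sample expression-response score
#'
#' The sample-specific measure of the gene-expression response: over a
#' gene list G (by default the union of the differentially expressed
#' lists), each sample's log expression is adjusted for the median of the
#' sham group, and the root mean square of the deviations is taken:
#' \code{score_s = sqrt(mean_g (x_gs - median_sham(x_g))^2)}. The score
#' is 0 iff the sample sits exactly on the sham medians for every listed
#' gene.
#'
#' @param matrix genes x samples natural-log expression matrix.
#' @param genes non-empty character vector of genes (must be matrix rows).
#' @param design \code{study_design}; the SHAM group must be non-empty.
#' @return data.frame of class \code{response_scores}: sample_id, group,
#'   score; attributes \code{genes} and \code{sham_median}.
#' @export
response_score <- function(matrix, genes, design) {
  stopifnot(is.matrix(matrix))
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  missing_g <- setdiff(genes, rownames(matrix))
  if (length(missing_g) > 0L) {
    stop("gene(s) not in matrix: ",
         paste(utils::head(missing_g, 10L), collapse = ", "), call. = FALSE)
  }
  group <- design$group[match(colnames(matrix), design$sample_id)]
  if (anyNA(group)) stop("matrix sample(s) absent from design", call. = FALSE)
  sham_cols <- which(group == "SHAM")
  if (length(sham_cols) == 0L) stop("SHAM group is empty", call. = FALSE)
  sub <- matrix[genes, , drop = FALSE]
  sham_median <- apply(sub[, sham_cols, drop = FALSE], 1L, stats::median)
  dev <- sub - sham_median
  score <- sqrt(colMeans(dev^2))
  out <- data.frame(sample_id = colnames(matrix), group = group,
                    score = unname(score), stringsAsFactors = FALSE)
  attr(out, "genes") <- genes
  attr(out, "sham_median") <- sham_median
  class(out) <- c("response_scores", "data.frame")
  out
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
permutation_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  smaller <- permutation_matrix(n - 1L)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    left <- smaller
    left[left >= i] <- left[left >= i] + 1L
    blocks[[i]] <- cbind(rep(i, nrow(smaller)), left, deparse.level = 0)
  }
  do.call(rbind, blocks)
}

#' Spearman rank correlation
#'
#' Average ranks for ties. The two-sided p-value is exact (full
#' permutation enumeration of one margin) for n <= 9 with no ties, and
#' uses the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list: \code{rho}, \code{p}, \code{n}, \code{method}.
#' @export
spearman_corr <- function(x, y) {
  check_paired(x, y)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    perms <- permutation_matrix(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    s <- as.numeric(ry_perm %*% rx)
    rho_perm <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- t_pvalue(rho, n)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Pearson correlation
#'
#' Product-moment correlation with the usual two-sided t-test p-value on
#' n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 3, non-constant.
#' @return list: \code{r}, \code{p}, \code{n}.
#' @export
pearson_corr <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  list(r = r, p = t_pvalue(r, length(x)), n = length(x))
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  invisible(TRUE)
}

t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Correlate response scores with a phenotype marker
#'
#' Joins scores and phenotypes on sample_id (all animals present in both
#' tables) and computes the requested correlation. Below-detection MPO
#' activity values are substituted by 0 (default; a logged note is
#' emitted) or by half the minimum detected value.
#'
#' @param scores \code{response_scores}.
#' @param phenotypes \code{phenotype_table}.
#' @param marker phenotype column: \code{"m1dg"},
#'   \code{"mpo_balf_activity"} or \code{"mpo_lung_protein"}.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @param below_detection \code{"zero"} or \code{"half-min"}.
#' @return list: \code{method}, \code{marker}, \code{estimate},
#'   \code{p}, \code{n}.
#' @export
correlate_response_with_phenotype <- function(scores, phenotypes,
                                              marker = "m1dg",
                                              method = c("spearman", "pearson"),
                                              below_detection = c("zero", "half-min")) {
  method <- match.arg(method)
  below_detection <- match.arg(below_detection)
  stopifnot(inherits(scores, "response_scores"),
            inherits(phenotypes, "phenotype_table"))
  if (!marker %in% c("m1dg", "mpo_balf_activity", "mpo_lung_protein")) {
    stop("unknown marker: ", marker, call. = FALSE)
  }
  shared <- intersect(scores$sample_id, phenotypes$sample_id)
  if (length(shared) < 3L) {
    stop("need >= 3 animals shared between scores and phenotypes (got ",
         length(shared), ")", call. = FALSE)
  }
  v <- phenotypes[[marker]][match(shared, phenotypes$sample_id)]
  if (marker == "mpo_balf_activity") {
    below <- phenotypes$mpo_below_detection[match(shared, phenotypes$sample_id)]
    if (any(below)) {
      if (below_detection == "zero") {
        message(sum(below), " below-detection MPO value(s) treated as 0")
        v[below] <- 0
      } else {
        half_min <- min(v[!below]) / 2
        message(sum(below), " below-detection MPO value(s) set to half ",
                "the minimum detected value")
        v[below] <- half_min
      }
    }
  }
  s <- scores$score[match(shared, scores$sample_id)]
  res <- if (method == "spearman") spearman_corr(s, v) else pearson_corr(s, v)
  list(method = method, marker = marker,
       estimate = if (method == "spearman") res$rho else res$r,
       p = res$p, n = res$n)
}
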