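#' Upper-tail hypergeometric probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}: the chance of
#' drawing at least \code{k} members of a \code{K}-gene set when sampling
#' \code{n} genes without replacement from a universe of \code{N}.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param n query list size (<= N).
#' @param K set size within the universe (<= N).
#' @param N universe size.
#' @return one-sided p-value in (0, 1].
#' @export
hypergeom_p <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N || k > min(n, K)) {
    stop("impossible counts: need k <= min(n, K) and n, K <= N", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j}, capped at
#' 1 and monotone non-decreasing in p.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(pvalues[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric (Fisher-exact) test per gene set, after
#' intersecting every set with the expression universe (the genes actually
#' on the collapsed array, not the genome). \code{method = "ease"} uses
#' DAVID's conservative EASE variant, replacing the observed overlap k by
#' \code{max(k - 1, 0)} in the tail.
#'
#' @param query character vector of genes of interest (must be a subset of
#'   the universe).
#' @param universe character vector of all measurable genes.
#' @param sets \code{gene_set_collection}.
#' @param method \code{"fisher"} or \code{"ease"}.
#' @param min_set minimum expressed set size for a set to be reported.
#' @return data.frame of class \code{enrichment_result}, one row per
#'   reported set, sorted by p: set_name, K, k, n, N, p, q, overlap
#'   (comma-separated symbols). BH q-values are computed across the
#'   reported rows.
#' @export
enrich <- function(query, universe, sets, method = c("fisher", "ease"),
                   min_set = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0L) {
    stop("query gene(s) not in universe: ",
         paste(utils::head(offenders, 10L), collapse = ", "), call. = FALSE)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, universe)
    K <- length(members)
    if (K < min_set) return(NULL)
    ov <- sort(intersect(members, query))
    k <- length(ov)
    k_eff <- if (method == "ease") max(k - 1L, 0L) else k
    data.frame(set_name = s$name, K = K, k = k, n = n, N = N,
               p = hypergeom_p(k_eff, n, K, N),
               overlap = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(set_name = character(), K = integer(), k = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), overlap = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), c("set_name", "K", "k", "n", "N",
                                           "p", "q", "overlap")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
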