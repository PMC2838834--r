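#' Natural-log transform a spot table into a two-channel matrix
#'
#' First step of the four-step normalization. Produces a
#' \code{channel_matrix}: spots x arrays log-intensity matrices for the
#' sample (Cy5) and reference (Cy3) channels plus spot metadata. Arrays
#' are ordered by first appearance, spots by their order on the first
#' array.
#'
#' @param spots \code{spot_table} (signals strictly positive; the floor
#'   policy is applied at read time).
#' @return list of class \code{channel_matrix} with elements
#'   \code{sample}, \code{reference} (numeric matrices), \code{spot_info}
#'   (data.frame: spot_id, probe_id, gene_symbol, spot_kind) and
#'   \code{array_ids}.
#' @export
ln_transform <- function(spots) {
  stopifnot(inherits(spots, "spot_table"))
  if (any(spots$sample_signal <= 0) || any(spots$reference_signal <= 0)) {
    stop("internal error: non-positive signal reached ln_transform; ",
         "the floor policy must be applied upstream", call. = FALSE)
  }
  array_ids <- unique(spots$array_id)
  first <- spots[spots$array_id == array_ids[[1L]], ]
  spot_order <- first$spot_id
  n_spots <- length(spot_order)
  s <- r <- matrix(NA_real_, n_spots, length(array_ids),
                   dimnames = list(spot_order, array_ids))
  for (a in array_ids) {
    part <- spots[spots$array_id == a, ]
    idx <- match(spot_order, part$spot_id)
    s[, a] <- log(part$sample_signal[idx])
    r[, a] <- log(part$reference_signal[idx])
  }
  structure(list(
    sample = s, reference = r,
    spot_info = data.frame(spot_id = first$spot_id, probe_id = first$probe_id,
                           gene_symbol = first$gene_symbol,
                           spot_kind = first$spot_kind,
                           stringsAsFactors = FALSE),
    array_ids = array_ids), class = "channel_matrix")
}

#' Drop control spots from a channel matrix
#'
#' Positive and negative controls serve quality control only and are
#' excluded before quantile normalization.
#'
#' @param channels \code{channel_matrix}.
#' @return \code{channel_matrix} restricted to regular spots; the number
#'   of removed control spots is reported.
#' @export
drop_controls <- function(channels) {
  stopifnot(inherits(channels, "channel_matrix"))
  keep <- channels$spot_info$spot_kind == "regular"
  n_drop <- sum(!keep)
  if (n_drop > 0L) message("excluded ", n_drop, " control spot(s)")
  channels$sample <- channels$sample[keep, , drop = FALSE]
  channels$reference <- channels$reference[keep, , drop = FALSE]
  channels$spot_info <- channels$spot_info[keep, ]
  rownames(channels$spot_info) <- NULL
  channels
}

# --- quantile normalization core ------------------------------------------

# Classic quantile normalization: every channel's empirical distribution is
# replaced by the mean-of-sorted-values reference distribution; ties within
# a channel receive the mean of the reference values over the ranks they
# span.
qn_classic <- function(m) {
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    grp <- cumsum(!duplicated(m[o, j]))
    tie_means <- as.numeric(tapply(ref, grp, mean))
    out[o, j] <- tie_means[grp]
  }
  out
}

# Invariant-anchored quantile normalization. Channel offsets and spot
# consensus levels are estimated by a one-step median polish; spots whose
# residuals stay within `mad_mult` robust SDs in every channel are treated
# as empirically invariant and used as anchors. Each channel is then mapped
# onto the cross-channel mean level of the anchors by monotone piecewise-
# linear quantile matching (slope-1 extension beyond the anchor range).
# Differentially expressed spots, which classic quantile normalization
# compresses toward the pooled distribution, ride along the interpolated
# map and keep their offsets; when channels differ only by additive
# constants the map removes them exactly.
qn_invariant <- function(m, mad_mult = 3, min_anchor_frac = 0.01) {
  spot_level <- apply(m, 1L, stats::median)
  res <- m - spot_level
  chan_offset <- apply(res, 2L, stats::median)
  res <- sweep(res, 2L, chan_offset)
  thr <- mad_mult * stats::mad(res, center = 0) + 1e-12
  anchors <- which(apply(abs(res), 1L, max) <= thr)
  if (length(anchors) < max(3L, ceiling(min_anchor_frac * nrow(m)))) {
    warning("too few invariant anchor spots (", length(anchors),
            "); falling back to classic quantile normalization")
    return(qn_classic(m))
  }
  ys <- sort(rowMeans(m)[anchors])
  out <- m
  k <- length(ys)
  for (j in seq_len(ncol(m))) {
    xs <- sort(m[anchors, j])
    dup <- duplicated(xs)
    if (any(dup)) { # collapse tied anchor values to their mean target
      ys_j <- as.numeric(tapply(ys, cumsum(!dup), mean))
      xs_j <- xs[!dup]
    } else {
      ys_j <- ys; xs_j <- xs
    }
    kj <- length(xs_j)
    v <- m[, j]
    if (kj == 1L) {
      out[, j] <- v - xs_j + ys_j
      next
    }
    lo <- v < xs_j[1L]; hi <- v > xs_j[kj]; mid <- !(lo | hi)
    out[mid, j] <- stats::approx(xs_j, ys_j, xout = v[mid], ties = "ordered")$y
    out[lo, j] <- ys_j[1L] - (xs_j[1L] - v[lo])
    out[hi, j] <- ys_j[kj] + (v[hi] - xs_j[kj])
  }
  out
}

#' Quantile normalization of all scans
#'
#' Second step of the four-step normalization. All channels (Cy5 sample
#' scans and Cy3 reference scans of every array, 2 x n_arrays in total)
#' are normalized together by default; \code{pool = "by-role"} normalizes
#' the sample scans and the reference scans separately for sensitivity
#' analysis.
#'
#' Two mapping variants are provided. \code{anchor = "all"} (the default
#' for matrices) is classic quantile normalization: afterwards every
#' channel has identical sorted values, with ties receiving the mean of
#' the reference values they span. \code{anchor = "invariant"} (the
#' pipeline default, see [normalize_arrays()]) estimates the map on
#' empirically invariant spots only and extends it by monotone
#' interpolation, which leaves genuine differential signal uncompressed
#' and is exactly offset-removing when channels differ by additive
#' constants.
#'
#' @param channels \code{channel_matrix}, or a plain spots x channels
#'   numeric matrix (>= 2 columns).
#' @param anchor \code{"all"} or \code{"invariant"}.
#' @param pool \code{"all"} or \code{"by-role"} (channel_matrix input only).
#' @param mad_mult robust-SD multiple delimiting invariant residuals.
#' @param min_anchor_frac minimum usable anchor fraction before falling
#'   back to the classic map.
#' @return object of the same shape as the input.
#' @export
quantile_normalize <- function(channels, anchor = c("all", "invariant"),
                               pool = c("all", "by-role"),
                               mad_mult = 3, min_anchor_frac = 0.01) {
  anchor <- match.arg(anchor)
  pool <- match.arg(pool)
  core <- function(m) {
    if (ncol(m) < 2L) stop("quantile normalization needs >= 2 channels", call. = FALSE)
    if (anchor == "all") qn_classic(m) else
      qn_invariant(m, mad_mult = mad_mult, min_anchor_frac = min_anchor_frac)
  }
  if (is.matrix(channels)) {
    if (anyNA(channels) || any(!is.finite(channels))) {
      stop("channels must be finite", call. = FALSE)
    }
    return(core(channels))
  }
  stopifnot(inherits(channels, "channel_matrix"))
  if (any(channels$spot_info$spot_kind != "regular")) {
    stop("control spots must be excluded (drop_controls) before ",
         "quantile normalization", call. = FALSE)
  }
  if (pool == "all") {
    m <- cbind(channels$sample, channels$reference)
    m <- core(m)
    n <- ncol(channels$sample)
    channels$sample <- m[, seq_len(n), drop = FALSE]
    channels$reference <- m[, n + seq_len(n), drop = FALSE]
  } else {
    channels$sample <- core(channels$sample)
    channels$reference <- core(channels$reference)
  }
  channels
}

#' Common-reference correction
#'
#' Third step: the sample-channel log signal of each spot is corrected for
#' the deviation of its array's reference-channel signal from the
#' across-array mean reference signal of that spot,
#' \code{corrected_ga = s_ga - (r_ga - mean_a' r_ga')}; reference channels
#' are then dropped. The correction is mean-preserving per spot. With
#' \code{mode = "ratio"} the plain log-ratio \code{s - r} is used instead.
#'
#' @param channels quantile-normalized \code{channel_matrix}.
#' @param mode \code{"deviation"} (default) or \code{"ratio"}.
#' @return list of class \code{spot_matrix}: \code{values} (spots x
#'   arrays), \code{spot_info}, \code{array_ids}.
#' @export
reference_correct <- function(channels, mode = c("deviation", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(channels, "channel_matrix"))
  if (is.null(channels$reference) ||
      !identical(dim(channels$reference), dim(channels$sample))) {
    stop("every array must carry its reference channel", call. = FALSE)
  }
  values <- if (mode == "deviation") {
    channels$sample - (channels$reference - rowMeans(channels$reference))
  } else {
    channels$sample - channels$reference
  }
  structure(list(values = values, spot_info = channels$spot_info,
                 array_ids = channels$array_ids), class = "spot_matrix")
}

#' Collapse spots to genes
#'
#' Fourth step: spots annotated with an identical gene symbol are averaged
#' (arithmetic mean of corrected log values, per sample). Spots without a
#' symbol are dropped with a logged count.
#'
#' @param spot_matrix \code{spot_matrix} from [reference_correct()].
#' @param annotation optional probe-to-gene table overriding the symbols
#'   carried in the spot table.
#' @return genes x samples numeric matrix of natural-log expression with
#'   unique gene-symbol rownames (an \code{ExpressionMatrix}).
#' @export
collapse_genes <- function(spot_matrix, annotation = NULL) {
  stopifnot(inherits(spot_matrix, "spot_matrix"))
  info <- spot_matrix$spot_info
  symbols <- info$gene_symbol
  if (!is.null(annotation)) {
    idx <- match(info$probe_id, annotation$probe_id)
    symbols <- ifelse(is.na(idx), "", annotation$gene_symbol[idx])
  }
  regular <- info$spot_kind == "regular"
  keep <- regular & nzchar(symbols)
  n_drop <- sum(regular & !nzchar(symbols))
  if (n_drop > 0L) message("dropped ", n_drop, " unannotated spot(s)")
  if (sum(keep) == 0L) stop("no annotated regular spots to collapse", call. = FALSE)
  v <- spot_matrix$values[keep, , drop = FALSE]
  g <- symbols[keep]
  sums <- rowsum(v, g)              # sorted by group label
  counts <- as.integer(table(g)[rownames(sums)])
  out <- sums / counts
  colnames(out) <- spot_matrix$array_ids
  out
}

#' PCA quality control
#'
#' Covariance PCA on gene-centered log expression (genes already share a
#' common scale, so no per-gene scaling). Reports per-sample scores on the
#' first two principal components, the mean within-group distance to the
#' group centroid in that plane, and flags the most heterogeneous group.
#'
#' @param matrix genes x samples expression matrix (>= 3 samples).
#' @param design \code{study_design} covering the matrix columns.
#' @return list of class \code{pca_qc}: \code{scores} (sample_id, group,
#'   PC1, PC2), \code{dispersion} (group, mean_dist), \code{flagged},
#'   \code{var_explained}.
#' @export
pca_qc <- function(matrix, design) {
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 3L) stop("PCA QC needs >= 3 samples", call. = FALSE)
  missing_s <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing_s) > 0L) {
    stop("sample(s) absent from design: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  centered <- matrix - rowMeans(matrix)
  if (all(abs(centered) < 1e-12)) {
    warning("constant expression matrix: all PCA scores are zero")
    scores <- cbind(PC1 = numeric(ncol(matrix)), PC2 = numeric(ncol(matrix)))
    var_explained <- c(PC1 = 0, PC2 = 0)
  } else {
    pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
    k <- ncol(pc$x)
    scores <- cbind(PC1 = pc$x[, 1L],
                    PC2 = if (k >= 2L) pc$x[, 2L] else numeric(ncol(matrix)))
    tot <- sum(pc$sdev^2)
    var_explained <- c(PC1 = pc$sdev[1L]^2 / tot,
                       PC2 = if (k >= 2L) pc$sdev[2L]^2 / tot else 0)
  }
  group <- design$group[match(colnames(matrix), design$sample_id)]
  sc <- data.frame(sample_id = colnames(matrix), group = group,
                   PC1 = scores[, "PC1"], PC2 = scores[, "PC2"],
                   stringsAsFactors = FALSE, row.names = NULL)
  disp <- vapply(split(sc[, c("PC1", "PC2")], sc$group), function(d) {
    ctr <- colMeans(d)
    mean(sqrt((d$PC1 - ctr[[1L]])^2 + (d$PC2 - ctr[[2L]])^2))
  }, numeric(1))
  disp_df <- data.frame(group = names(disp), mean_dist = unname(disp),
                        stringsAsFactors = FALSE)
  flagged <- disp_df$group[which.max(disp_df$mean_dist)]
  structure(list(scores = sc, dispersion = disp_df, flagged = flagged,
                 var_explained = var_explained), class = "pca_qc")
}

#' Run the full four-step normalization
#'
#' \code{ln_transform} -> \code{drop_controls} -> \code{quantile_normalize}
#' -> \code{reference_correct} -> \code{collapse_genes}. The pipeline
#' default uses the invariant-anchored quantile map (see
#' [quantile_normalize()]) so that strong differential signal is not
#' compressed toward the pooled intensity distribution.
#'
#' @param spots \code{spot_table}.
#' @param annotation optional probe-to-gene table.
#' @param qn_anchor \code{"invariant"} (default) or \code{"all"}.
#' @param pool channel pooling for quantile normalization.
#' @param reference_mode \code{"deviation"} or \code{"ratio"}.
#' @return genes x samples natural-log expression matrix.
#' @export
normalize_arrays <- function(spots, annotation = NULL,
                             qn_anchor = c("invariant", "all"),
                             pool = c("all", "by-role"),
                             reference_mode = c("deviation", "ratio")) {
  qn_anchor <- match.arg(qn_anchor)
  ch <- ln_transform(spots)
  ch <- drop_controls(ch)
  ch <- quantile_normalize(ch, anchor = qn_anchor, pool = match.arg(pool))
  sm <- reference_correct(ch, mode = match.arg(reference_mode))
  collapse_genes(sm, annotation = annotation)
}
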