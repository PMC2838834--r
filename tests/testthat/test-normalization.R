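test_that("ln_transform replaces signals by natural logs, preserving order", {
  df <- spot_df("a1", paste0("s", 1:3), paste0("p", 1:3), c("A", "B", "C"),
                "regular", c(exp(1), exp(2), exp(3)), c(1, exp(2), exp(3)))
  ch <- ln_transform(as_spot_table(df))
  expect_equal(unname(ch$sample[, "a1"]), c(1, 2, 3))
  expect_equal(unname(ch$reference[, "a1"]), c(0, 2, 3))
  expect_equal(ch$spot_info$spot_id, paste0("s", 1:3))
})

test_that("classic quantile normalization matches the worked examples", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(quantile_normalize(m),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  same <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)

  # ties get the mean of the reference values over the ranks they span
  tied <- cbind(c(1, 1, 2), c(3, 4, 5))
  out <- quantile_normalize(tied)
  expect_equal(out[, 1], c(2.25, 2.25, 3.5))
  expect_equal(out[, 2], c(2.0, 2.5, 3.5))

  expect_error(quantile_normalize(cbind(c(1, 2, 3))), ">= 2 channels")
})

test_that("classic quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(rnorm(300), 50, 6)
    expect_equal(quantile_normalize(m),
                 limma::normalizeQuantiles(m, ties = TRUE),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("classic quantile normalization is idempotent with equal multisets", {
  set.seed(2)
  m <- matrix(rnorm(200, sd = 2), 40, 5)
  once <- quantile_normalize(m)
  expect_equal(quantile_normalize(once), once, tolerance = 1e-12)
  sorted <- apply(once, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
})

test_that("invariant-anchored normalization removes channel offsets exactly", {
  set.seed(3)
  base <- rnorm(200, 7, 1)
  shifts <- c(0.5, -0.3, 0.1, 0.0)
  m <- outer(base, shifts, `+`)
  # inject strong DE into channel 2 for 15 spots
  de_idx <- 1:15
  m[de_idx, 2] <- m[de_idx, 2] + log(4)
  out <- quantile_normalize(m, anchor = "invariant")
  # every channel is truth + the same global constant
  truth <- outer(base, rep(mean(shifts), 4), `+`)
  truth[de_idx, 2] <- truth[de_idx, 2] + log(4)
  expect_equal(out, truth, tolerance = 1e-9)
  # idempotent on this (noise-free) configuration
  expect_equal(quantile_normalize(out, anchor = "invariant"), out,
               tolerance = 1e-9)
})

test_that("invariant anchoring falls back to classic when anchors are scarce", {
  # only two consistent spots (< 3 required anchors): classic map is used
  m <- cbind(c(0, 0, 0), c(5, 5, 9))
  expect_warning(out <- quantile_normalize(m, anchor = "invariant"),
                 "falling back")
  expect_equal(out, quantile_normalize(m))
})

test_that("quantile_normalize on channel matrices requires controls removed", {
  sim <- simulate_experiment(small_config())
  ch <- ln_transform(sim$spots)
  expect_error(quantile_normalize(ch), "control spots")
  ch <- suppressMessages(drop_controls(ch))
  out <- quantile_normalize(ch, anchor = "invariant")
  expect_equal(dim(out$sample), dim(ch$sample))
  # by-role pooling normalizes the two roles separately
  out2 <- quantile_normalize(ch, anchor = "all", pool = "by-role")
  s_sorted <- apply(out2$sample, 2, sort)
  for (j in 2:ncol(s_sorted)) expect_equal(s_sorted[, j], s_sorted[, 1])
})

test_that("reference_correct applies the stated formula and is mean-preserving", {
  info <- data.frame(spot_id = "s1", probe_id = "p1", gene_symbol = "A",
                     spot_kind = "regular", stringsAsFactors = FALSE)
  ch <- structure(list(
    sample = matrix(c(10, 10), 1, 2, dimnames = list("s1", c("a1", "a2"))),
    reference = matrix(c(5, 7), 1, 2, dimnames = list("s1", c("a1", "a2"))),
    spot_info = info, array_ids = c("a1", "a2")), class = "channel_matrix")
  out <- reference_correct(ch)
  expect_equal(unname(out$values[1, ]), c(11, 9))

  # identical references leave the sample channel unchanged
  ch$reference[] <- c(6, 6)
  expect_equal(unname(reference_correct(ch)$values[1, ]), c(10, 10))

  # ratio mode is the plain log-ratio
  ch$reference[] <- c(5, 7)
  expect_equal(unname(reference_correct(ch, mode = "ratio")$values[1, ]),
               c(5, 3))

  # mean preservation on random instances, against the direct formula
  set.seed(5)
  for (i in 1:10) {
    s <- matrix(rnorm(40), 8, 5); r <- matrix(rnorm(40), 8, 5)
    dimnames(s) <- dimnames(r) <- list(paste0("s", 1:8), paste0("a", 1:5))
    chR <- structure(list(sample = s, reference = r,
                          spot_info = data.frame(spot_id = paste0("s", 1:8),
                                                 probe_id = paste0("p", 1:8),
                                                 gene_symbol = "g",
                                                 spot_kind = "regular"),
                          array_ids = paste0("a", 1:5)),
                     class = "channel_matrix")
    corrected <- reference_correct(chR)$values
    oracle <- s - (r - rowMeans(r))     # stated formula, recomputed
    expect_equal(corrected, oracle)
    expect_equal(rowMeans(corrected), rowMeans(s))
  }
})

test_that("collapse_genes averages spots per symbol and logs drops", {
  values <- matrix(c(1, 3, 5, 2, 7,
                     2, 4, 6, 4, 8), 5, 2,
                   dimnames = list(paste0("s", 1:5), c("a1", "a2")))
  info <- data.frame(spot_id = paste0("s", 1:5),
                     probe_id = paste0("p", 1:5),
                     gene_symbol = c("A", "A", "B", "B", ""),
                     spot_kind = "regular", stringsAsFactors = FALSE)
  sm <- structure(list(values = values, spot_info = info,
                       array_ids = c("a1", "a2")), class = "spot_matrix")
  expect_message(m <- collapse_genes(sm), "dropped 1")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["A", ], c(a1 = 2, a2 = 3))
  expect_equal(m["B", ], c(a1 = 3.5, a2 = 5))

  # single-spot genes pass through unchanged
  one <- sm; one$spot_info$gene_symbol <- c("A", "B", "C", "D", "E")
  expect_equal(unname(collapse_genes(one)["E", ]), unname(values[5, ]))

  none <- sm; none$spot_info$gene_symbol <- ""
  expect_error(suppressMessages(collapse_genes(none)), "no annotated")
})

test_that("an annotation table can override spot symbols", {
  sim <- simulate_experiment(default_config(n_genes = 400L))
  m1 <- suppressMessages(normalize_arrays(sim$spots))
  m2 <- suppressMessages(normalize_arrays(sim$spots,
                                          annotation = sim$annotation))
  expect_equal(m1, m2)
})

test_that("pca_qc scores, dispersion and edge cases", {
  d <- tiny_design(2L)
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), d$sample_id))
  m[, 2] <- m[, 1]                      # two identical samples
  qc <- pca_qc(m, d)
  expect_equal(qc$scores$PC1[1], qc$scores$PC1[2], tolerance = 1e-9)
  expect_equal(qc$scores$PC2[1], qc$scores$PC2[2], tolerance = 1e-9)
  expect_s3_class(qc$scores, "data.frame")

  zeros <- matrix(0, 5, 6, dimnames = dimnames(m))
  expect_warning(qc0 <- pca_qc(zeros, d), "constant")
  expect_true(all(qc0$scores$PC1 == 0))

  expect_error(pca_qc(m[, 1:2], d), ">= 3 samples")
  bad <- m; colnames(bad)[1] <- "stranger"
  expect_error(pca_qc(bad, d), "absent from design")
})

test_that("LPS groups are flagged as most heterogeneous in >= 90% of seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_experiment(default_config(n_genes = 500L, seed = 100L + s))
    m <- suppressMessages(normalize_arrays(sim$spots))
    qc <- pca_qc(m, sim$design)
    if (qc$flagged %in% c("LPS_PMN", "LPS_NOPMN")) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("noise-free pipeline reproduces true expression up to one constant", {
  sim <- simulate_experiment(noise_free_config(n_genes = 500L))
  m <- suppressMessages(normalize_arrays(sim$spots))
  truth <- sim$truth
  b <- truth$effects$baseline
  names(b) <- truth$effects$gene_symbol
  x_true <- vapply(seq_len(nrow(truth$animals)), function(i) {
    g <- truth$animals$group[i]
    eff <- switch(g, SHAM = 0, LPS_PMN = truth$effects$effect_lps_pmn,
                  LPS_NOPMN = truth$effects$effect_lps_nopmn)
    b + truth$animals$alpha[i] * eff
  }, numeric(length(b)))
  colnames(x_true) <- truth$animals$sample_id
  x_true <- x_true[rownames(m), colnames(m)]
  resid <- m - x_true
  expect_lt(max(abs(resid - resid[1, 1])), 1e-9)
})
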