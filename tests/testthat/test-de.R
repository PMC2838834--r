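make_matrix <- function(values, design) {
  # one gene per row of `values`, columns follow design$sample_id
  matrix(values, nrow = nrow(values), dimnames = list(rownames(values),
                                                      design$sample_id))
}

test_that("group_medians is robust and uses the even-n convention", {
  d <- tiny_design(3L)
  m <- matrix(0, 2, 9, dimnames = list(c("g1", "g2"), d$sample_id))
  m["g1", d$group == "SHAM"] <- c(1, 2, 100)
  med <- group_medians(m, d)
  expect_equal(med["g1", "SHAM"], 2)

  d2 <- tiny_design(2L)
  m2 <- matrix(0, 1, 6, dimnames = list("g", d2$sample_id))
  m2[1, d2$group == "SHAM"] <- c(1, 3)
  expect_equal(group_medians(m2, d2)["g", "SHAM"], 2)

  # single-sample group passes the value through
  d1 <- as_study_design(data.frame(
    sample_id = c("s1", "s2", "s3"),
    group = c("SHAM", "LPS_PMN", "LPS_NOPMN")))
  m1 <- matrix(c(5, 7, 9), 1, 3, dimnames = list("g", d1$sample_id))
  expect_equal(unname(group_medians(m1, d1)["g", ]), c(5, 7, 9))

  bad <- m; colnames(bad)[1] <- "stranger"
  expect_error(group_medians(bad, d), "absent from design")
})

test_that("contrast_fold_changes follows the log-median convention", {
  med <- cbind(SHAM = c(0, 1, 2), LPS_PMN = c(log(2), 1, 2 - log(2.6)),
               LPS_NOPMN = c(0, 1, 2))
  rownames(med) <- c("up2", "flat", "down26")
  ct <- contrast_fold_changes(med)
  expect_s3_class(ct, "contrast_table")
  expect_equal(fc_of(ct, "up2", "A"), 2)
  expect_equal(ct$direction[ct$gene_symbol == "up2" & ct$contrast == "A"], "up")
  expect_equal(fc_of(ct, "flat", "A"), 1)
  expect_equal(ct$direction[ct$gene_symbol == "flat" & ct$contrast == "A"], "none")
  expect_equal(fc_of(ct, "down26", "A"), 2.6)
  expect_equal(ct$direction[ct$gene_symbol == "down26" & ct$contrast == "A"],
               "down")
  expect_true(all(ct$fold_change >= 1))
})

test_that("antisymmetry: reversing group order negates log-ratios", {
  set.seed(6)
  med <- cbind(SHAM = rnorm(20), LPS_PMN = rnorm(20), LPS_NOPMN = rnorm(20))
  rownames(med) <- paste0("g", 1:20)
  ct <- contrast_fold_changes(med)
  swapped <- med[, c("LPS_PMN", "SHAM", "LPS_NOPMN")]
  colnames(swapped) <- c("SHAM", "LPS_PMN", "LPS_NOPMN")
  ct2 <- contrast_fold_changes(swapped, contrasts = "A")
  a <- ct[ct$contrast == "A", ]
  expect_equal(ct2$log_ratio, -a$log_ratio)
  expect_equal(ct2$fold_change, a$fold_change)
})

test_that("call_de applies the strict boundary and counts directions", {
  med <- cbind(SHAM = c(0, 0, 0), LPS_PMN = log(c(1.50, 1.51, 1 / 1.6)),
               LPS_NOPMN = c(0, 0, 0))
  rownames(med) <- c("atthr", "above", "below16")
  ct <- contrast_fold_changes(med)
  strict <- call_de(ct, threshold = 1.5, strict = TRUE)
  expect_false(strict$flags["atthr", "A"])
  expect_true(strict$flags["above", "A"])
  lax <- call_de(ct, threshold = 1.5, strict = FALSE)
  expect_true(lax$flags["atthr", "A"])
  cnt <- strict$counts[strict$counts$contrast == "A", ]
  expect_equal(c(cnt$n_de, cnt$n_up, cnt$n_down), c(2L, 1L, 1L))
  expect_error(call_de(ct, threshold = 1), "> 1")
})

test_that("call_de is monotone in the threshold", {
  set.seed(7)
  med <- cbind(SHAM = rnorm(100), LPS_PMN = rnorm(100), LPS_NOPMN = rnorm(100))
  rownames(med) <- paste0("g", 1:100)
  ct <- contrast_fold_changes(med)
  thresholds <- c(1.2, 1.5, 2, 3)
  flags <- lapply(thresholds, function(th) call_de(ct, threshold = th)$flags)
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(flags[[i]] <= flags[[i - 1]]))
  }
})

test_that("a 700-gene fixture reproduces the published contrast-A counts", {
  # 394 up and 120 down past 1.5-fold, 186 null: counts (514, 394, 120)
  n <- 700L
  lr <- c(seq(log(1.6), log(15), length.out = 394),
          -seq(log(1.6), log(2.6), length.out = 120),
          seq(-log(1.4), log(1.4), length.out = 186))
  med <- cbind(SHAM = numeric(n), LPS_PMN = lr, LPS_NOPMN = numeric(n))
  rownames(med) <- paste0("g", seq_len(n))
  calls <- call_de(contrast_fold_changes(med))
  cnt <- calls$counts[calls$counts$contrast == "A", ]
  expect_equal(c(cnt$n_de, cnt$n_up, cnt$n_down), c(514L, 394L, 120L))
})

test_that("venn_partition handles the worked set cases", {
  vp <- venn_partition(c("a"), c("b", "c"), c("d", "e", "f"))
  expect_equal(vp$union_count, 6L)
  expect_equal(unname(vp$counts[c("AB", "AC", "BC", "ABC")]),
               rep(0L, 4L))

  same <- c("x", "y", "z")
  vp2 <- venn_partition(same, same, same)
  expect_equal(vp2$union_count, 3L)
  expect_equal(unname(vp2$counts["ABC"]), 3L)
  expect_true(all(vp2$counts[names(vp2$counts) != "ABC"] == 0L))
})

test_that("venn region counts always sum to the union", {
  set.seed(8)
  universe <- paste0("g", 1:60)
  for (i in 1:20) {
    a <- sample(universe, sample(0:40, 1))
    b <- sample(universe, sample(0:40, 1))
    c_ <- sample(universe, sample(0:40, 1))
    vp <- venn_partition(a, b, c_)
    expect_equal(sum(vp$counts), vp$union_count)
    expect_equal(length(unique(unlist(vp$regions))),
                 length(unlist(vp$regions)))     # pairwise disjoint
    # |A| is recoverable from its four regions
    expect_equal(sum(vp$counts[c("A_only", "AB", "AC", "ABC")]),
                 length(unique(a)))
  }
})

test_that("venn_partition on logical flags demands one shared universe", {
  u <- paste0("g", 1:5)
  a <- setNames(c(TRUE, FALSE, TRUE, FALSE, FALSE), u)
  b <- setNames(c(FALSE, TRUE, TRUE, FALSE, FALSE), u)
  c_ <- setNames(c(FALSE, FALSE, FALSE, TRUE, FALSE), u)
  vp <- venn_partition(a, b, c_)
  expect_equal(vp$union_count, 4L)
  names(c_)[5] <- "other"
  expect_error(venn_partition(a, b, c_), "universe")
})

test_that("overlap_percentage uses half-up integer rounding", {
  x <- paste0("g", 1:360); y <- paste0("g", 1:265)
  expect_equal(overlap_percentage(x, y), 74L)          # 73.61 -> 74
  expect_equal(overlap_percentage(paste0("g", 1:107), paste0("g", 1:95)), 89L)
  expect_equal(overlap_percentage(c("a", "b"), c("a", "b", "c")), 100L)
  expect_equal(overlap_percentage(paste0("g", 1:8), "g1"), 13L)  # 12.5 -> 13
  expect_error(overlap_percentage(character(), "a"), "empty")
})

test_that("extreme_changes picks argmax per direction with lexicographic ties", {
  med <- cbind(SHAM = c(0, 0, 0, 0), LPS_PMN = c(log(3), log(3), -log(2), 0),
               LPS_NOPMN = c(0, 0, 0, 0))
  rownames(med) <- c("zeb", "alpha", "dn", "flat")
  ct <- contrast_fold_changes(med)
  ex <- extreme_changes(ct, "A")
  expect_equal(ex$up$gene_symbol, "alpha")   # tie at 3-fold: lexicographic
  expect_equal(ex$up$fold_change, 3)
  expect_equal(ex$down$gene_symbol, "dn")
  expect_equal(ex$down$fold_change, 2)

  flat_med <- matrix(0, 2, 3, dimnames = list(c("a", "b"), lung_groups()))
  flat <- contrast_fold_changes(flat_med)
  expect_null(extreme_changes(flat, "A")$up)
  expect_null(extreme_changes(flat, "A")$down)
})

test_that("cross_contrast_regression matches closed-form least squares", {
  med <- cbind(SHAM = numeric(5),
               LPS_PMN = c(0.0, 0.5, 1.0, 1.5, 2.0),
               LPS_NOPMN = c(0.1, 0.4, 0.5, 1.1, 1.2))
  rownames(med) <- paste0("g", 1:5)
  ct <- contrast_fold_changes(med)
  fit <- cross_contrast_regression(ct, paste0("g", 1:5))
  # frozen values from the closed-form normal equations on this instance
  expect_equal(fit$slope, 0.58, tolerance = 1e-12)
  expect_equal(fit$r, 0.970991818765, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.08, tolerance = 1e-12)

  # identical vectors: slope 1, r 1; y = 0.6 x: slope 0.6, r 1
  med2 <- cbind(SHAM = numeric(4), LPS_PMN = c(1, 2, 3, 4),
                LPS_NOPMN = c(1, 2, 3, 4))
  rownames(med2) <- paste0("g", 1:4)
  fit2 <- cross_contrast_regression(contrast_fold_changes(med2), paste0("g", 1:4))
  expect_equal(c(fit2$slope, fit2$r), c(1, 1))
  med2[, "LPS_NOPMN"] <- 0.6 * med2[, "LPS_PMN"]
  fit3 <- cross_contrast_regression(contrast_fold_changes(med2), paste0("g", 1:4))
  expect_equal(c(fit3$slope, fit3$r), c(0.6, 1))

  med2[, "LPS_PMN"] <- 1
  expect_error(cross_contrast_regression(contrast_fold_changes(med2),
                                         paste0("g", 1:4)), "zero variance")
})
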