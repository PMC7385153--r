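test_that("rank-sum test matches enumeration on small groups and handles identical inputs", {
  r <- ranksum_test(1:3, 4:6)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, oracle_ranksum_exact(1:3, 4:6))
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(8)
  for (i in 1:10) {
    x <- runif(sample(3:6, 1)); y <- runif(sample(3:6, 1))
    expect_equal(ranksum_test(x, y)$p_value, oracle_ranksum_exact(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("a clearly shifted distribution is detected at n = 50", {
  set.seed(42)
  hits <- 0L
  for (i in 1:50) {
    p <- ranksum_test(rnorm(50), rnorm(50, 2))$p_value
    if (p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})

test_that("one-vs-rest isolates the shifted group and demands three labels", {
  set.seed(31)
  groups <- rep(c("a", "b", "c"), each = 30)
  values <- c(rnorm(30, 3), rnorm(30), rnorm(30))
  res <- one_vs_rest(groups, values)
  expect_lt(res$p_value[res$label == "a"], 1e-6)
  expect_gt(min(res$p_value[res$label != "a"]), 1e-6)
  expect_error(one_vs_rest(rep(c("a", "b"), 5), rnorm(10)), "3 groups")
})

test_that("BH adjustment matches the literal step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the vectorized rank-sum used for expression matrices matches wilcox.test", {
  set.seed(9)
  mat <- matrix(rnorm(30 * 20), 30, 20)
  mat[3, ] <- round(mat[3, ])  # introduce ties on one gene
  p_fast <- hrdpipe:::.ranksum_rows(mat, 1:8, 9:20)
  p_ref <- apply(mat, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[1:8], v[9:20], exact = FALSE,
                                        correct = TRUE)$p.value))
  expect_equal(p_fast, unname(p_ref), tolerance = 1e-12)
})

test_that("DEG selection finds planted shifts and nothing among duplicated groups", {
  set.seed(23)
  n1 <- 15; n2 <- 15
  genes <- c(sprintf("UP%02d", 1:10), sprintf("NULL%03d", 1:200))
  expr <- matrix(2^rnorm(length(genes) * (n1 + n2), 3, 0.5),
                 length(genes), n1 + n2,
                 dimnames = list(genes, sprintf("s%02d", 1:(n1 + n2))))
  expr[1:10, (n1 + 1):(n1 + n2)] <- expr[1:10, (n1 + 1):(n1 + n2)] * 2^2
  res <- select_degs(expr, colnames(expr)[1:n1],
                     colnames(expr)[(n1 + 1):(n1 + n2)])
  expect_gte(sum(res$selected & startsWith(res$gene, "UP")), 9L)
  expect_equal(sum(res$selected & startsWith(res$gene, "NULL")), 0L)

  dup <- cbind(expr[, 1:n1], expr[, 1:n1])
  colnames(dup) <- sprintf("d%02d", 1:(2 * n1))
  res_dup <- select_degs(dup, colnames(dup)[1:n1],
                         colnames(dup)[(n1 + 1):(2 * n1)])
  expect_equal(sum(res_dup$selected), 0L)
  expect_error(select_degs(expr, colnames(expr)[1:5], colnames(expr)[5:8]),
               "overlap")
})

test_that("degenerate fold changes are excluded from selection and logged", {
  expr <- matrix(c(0, 0, 0, 5, 5, 5,
                   1, 1, 1, 2, 2, 2,
                   0, 0, 0, 0, 0, 0), 3, 6, byrow = TRUE,
                 dimnames = list(c("g_zero1", "g_ok", "g_zero_both"),
                                 sprintf("s%d", 1:6)))
  msgs <- capture_messages(
    res <- select_degs(expr, sprintf("s%d", 1:3), sprintf("s%d", 4:6)))
  expect_true(any(grepl("zero mean in both", msgs)))
  expect_true(any(grepl("fold-change ranking", msgs)))
  expect_false("g_zero_both" %in% res$gene)
  expect_true(res$degenerate_fc[res$gene == "g_zero1"])
  expect_false(res$selected[res$gene == "g_zero1"])
})

test_that("IFN-gamma score averages available genes on the log scale", {
  genes <- c("IDO1", "CXCL10", "CXCL9", "HLA-DRA", "STAT1", "IFNG")
  expr <- matrix(3, 6, 2, dimnames = list(genes, c("s1", "s2")))
  expr[, 2] <- 6
  sc <- ifng_signature(expr)
  expect_equal(unname(sc), c(log2(4), log2(7)))
  expect_lt(sc["s1"], sc["s2"])
  expect_warning(sc5 <- ifng_signature(expr[1:5, ]), "missing")
  expect_equal(unname(sc5["s1"]), log2(4))
  expect_error(ifng_signature(expr[0, , drop = FALSE]), "none")
  raw <- ifng_signature(expr, log_scale = FALSE)
  expect_equal(unname(raw), c(3, 6))
})

test_that("Tukey fences flag exactly the points outside 1.5 IQR", {
  res <- tukey_outliers(c(1, 2, 3, 4, 100))
  expect_equal(res$outlier_idx, 5L)
  expect_equal(res$kept, c(1, 2, 3, 4))
  expect_equal(res$summary$Q1, 2)
  expect_equal(res$summary$Q3, 4)
  expect_equal(res$summary$upper_fence, 7)
  same <- tukey_outliers(rep(5, 6))
  expect_equal(length(same$outlier_idx), 0L)
  sym <- tukey_outliers(c(-2, -1, 0, 1, 2))
  expect_equal(sym$kept, c(-2, -1, 0, 1, 2))
  set.seed(4)
  v <- rnorm(50)
  perm <- sample(v)
  expect_equal(tukey_outliers(v)$summary, tukey_outliers(perm)$summary)
  expect_error(tukey_outliers(1:3), "n >= 4")
})

test_that("burden-activity fit is exact on collinear data and errors on empty subsets", {
  act <- seq(0.5, 1, length.out = 20)
  fit <- suppressWarnings(burden_activity_fit(2 * act + 1, act))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$n_used, 20L)
  expect_error(burden_activity_fit(rnorm(10), rep(0.2, 10)), "activity")
  set.seed(66)
  ok <- 0L
  for (i in 1:30) {
    a <- runif(200, 0, 1)
    b <- 2 * a + rnorm(200, 0, 0.1)
    f <- burden_activity_fit(b, a)
    if (f$slope > 1.8 && f$slope < 2.2) ok <- ok + 1L
  }
  expect_gte(ok, 29L)
})
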