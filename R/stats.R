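## Group-comparison statistics: rank-sum tests (pairwise and
## one-vs-rest), BH-FDR, differential expression selection, the IFN-gamma
## six-gene score, Tukey outlier handling, and the burden-vs-activity
## linear fit.

#' Two-sided Wilcoxon rank-sum test
#'
#' Wraps the standard rank-sum test with an explicit exact/approximate
#' policy: exact when both groups are at or below `exact_limit` and
#' tie-free, otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_limit maximum per-group size for the exact null.
#' @return list with `statistic` (rank-sum W) and `p_value`.
#' @export
ranksum_test <- function(x, y, exact_limit = 50L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_data("ranksum_test: both groups must be non-empty")
  }
  use_exact <- length(x) <= exact_limit && length(y) <= exact_limit &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' One-vs-rest rank-sum tests over three or more groups
#'
#' For each group label, tests that group against all remaining samples.
#'
#' @param groups label per sample.
#' @param values numeric vector matched to `groups`.
#' @return data.frame with `label`, `n`, `p_value` (one row per label).
#' @export
one_vs_rest <- function(groups, values) {
  if (length(groups) != length(values)) {
    stop_data("groups and values differ in length")
  }
  labels <- unique(groups)
  if (length(labels) < 3L) {
    stop_data("one_vs_rest needs >= 3 groups; use ranksum_test for two")
  }
  out <- lapply(labels, function(lb) {
    inx <- groups == lb
    if (sum(inx) < 1L || sum(!inx) < 1L) {
      warning(sprintf("one_vs_rest: label '%s' has an empty side; skipped", lb))
      return(NULL)
    }
    data.frame(label = lb, n = sum(inx),
               p_value = ranksum_test(values[inx], values[!inx])$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_data("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# vectorized tie-corrected normal-approximation rank-sum p-values for
# every row of a matrix (columns idx1 vs idx2); matches
# wilcox.test(exact = FALSE, correct = TRUE)
.ranksum_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  sub <- mat[, c(idx1, idx2), drop = FALSE]
  p <- numeric(nrow(sub))
  mu <- n1 * n2 / 2
  for (g in seq_len(nrow(sub))) {
    r <- rank(sub[g, ])
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(sub[g, ])
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) { p[g] <- 1; next }
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma
    p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}

#' Differential expression between two sample groups
#'
#' Per-gene fold change of group means, rank-sum p-value, BH adjustment
#' across all tested genes, and selection by `|log2 FC| > fc_cut` with
#' adjusted p below `q_cut` (strict). Genes with zero mean in both groups
#' are dropped; genes with zero mean in exactly one group have an
#' infinite fold change, are never selected, and are flagged
#' `degenerate_fc`.
#'
#' @param expr genes x samples matrix (FPKM).
#' @param group1,group2 disjoint non-empty character vectors of sample
#'   ids (fold change is group2 over group1).
#' @param fc_cut absolute log2 fold-change threshold (strict `>`).
#' @param q_cut adjusted-p threshold (strict `<`).
#' @param select when `FALSE`, reports statistics without applying the
#'   selection rule (all `selected` are `NA`).
#' @return data.frame with `gene`, `mean_fpkm_group1`, `mean_fpkm_group2`,
#'   `log2fc`, `p_value`, `adj_p`, `degenerate_fc`, `selected`.
#' @export
select_degs <- function(expr, group1, group2, fc_cut = 1.5, q_cut = 0.05,
                        select = TRUE) {
  if (length(intersect(group1, group2)) > 0L) {
    stop_data("groups overlap")
  }
  if (length(group1) == 0L || length(group2) == 0L) {
    stop_data("both groups must be non-empty")
  }
  missing <- setdiff(c(group1, group2), colnames(expr))
  if (length(missing) > 0L) {
    stop_data("samples not in expression matrix: %s",
              paste(missing, collapse = ", "))
  }
  m1 <- rowMeans(expr[, group1, drop = FALSE])
  m2 <- rowMeans(expr[, group2, drop = FALSE])
  both_zero <- m1 == 0 & m2 == 0
  if (any(both_zero)) {
    message(sprintf("select_degs: dropped %d gene(s) with zero mean in both groups",
                    sum(both_zero)))
  }
  keep <- !both_zero
  lfc <- log2(m2[keep] / m1[keep])
  degenerate <- !is.finite(lfc)
  if (any(degenerate)) {
    message(sprintf("select_degs: %d gene(s) with a zero mean in one group excluded from fold-change ranking",
                    sum(degenerate)))
  }
  idx1 <- match(group1, colnames(expr))
  idx2 <- match(group2, colnames(expr))
  p <- .ranksum_rows(expr[keep, , drop = FALSE], idx1, idx2)
  adj <- bh_adjust(p)
  sel <- if (select) {
    abs(lfc) > fc_cut & adj < q_cut & !degenerate
  } else {
    rep(NA, sum(keep))
  }
  data.frame(gene = rownames(expr)[keep],
             mean_fpkm_group1 = unname(m1[keep]),
             mean_fpkm_group2 = unname(m2[keep]),
             log2fc = unname(lfc), p_value = p, adj_p = adj,
             degenerate_fc = unname(degenerate), selected = sel,
             stringsAsFactors = FALSE, row.names = NULL)
}

.ifng_genes <- c("IDO1", "CXCL10", "CXCL9", "HLA-DRA", "STAT1", "IFNG")

#' IFN-gamma six-gene signature score
#'
#' Per-sample mean expression of the six immune genes IDO1, CXCL10,
#' CXCL9, HLA-DRA, STAT1 and IFNG, on the `log2(FPKM + 1)` scale by
#' default. Missing genes are dropped with a warning; at least one must
#' be present.
#'
#' @param expr genes x samples FPKM matrix.
#' @param genes signature gene set.
#' @param log_scale take `log2(FPKM + 1)` before averaging (default);
#'   `FALSE` averages raw FPKM.
#' @return named numeric vector of per-sample scores.
#' @export
ifng_signature <- function(expr, genes = .ifng_genes, log_scale = TRUE) {
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L) {
    stop_data("none of the signature genes are present in the expression matrix")
  }
  if (length(present) < length(genes)) {
    warning(sprintf("ifng_signature: missing gene(s) %s; using %d of %d",
                    paste(setdiff(genes, present), collapse = ", "),
                    length(present), length(genes)))
  }
  x <- expr[present, , drop = FALSE]
  if (log_scale) x <- log2(x + 1)
  colMeans(x)
}

#' Tukey fences and outlier removal
#'
#' Quartiles by linear interpolation of order statistics; values strictly
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are outliers.
#'
#' @param values numeric vector, `n >= 4`.
#' @return list with `kept` (values inside the fences), `outlier_idx`
#'   (indices into `values`) and `summary` (Q1, Q2, Q3, IQR,
#'   lower_fence, upper_fence).
#' @export
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))
tukey_outliers <- function(values) {
  if (length(values) < 4L) stop_data("tukey_outliers needs n >= 4")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[3] + 1.5 * iqr
  out <- which(values < lower | values > upper)
  list(kept = if (length(out)) values[-out] else values,
       outlier_idx = out,
       summary = data.frame(Q1 = q[1], Q2 = q[2], Q3 = q[3], IQR = iqr,
                            lower_fence = lower, upper_fence = upper))
}

#' Linear fit of mutation burden on signature activity
#'
#' Restricts to samples with activity at or above `activity_floor`,
#' removes burden outliers by the Tukey rule, then fits ordinary least
#' squares of burden on activity, reporting the coefficient of
#' determination and the model F-test p-value.
#'
#' @param burden per-sample mutation burden.
#' @param activity matched per-sample signature activity.
#' @param activity_floor inclusive activity threshold (default 0.5).
#' @return list with `r_squared`, `p_value`, `slope`, `intercept`,
#'   `n_used`.
#' @export
burden_activity_fit <- function(burden, activity, activity_floor = 0.5) {
  if (length(burden) != length(activity)) {
    stop_data("burden and activity differ in length")
  }
  keep <- !is.na(activity) & activity >= activity_floor & !is.na(burden)
  if (sum(keep) < 4L) {
    stop_data("fewer than 4 samples at activity >= %.2f", activity_floor)
  }
  b <- burden[keep]; a <- activity[keep]
  tk <- tukey_outliers(b)
  if (length(tk$outlier_idx) > 0L) {
    b <- b[-tk$outlier_idx]; a <- a[-tk$outlier_idx]
  }
  if (length(b) < 3L) stop_data("fewer than 3 samples after outlier removal")
  fit <- stats::lm(b ~ a)
  sm <- summary(fit)
  pv <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  }
  list(r_squared = sm$r.squared, p_value = pv,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n_used = length(b))
}
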