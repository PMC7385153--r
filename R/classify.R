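## HRD classification by top-quantile or fixed cutoff, and ROC analysis
## of HRD predictors against germline BRCA status. Convention: a higher
## score predicts the positive class (more HRD / more likely mutated).

#' Classify HRD tumors by top score quantile
#'
#' The realized threshold is the smallest score such that the fraction of
#' samples at or above it does not exceed `q`; tied scores are always
#' classified together (a tie group at the boundary is kept whole, so the
#' realized fraction can fall below `q` but never splits equal scores).
#'
#' @param scores named numeric vector of HRD scores (no missing values).
#' @param q top fraction to classify as HRD (default 0.10).
#' @return data.frame with `sample`, `hrd_score`, `cohort_quantile`,
#'   `is_hrd_top`, `rule`, and the realized `threshold`.
#' @export
classify_by_quantile <- function(scores, q = 0.10) {
  if (length(scores) == 0L) stop_data("no scores supplied")
  if (anyNA(scores)) stop_data("scores contain missing values")
  n <- length(scores)
  cand <- sort(unique(scores), decreasing = TRUE)
  frac <- vapply(cand, function(t) mean(scores >= t), numeric(1))
  ok <- which(frac <= q)
  threshold <- if (length(ok) > 0L) cand[max(ok)] else Inf
  is_top <- scores >= threshold
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(sample = ids, hrd_score = unname(scores),
             cohort_quantile = unname(rank(scores) / n),
             is_hrd_top = unname(is_top),
             rule = sprintf("top_quantile %.2f", q),
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Classify HRD tumors by a fixed score cutoff
#'
#' @param scores named numeric vector of HRD scores.
#' @param cutoff inclusive threshold (default 57: scores >= 57 are HRD).
#' @return data.frame as in [classify_by_quantile()].
#' @export
#' @examples
#' classify_by_cutoff(c(a = 57, b = 56))
classify_by_cutoff <- function(scores, cutoff = 57) {
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  n <- length(scores)
  data.frame(sample = ids, hrd_score = unname(scores),
             cohort_quantile = if (n) unname(rank(scores) / n) else numeric(0),
             is_hrd_top = unname(scores >= cutoff),
             rule = rep(sprintf("fixed_cutoff %s", cutoff), n),
             threshold = rep(cutoff, n),
             stringsAsFactors = FALSE)
}

#' ROC curve, AUC and best sensitivity+specificity cutoff
#'
#' Evaluates every unique score as a threshold (score >= threshold
#' predicts positive), plus sentinels predicting all-positive and
#' all-negative. AUC is computed by the trapezoidal rule over the
#' resulting curve. The best cutoff maximizes sensitivity + specificity;
#' ties go to the lowest threshold (favouring sensitivity), with a
#' message.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary labels (logical, or 0/1) matched to `scores`.
#' @return an `roc_result`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `best_cutoff`, `best_sens`, `best_spec`,
#'   `youden_sum`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_data("scores and labels differ in length")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_data("roc_curve needs both classes present")
  }
  finite_thr <- sort(unique(scores))
  thresholds <- c(-Inf, finite_thr, Inf)
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & !labels) / n_neg,
                 numeric(1))
  # trapezoid over (FPR, TPR), ordered by increasing FPR
  fpr <- 1 - spec; tpr <- sens
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  sums <- sens + spec
  finite_idx <- which(is.finite(thresholds))
  best_i <- finite_idx[which.max(sums[finite_idx])]
  best_sum <- sums[best_i]
  tied <- finite_idx[abs(sums[finite_idx] - best_sum) < 1e-12]
  if (length(tied) > 1L) {
    best_i <- min(tied)
    message(sprintf("roc_curve: %d thresholds tie at sensitivity+specificity = %.4f; reporting the lowest",
                    length(tied), best_sum))
  }
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 best_cutoff = thresholds[best_i],
                 best_sens = sens[best_i], best_spec = spec[best_i],
                 youden_sum = sens[best_i] + spec[best_i],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d pos / %d neg); best cutoff %s (sens %.3f, spec %.3f, sum %.3f)\n",
              x$auc, x$n_pos, x$n_neg, format(x$best_cutoff), x$best_sens,
              x$best_spec, x$youden_sum))
  invisible(x)
}

#' ROC comparison across several predictors
#'
#' Computes [roc_curve()] for each predictor on the common set of samples
#' where every compared quantity and the label are non-missing.
#'
#' @param predictor_map named list of named numeric score vectors.
#' @param labels named binary label vector.
#' @return named list of `roc_result` objects (one per predictor), with
#'   attribute `n_common` (size of the shared sample set).
#' @export
compare_predictors <- function(predictor_map, labels) {
  if (length(predictor_map) == 0L) stop_data("no predictors supplied")
  ids <- names(labels)
  for (p in predictor_map) ids <- intersect(ids, names(p)[!is.na(p)])
  ids <- ids[!is.na(labels[ids])]
  if (length(ids) == 0L) {
    stop_data("no samples shared by all predictors and labels")
  }
  out <- lapply(predictor_map, function(p) roc_curve(p[ids], labels[ids]))
  attr(out, "n_common") <- length(ids)
  out
}
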