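## De novo signature extraction (consensus KL-NMF over restarts),
## NNLS refitting against a reference set, and cosine-similarity naming.

#' Cosine similarity between two non-negative vectors
#'
#' @param u,v numeric vectors of equal length, non-negative, non-zero.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_data("vectors differ in length")
  if (any(u < 0) || any(v < 0)) stop_data("vectors must be non-negative")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_data("cosine similarity undefined for a zero vector")
  min(1, sum(u * v) / (nu * nv))
}

# all-pairs cosine matrix between rows of A (a x p) and rows of B (b x p)
.cosine_rows <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  pmin(An %*% t(Bn), 1)
}

# One KL-NMF fit with multiplicative updates and automatic relevance
# determination: each component carries a relevance weight updated from
# its total W/H mass, whose inverse enters the update denominators as an
# adaptive penalty; irrelevant (duplicated or unsupported) components are
# driven to zero and pruned. Components are dropped during fitting when
# their share of attributed activity falls below 0.1%; the converged
# component count keeps shares >= `prune_share`. V is 96 x n (counts);
# returns W (96 x k', columns normalized to sum 1) and H (k' x n) with
# the scale absorbed into H.
.nmf_kl_fit <- function(V, k, seed, max_iter = 2000L, tol = 1e-8,
                        prune_share = 0.01, ard_shape = 10) {
  eps <- .Machine$double.eps
  M <- nrow(V); N <- ncol(V)
  init <- with_seed(seed, {
    sc <- sqrt(mean(V) / k)
    list(W = matrix(stats::runif(M * k, 0.5, 1.5) * sc, M, k),
         H = matrix(stats::runif(k * N, 0.5, 1.5) * sc, k, N))
  })
  W <- init$W; H <- init$H
  a <- ard_shape
  b <- sqrt((a - 1) * (a - 2) * mean(V) / k)
  relevance_norm <- M + N + a + 1
  dev_prev <- Inf
  for (it in seq_len(max_iter)) {
    lam <- relevance_norm / (colSums(W) + rowSums(H) + b)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) /
      (matrix(rowSums(H) + lam, M, ncol(W), byrow = TRUE) + eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) + lam + eps)
    if (it %% 25L == 0L || it == max_iter) {
      act <- colSums(W) * rowSums(H)
      keep <- act / (sum(act) + eps) >= 1e-3
      if (!any(keep)) keep[which.max(act)] <- TRUE
      if (!all(keep)) {
        W <- W[, keep, drop = FALSE]
        H <- H[keep, , drop = FALSE]
      }
      WH <- W %*% H + eps
      dev <- sum(V * log((V + eps) / WH) - V + WH)
      if (it > 200L && is.finite(dev_prev) &&
          abs(dev_prev - dev) < tol * abs(dev_prev)) break
      dev_prev <- dev
    }
  }
  act <- colSums(W) * rowSums(H)
  sel <- act / sum(act) >= prune_share
  if (!any(sel)) sel[which.max(act)] <- TRUE
  W <- W[, sel, drop = FALSE]
  H <- H[sel, , drop = FALSE]
  s <- colSums(W)
  list(W = sweep(W, 2, s, "/"), H = H * s, k = ncol(W))
}

# greedy cosine matching of profile rows in `mat` to rows of `template`;
# returns the permutation of mat rows aligned to template rows
.match_profiles <- function(template, mat) {
  sim <- .cosine_rows(template, mat)
  k <- nrow(template)
  assign <- integer(k)
  for (step in seq_len(k)) {
    idx <- arrayInd(which.max(sim), dim(sim))
    assign[idx[1]] <- idx[2]
    sim[idx[1], ] <- -Inf
    sim[, idx[2]] <- -Inf
  }
  assign
}

#' De novo signature extraction by consensus NMF over random restarts
#'
#' Runs `n_restarts` randomly initialized KL-divergence NMF fits starting
#' from `k_max` components, each with automatic relevance determination:
#' duplicated or unsupported components are driven to zero during fitting
#' and components ending below a `prune_share` share of total activity are
#' dropped. Each restart votes for the component count it converged to;
#' the chosen count is the modal vote, which must reach `quorum` of
#' restarts. The consensus profiles are the per-signature centroids
#' (after cosine matching) of the restarts voting for the chosen count.
#'
#' @param catalog a `trinuc_catalog`.
#' @param n_restarts number of random restarts (default 50).
#' @param k_max number of components each restart starts from.
#' @param seed integer seed; restarts use derived sub-seeds.
#' @param quorum minimum fraction of restarts the modal count must win.
#' @param prune_share floor on a converged component's share of total
#'   activity.
#' @param ard_shape shape hyperparameter of the relevance prior.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @return an `extraction_report`: list with `n_restarts`,
#'   `signature_count_votes`, `chosen_k`, `vote_fraction`,
#'   `consensus_profiles` (k x 96 matrix, rows `W1`...), `exposures`
#'   (an `exposure_table` refit of the catalog on the consensus profiles)
#'   and `singleton_flags` (see [flag_singleton_signature()]).
#' @export
extract_signatures <- function(catalog, n_restarts = 50L, k_max = 10L,
                               seed = 1L, quorum = 0.6, prune_share = 0.01,
                               ard_shape = 10, max_iter = 2000L) {
  stopifnot(inherits(catalog, "trinuc_catalog"))
  if (length(catalog$samples) == 0L || sum(catalog$counts) == 0) {
    stop_data("catalog is empty; nothing to extract")
  }
  V <- t(catalog$counts)  # 96 x n
  fits <- lapply(seq_len(n_restarts), function(r) {
    .nmf_kl_fit(V, k_max, seed = derive_seed(seed, r),
                max_iter = max_iter, prune_share = prune_share,
                ard_shape = ard_shape)
  })
  ks <- vapply(fits, `[[`, integer(1), "k")
  votes <- table(ks)
  chosen_k <- as.integer(names(votes)[which.max(votes)])
  vote_n <- max(votes)
  if (vote_n < quorum * n_restarts) {
    stop_data(paste0("no stable signature count: modal k = %d won %d/%d ",
                     "restarts (quorum %.0f%%); votes: %s"),
              chosen_k, vote_n, n_restarts, 100 * quorum,
              paste(sprintf("k=%s:%d", names(votes), as.integer(votes)),
                    collapse = ", "))
  }
  winners <- fits[ks == chosen_k]
  template <- t(winners[[1]]$W)  # k x 96
  acc <- template
  for (f in winners[-1]) {
    prof <- t(f$W)
    acc <- acc + prof[.match_profiles(template, prof), , drop = FALSE]
  }
  consensus <- acc / rowSums(acc)
  rownames(consensus) <- paste0("W", seq_len(chosen_k))
  colnames(consensus) <- catalog$context_order
  exposures <- refit_exposures(catalog, consensus, floor = 0)
  # dominance is judged on absolute attributed activity (mutations), not
  # per-sample fractions: an ultra-mutated tumor dominates a signature by
  # carrying most of its mutations cohort-wide
  absolute <- exposures$activities * rowSums(catalog$counts)
  report <- structure(
    list(n_restarts = n_restarts,
         signature_count_votes = votes,
         chosen_k = chosen_k,
         vote_fraction = vote_n / n_restarts,
         consensus_profiles = consensus,
         exposures = exposures,
         singleton_flags = flag_singleton_signature(absolute)),
    class = "extraction_report")
  report
}

#' @export
print.extraction_report <- function(x, ...) {
  cat(sprintf("extraction_report: chosen k = %d (%.0f%% of %d restarts)\n",
              x$chosen_k, 100 * x$vote_fraction, x$n_restarts))
  if (nrow(x$singleton_flags) > 0L) {
    cat(sprintf("  singleton flag: %s dominated by %s (%.0f%%)\n",
                x$singleton_flags$signature, x$singleton_flags$sample,
                100 * x$singleton_flags$fraction))
  }
  invisible(x)
}

#' Flag signatures dominated by a single sample
#'
#' A signature is a singleton when one sample contributes at least
#' `threshold_fraction` of its total activity — the hallmark of a
#' component created by a single ultra-mutated tumor. The pipeline
#' contract is to exclude the dominant sample and re-run extraction.
#'
#' @param exposures an `exposure_table` or a samples x k activity matrix.
#' @param threshold_fraction inclusive dominance threshold (default 0.5).
#' @return data.frame with columns `signature`, `sample`, `fraction`
#'   (zero rows when nothing is flagged).
#' @export
flag_singleton_signature <- function(exposures, threshold_fraction = 0.5) {
  act <- if (inherits(exposures, "exposure_table")) exposures$activities
         else as.matrix(exposures)
  flags <- lapply(colnames(act), function(sig) {
    tot <- sum(act[, sig])
    if (tot <= 0) return(NULL)
    i <- which.max(act[, sig])
    frac <- act[i, sig] / tot
    if (frac >= threshold_fraction) {
      data.frame(signature = sig, sample = rownames(act)[i],
                 fraction = frac, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, flags)
  if (is.null(out)) {
    out <- data.frame(signature = character(), sample = character(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Refit per-sample signature exposures by non-negative least squares
#'
#' Each sample's 96-count vector, normalized to frequencies, is projected
#' onto the reference profiles by NNLS. Contributions below `floor` (on
#' the normalized scale) are zeroed and the remainder renormalized — small
#' fitted contributions are not considered interpretable. The cosine
#' between each observed frequency vector and its reconstruction is
#' reported as a fit diagnostic.
#'
#' @param catalog a `trinuc_catalog`.
#' @param reference_signatures k x 96 matrix of reference profiles (rows
#'   sum to 1).
#' @param floor reporting floor on normalized exposures (default 0.06).
#' @return an `exposure_table`: list with `samples`, `activities`
#'   (samples x k, floored and renormalized), `raw_activities` (unfloored
#'   NNLS solution, normalized), `first_signature`, `recon_cosine` and
#'   `zero_samples` (ids of zero-mutation samples).
#' @export
refit_exposures <- function(catalog, reference_signatures, floor = 0.06) {
  stopifnot(inherits(catalog, "trinuc_catalog"))
  ref <- as.matrix(reference_signatures)
  if (ncol(ref) != 96L) stop_data("reference must have 96 context columns")
  if (any(abs(rowSums(ref) - 1) > 1e-6)) {
    stop_data("reference profiles must each sum to 1")
  }
  k <- nrow(ref)
  signames <- rownames(ref)
  if (is.null(signames)) signames <- paste0("S", seq_len(k))
  C <- t(ref)  # 96 x k
  n <- length(catalog$samples)
  raw <- matrix(0, n, k, dimnames = list(catalog$samples, signames))
  recon_cos <- rep(NA_real_, n)
  zero_samples <- character()
  for (i in seq_len(n)) {
    v <- catalog$counts[i, ]
    tot <- sum(v)
    if (tot == 0) {
      zero_samples <- c(zero_samples, catalog$samples[i])
      next
    }
    f <- v / tot
    fit <- pracma::lsqnonneg(C, f)
    raw[i, ] <- fit$x
    rec <- as.vector(C %*% fit$x)
    if (sum(rec) > 0) recon_cos[i] <- cosine_similarity(f, rec)
  }
  if (length(zero_samples) > 0L) {
    warning(sprintf("refit_exposures: %d zero-mutation sample(s) have zero exposures",
                    length(zero_samples)))
  }
  norm_raw <- raw
  rs <- rowSums(norm_raw)
  norm_raw[rs > 0, ] <- norm_raw[rs > 0, , drop = FALSE] / rs[rs > 0]
  act <- norm_raw
  act[act < floor] <- 0
  rs2 <- rowSums(act)
  act[rs2 > 0, ] <- act[rs2 > 0, , drop = FALSE] / rs2[rs2 > 0]
  structure(list(samples = catalog$samples,
                 activities = act,
                 raw_activities = norm_raw,
                 first_signature = assign_first_signature(act),
                 recon_cosine = stats::setNames(recon_cos, catalog$samples),
                 zero_samples = zero_samples),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("exposure_table: %d sample(s) x %d signature(s)\n",
              length(x$samples), ncol(x$activities)))
  print(table(x$first_signature))
  invisible(x)
}

#' Dominant signature per sample
#'
#' @param exposures an `exposure_table` or samples x k activity matrix.
#' @return character vector of signature names (argmax of normalized
#'   activity). Exact ties go to the lexicographically first signature
#'   name with a warning; all-zero rows are labelled `"unassigned"`.
#' @export
assign_first_signature <- function(exposures) {
  act <- if (inherits(exposures, "exposure_table")) exposures$activities
         else as.matrix(exposures)
  signames <- colnames(act)
  ties <- 0L
  labels <- apply(act, 1, function(row) {
    if (all(row == 0)) return("unassigned")
    top <- which(row == max(row))
    if (length(top) > 1L) {
      ties <<- ties + 1L
      sort(signames[top])[1]
    } else {
      signames[top]
    }
  })
  if (ties > 0L) {
    warning(sprintf("assign_first_signature: %d tie(s) resolved to the %s",
                    ties, "lexicographically first signature"))
  }
  unname(labels)
}

#' Name extracted signatures by cosine similarity to a reference set
#'
#' Computes cosines between each extracted profile and every reference
#' profile. The label is the best match's id (with its etiology when
#' known); when the two best matches form a configured mergeable pair
#' (by default the two APOBEC ids, COSMIC 2 and 13) and both exceed
#' `report_floor`, a combined label carrying both similarities is emitted.
#'
#' @param extracted k x 96 matrix of extracted profiles.
#' @param cosmic reference matrix (default [synthetic_cosmic_v2()]).
#' @param merged_pairs list of length-2 character vectors of reference ids
#'   that may be reported jointly.
#' @param report_floor minimum cosine for label promotion (default 0.8).
#' @return data.frame with `extracted_name`, `best_cosmic`, `best_cosine`,
#'   `second_cosmic`, `second_cosine`, `assigned_label`.
#' @export
match_to_cosmic <- function(extracted, cosmic = synthetic_cosmic_v2(),
                            merged_pairs = list(c("COSMIC_2", "COSMIC_13")),
                            report_floor = 0.8) {
  extracted <- as.matrix(extracted)
  cosmic <- as.matrix(cosmic)
  if (nrow(extracted) == 0L || nrow(cosmic) == 0L) {
    stop_data("both extracted and reference matrices must be non-empty")
  }
  sims <- .cosine_rows(extracted, cosmic)
  exnames <- rownames(extracted)
  if (is.null(exnames)) exnames <- paste0("W", seq_len(nrow(extracted)))
  out <- lapply(seq_len(nrow(extracted)), function(i) {
    ord <- order(sims[i, ], decreasing = TRUE)
    best <- colnames(sims)[ord[1]]; second <- colnames(sims)[ord[2]]
    cb <- sims[i, ord[1]]; cs <- sims[i, ord[2]]
    label <- .signature_label(best, cb, report_floor)
    merged <- any(vapply(merged_pairs, function(p)
      setequal(p, c(best, second)), logical(1)))
    if (merged && cb >= report_floor && cs >= report_floor) {
      ids <- paste(sub("COSMIC_", "", c(best, second)), collapse = " + ")
      et <- .cosmic_etiology[best]
      label <- sprintf("%s signature (COSMIC %s)",
                       if (is.na(et)) "combined" else et, ids)
    }
    data.frame(extracted_name = exnames[i], best_cosmic = best,
               best_cosine = cb, second_cosmic = second, second_cosine = cs,
               assigned_label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.signature_label <- function(id, cosine, floor) {
  plain <- sub("COSMIC_", "COSMIC ", id)
  if (cosine < floor) return(plain)
  et <- .cosmic_etiology[id]
  if (is.na(et)) plain else sprintf("%s signature (%s)", et, plain)
}
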