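# Independent oracles and fixture builders used across the suite.
# Each oracle re-applies a rule definition directly (loops, enumeration,
# closed forms) so it stays independent of the package's implementation.

# ---- scar-count oracles: per-segment explicit loops --------------------

oracle_loh <- function(seg, genome, min_len = 15e6) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    chrlen <- genome$length[genome$chrom == s$chrom]
    if (s$minor_cn == 0 &&
        (s$end - s$start + 1) > min_len &&
        !(s$start == 1 && s$end == chrlen)) {
      n <- n + 1L
    }
  }
  n
}

oracle_tai <- function(seg, genome, min_len = 11e6) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    g <- genome[genome$chrom == s$chrom, ]
    reaches_end <- s$start == 1 || s$end == g$length
    crosses <- s$start <= g$centro_end && s$end >= g$centro_start
    if (s$major_cn != s$minor_cn &&
        (s$end - s$start + 1) > min_len &&
        reaches_end && !crosses) {
      n <- n + 1L
    }
  }
  n
}

oracle_lst <- function(seg, genome, min_seg = 10e6, max_gap = 3e6,
                       smooth_below = 3e6) {
  total <- 0L
  for (ch in unique(seg$chrom)) {
    g <- genome[genome$chrom == ch, ]
    mid <- floor((g$centro_start + g$centro_end) / 2)
    s0 <- seg[seg$chrom == ch, , drop = FALSE]
    # split at the centromere midpoint into arm lists
    arms <- list(p = NULL, q = NULL)
    for (i in seq_len(nrow(s0))) {
      s <- s0[i, ]
      if (s$end <= mid) {
        arms$p <- rbind(arms$p, s)
      } else if (s$start > mid) {
        arms$q <- rbind(arms$q, s)
      } else {
        p <- s; p$end <- mid
        q <- s; q$start <- mid + 1
        arms$p <- rbind(arms$p, p)
        arms$q <- rbind(arms$q, q)
      }
    }
    for (a in arms) {
      if (is.null(a) || nrow(a) == 0L) next
      a <- a[order(a$start), , drop = FALSE]
      a <- a[(a$end - a$start + 1) >= smooth_below, , drop = FALSE]
      if (nrow(a) == 0L) next
      # merge adjacent same-state runs
      out <- a[1, , drop = FALSE]
      if (nrow(a) > 1L) {
        for (i in 2:nrow(a)) {
          j <- nrow(out)
          if (a$major_cn[i] == out$major_cn[j] &&
              a$minor_cn[i] == out$minor_cn[j]) {
            out$end[j] <- a$end[i]
          } else {
            out <- rbind(out, a[i, , drop = FALSE])
          }
        }
      }
      if (nrow(out) < 2L) next
      for (i in seq_len(nrow(out) - 1L)) {
        len1 <- out$end[i] - out$start[i] + 1
        len2 <- out$end[i + 1] - out$start[i + 1] + 1
        gap <- out$start[i + 1] - out$end[i] - 1
        changed <- out$major_cn[i] != out$major_cn[i + 1] ||
          out$minor_cn[i] != out$minor_cn[i + 1]
        if (changed && len1 >= min_seg && len2 >= min_seg && gap <= max_gap) {
          total <- total + 1L
        }
      }
    }
  }
  total
}

# random valid single-sample segment table on the default genome
random_segment_table <- function(n_segments, genome = synthetic_genome()) {
  rows <- list()
  for (ch in sample(genome$chrom, min(nrow(genome), 3))) {
    chrlen <- genome$length[genome$chrom == ch]
    k <- max(1L, rpois(1, n_segments / 3))
    cuts <- sort(sample.int(chrlen, 2 * k))
    for (j in seq_len(k)) {
      major <- sample(0:4, 1)
      minor <- sample(0:major, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = cuts[2 * j - 1], end = cuts[2 * j],
        major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- statistics oracles ------------------------------------------------

# literal step-up definition of the BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- min(1, val)
    prev <- val
  }
  adj
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  splits <- combn(length(pooled), n1)
  Ws <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- mean(Ws)
  min(1, sum(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9) / ncol(splits))
}

# dense 2-D grid search over non-negative weights for 2-signature
# least-squares refitting; returns the normalized argmin
oracle_refit_grid2 <- function(freq, ref, step = 5e-4) {
  G <- ref %*% t(ref)
  b <- as.vector(ref %*% freq)
  grid_min <- function(w1, w2) {
    rss <- outer(G[1, 1] * w1^2 - 2 * b[1] * w1,
                 G[2, 2] * w2^2 - 2 * b[2] * w2, `+`) +
      2 * G[1, 2] * outer(w1, w2)
    idx <- arrayInd(which.min(rss), dim(rss))
    c(w1[idx[1]], w2[idx[2]])
  }
  coarse <- grid_min(seq(0, 1.2, by = step), seq(0, 1.2, by = step))
  fine <- grid_min(seq(max(0, coarse[1] - step), coarse[1] + step, by = 1e-5),
                   seq(max(0, coarse[2] - step), coarse[2] + step, by = 1e-5))
  fine / sum(fine)
}

# exhaustive ROC oracle: every unique score as cutoff, direct counting
oracle_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores))
  sens <- sapply(thr, function(t) mean(scores[labels] >= t))
  spec <- sapply(thr, function(t) mean(scores[!labels] < t))
  sums <- sens + spec
  best <- max(sums)
  # concordance-count AUC (ties counted half)
  pos <- scores[labels]; neg <- scores[!labels]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  list(best_sum = best,
       best_cutoffs = thr[abs(sums - best) < 1e-12],
       auc = conc / (length(pos) * length(neg)))
}
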