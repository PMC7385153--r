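test_that("cosine similarity matches hand computations and rejects zero vectors", {
  u <- c(1, 2, 2, rep(0, 93))
  v <- c(2, 1, 2, rep(0, 93))
  expect_equal(cosine_similarity(u, v), 8 / 9)
  expect_equal(cosine_similarity(u, u), 1)
  w <- c(rep(0, 3), 1, rep(0, 92))
  expect_equal(cosine_similarity(u, w), 0)
  expect_error(cosine_similarity(u, rep(0, 96)), "zero vector")
  expect_error(cosine_similarity(u, c(1, 2)), "length")
})

test_that("an exact rank-1 catalog collapses to a single recovered signature", {
  profile <- default_true_signatures()["CpG", ]
  counts <- matrix(rep(round(2000 * profile), 12), nrow = 12, byrow = TRUE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("s", 1:12), trinucleotide_contexts())
  cat1 <- structure(list(samples = rownames(counts), counts = counts,
                         context_order = trinucleotide_contexts()),
                    class = "trinuc_catalog")
  rep1 <- extract_signatures(cat1, n_restarts = 6L, k_max = 6L, seed = 2L)
  expect_equal(rep1$chosen_k, 1L)
  expect_gt(cosine_similarity(rep1$consensus_profiles[1, ], profile), 0.999)
})

test_that("an unreachable consensus quorum raises a diagnostic error with the vote table", {
  co <- simulate_cohort(sim_config(n_samples = 10, seed = 6,
                                   mutations_per_sample = 200L))
  expect_error(
    extract_signatures(co$catalog, n_restarts = 4L, k_max = 6L, seed = 1L,
                       quorum = 1.2),
    "votes")
})

test_that("singleton flagging uses an inclusive dominance threshold", {
  act <- matrix(c(69, 31, rep(10, 8) * 0), ncol = 2)
  act <- matrix(0, 10, 2, dimnames = list(paste0("s", 1:10), c("W1", "W2")))
  act[, "W2"] <- 1
  act["s1", "W1"] <- 69
  act["s2", "W1"] <- 31
  flags <- flag_singleton_signature(act, threshold_fraction = 0.5)
  expect_equal(flags$signature, "W1")
  expect_equal(flags$sample, "s1")
  expect_equal(flags$fraction, 0.69)
  # uniform contributions are not singletons
  expect_equal(nrow(flag_singleton_signature(
    matrix(1, 10, 1, dimnames = list(paste0("s", 1:10), "W1")))), 0L)
  # threshold boundary is inclusive
  expect_equal(nrow(flag_singleton_signature(act, 0.69)), 1L)
  expect_equal(nrow(flag_singleton_signature(act, 0.691)), 0L)
})

test_that("refitting recovers exact members and orthogonal mixtures", {
  ref <- matrix(0, 2, 96,
                dimnames = list(c("A", "B"), trinucleotide_contexts()))
  ref["A", 1:48] <- 1 / 48
  ref["B", 49:96] <- 1 / 48
  # exact counts: 60 per A-channel, 40 per B-channel = a 0.6/0.4 mixture
  pure <- as.integer(1000 * 48 * ref["A", ])
  mixed <- as.integer(48 * (60 * ref["A", ] + 40 * ref["B", ]))
  counts <- rbind(s1 = pure, s2 = mixed)
  storage.mode(counts) <- "integer"
  cat1 <- structure(list(samples = c("s1", "s2"), counts = counts,
                         context_order = trinucleotide_contexts()),
                    class = "trinuc_catalog")
  ex <- refit_exposures(cat1, ref)
  expect_equal(unname(ex$activities["s1", ]), c(1, 0))
  expect_equal(unname(ex$activities["s2", ]), c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(ex$first_signature, c("A", "A"))
  # zero-mutation sample: zero row, flagged
  counts0 <- rbind(counts, s3 = rep(0L, 96))
  cat0 <- structure(list(samples = c("s1", "s2", "s3"), counts = counts0,
                         context_order = trinucleotide_contexts()),
                    class = "trinuc_catalog")
  expect_warning(ex0 <- refit_exposures(cat0, ref), "zero-mutation")
  expect_equal(unname(ex0$activities["s3", ]), c(0, 0))
  expect_equal(assign_first_signature(ex0)[3], "unassigned")
})

test_that("NNLS solutions match a dense grid-search oracle on two-signature problems", {
  set.seed(55)
  truth <- default_true_signatures()
  ref <- truth[c("CpG", "BRCA"), ]
  for (w in c(0.25, 0.5, 0.8)) {
    p <- w * ref[1, ] + (1 - w) * ref[2, ]
    counts <- matrix(as.integer(rmultinom(1, 5000, p)), 1, 96,
                     dimnames = list("s1", trinucleotide_contexts()))
    cat1 <- structure(list(samples = "s1", counts = counts,
                           context_order = trinucleotide_contexts()),
                      class = "trinuc_catalog")
    ex <- refit_exposures(cat1, ref, floor = 0)
    grid <- oracle_refit_grid2(counts[1, ] / sum(counts), ref)
    expect_lt(sum(abs(ex$activities[1, ] - grid)), 1e-3)
  }
})

test_that("refit is scale invariant and never fits worse than any single signature", {
  co <- simulate_cohort(sim_config(n_samples = 6, seed = 17,
                                   mutations_per_sample = 400L))
  ref <- default_true_signatures()
  ex <- refit_exposures(co$catalog, ref)
  scaled <- co$catalog
  scaled$counts <- scaled$counts * 7L
  ex7 <- refit_exposures(scaled, ref)
  expect_equal(ex$activities, ex7$activities)
  for (i in seq_along(co$catalog$samples)) {
    f <- co$catalog$counts[i, ] / sum(co$catalog$counts[i, ])
    singles <- apply(ref, 1, function(s) cosine_similarity(f, s))
    expect_gte(ex$recon_cosine[i] + 1e-12, max(singles))
  }
})

test_that("signature naming promotes etiology labels and merges the APOBEC pair", {
  ref <- synthetic_cosmic_v2()
  m1 <- match_to_cosmic(ref["COSMIC_1", , drop = FALSE], ref)
  expect_equal(m1$best_cosmic, "COSMIC_1")
  expect_equal(m1$best_cosine, 1)
  expect_match(m1$assigned_label, "COSMIC 1")

  apo <- (ref["COSMIC_2", ] + ref["COSMIC_13", ]) / 2
  apo <- matrix(apo / sum(apo), 1, 96, dimnames = list("W2", NULL))
  m2 <- match_to_cosmic(apo, ref)
  expect_setequal(c(m2$best_cosmic, m2$second_cosmic),
                  c("COSMIC_2", "COSMIC_13"))
  expect_match(m2$assigned_label, "APOBEC signature \\(COSMIC (2 \\+ 13|13 \\+ 2)\\)")
  direct2 <- cosine_similarity(apo[1, ], ref["COSMIC_2", ])
  expect_equal(max(m2$best_cosine, m2$second_cosine),
               max(direct2, cosine_similarity(apo[1, ], ref["COSMIC_13", ])))

  # below the report floor no etiology is promoted
  lone <- matrix(0, 1, 96)
  lone[1, 37] <- 1
  m3 <- match_to_cosmic(lone, ref)
  if (m3$best_cosine < 0.8) {
    expect_false(grepl("signature \\(", m3$assigned_label))
  }
})

test_that("dominant-signature assignment breaks exact ties lexicographically with a warning", {
  act <- matrix(c(0.7, 0.2, 0.1,
                  0.5, 0.5, 0.0), 2, 3, byrow = TRUE,
                dimnames = list(c("a", "b"), c("W2", "W1", "W3")))
  expect_warning(lab <- assign_first_signature(act), "tie")
  expect_equal(lab, c("W2", "W1"))
})

test_that("extraction votes and consensus are reproducible from the seed and sample order", {
  co <- simulate_cohort(sim_config(n_samples = 60, seed = 23,
                                   mutations_per_sample = c(500L, 1000L)))
  r1 <- extract_signatures(co$catalog, n_restarts = 6L, k_max = 6L,
                           seed = 9L, quorum = 0)
  r2 <- extract_signatures(co$catalog, n_restarts = 6L, k_max = 6L,
                           seed = 9L, quorum = 0)
  expect_identical(r1$consensus_profiles, r2$consensus_profiles)
  set.seed(1)
  perm <- sample(co$catalog$samples)
  r3 <- extract_signatures(subset_catalog(co$catalog, perm),
                           n_restarts = 6L, k_max = 6L, seed = 9L,
                           quorum = 0)
  expect_equal(r3$chosen_k, r1$chosen_k)
  sims <- sapply(seq_len(nrow(r1$consensus_profiles)), function(i)
    max(apply(r3$consensus_profiles, 1, cosine_similarity,
              r1$consensus_profiles[i, ])))
  expect_true(all(sims > 0.98))
})
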