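test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  bad_mix <- .default_mixtures()
  bad_mix["nonHRD", 1] <- bad_mix["nonHRD", 1] + 1e-6
  expect_error(sim_config(signature_mixtures = bad_mix),
               "signature_mixtures")
  neg_mix <- .default_mixtures()
  neg_mix["nonHRD", ] <- c(-0.1, 0.5, 0.3, 0.3)
  expect_error(sim_config(signature_mixtures = neg_mix),
               "signature_mixtures")
  bad_genome <- synthetic_genome()
  bad_genome$centro_end[1] <- bad_genome$length[1] + 10
  expect_error(sim_config(genome = bad_genome), "genome")
  expect_error(sim_config(group_sizes = c(BRCA1mut = 1, BRCA2mut = 1,
                                          HRDwt = 1, nonHRD = 1),
                          n_samples = 10), "group_sizes")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_samples = 6, seed = 21, mutations_per_sample = 60L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a single-component mixture yields catalog rows proportional to its profile", {
  mix <- matrix(c(1, 0, 0, 0), 1, 4,
                dimnames = list("nonHRD", c("CpG", "APOBEC", "BRCA", "MSI")))
  cfg <- sim_config(n_samples = 2, seed = 4,
                    group_sizes = c(nonHRD = 2L),
                    signature_mixtures = mix,
                    mutations_per_sample = 1000L,
                    exposure_concentration = 1)
  co <- simulate_cohort(cfg)
  profile <- default_true_signatures()["CpG", ]
  for (i in 1:2) {
    obs <- co$catalog$counts[i, ] / sum(co$catalog$counts[i, ])
    expect_gt(cosine_similarity(obs, profile), 0.98)
  }
  expect_equal(unname(rowSums(co$catalog$counts)),
               unname(co$truth$mutation_counts))
})

test_that("deterministic scar mode places exactly the requested qualifying segments", {
  rates <- matrix(c(10, 5, 8), 1, 3,
                  dimnames = list("nonHRD", c("loh", "tai", "lst")))
  cfg <- sim_config(n_samples = 2, seed = 13,
                    group_sizes = c(nonHRD = 2L),
                    scar_rate_params = rates, scar_mode = "deterministic",
                    scar_decoys = FALSE, mutations_per_sample = 20L)
  co <- simulate_cohort(cfg)
  for (sm in co$catalog$samples) {
    seg <- co$segments[co$segments$sample == sm, ]
    expect_equal(count_loh(seg, co$genome_meta), 10L)
    expect_equal(count_tai(seg, co$genome_meta), 5L)
    expect_equal(count_lst(seg, co$genome_meta), 8L)
    # brute-force enumerators agree by construction
    expect_equal(oracle_loh(seg, co$genome_meta), 10L)
    expect_equal(oracle_tai(seg, co$genome_meta), 5L)
    expect_equal(oracle_lst(seg, co$genome_meta), 8L)
  }
  expect_equal(co$truth$scar_counts$hrd_sum, c(23L, 23L))
})

test_that("every truth-ledger quantity is recomputable from the emitted tables", {
  cfg <- sim_config(n_samples = 12, seed = 31,
                    mutations_per_sample = c(100L, 200L),
                    group_sizes = c(BRCA1mut = 2L, BRCA2mut = 2L,
                                    HRDwt = 2L, nonHRD = 6L))
  co <- simulate_cohort(cfg)
  # catalog truth = consensus-filtered MAF recount
  cons <- consensus_filter(co$maf)
  rebuilt <- build_catalog(cons, co$reference, samples = co$catalog$samples)
  expect_identical(rebuilt$counts, co$catalog$counts)
  # decoy rows exist and are removed by consensus filtering
  expect_gt(nrow(co$maf), nrow(cons))
  # scar truth = counter recount
  sc <- hrd_scores(co$segments, co$genome_meta, samples = co$catalog$samples)
  expect_equal(sc$loh_count, co$truth$scar_counts$loh)
  expect_equal(sc$tai_count, co$truth$scar_counts$tai)
  expect_equal(sc$lst_count, co$truth$scar_counts$lst)
  # silencing truth = silencing-call tally
  calls <- silencing_calls(co$methylation, co$fpkm)
  called <- calls[calls$silenced %in% TRUE, c("sample", "gene")]
  expect_setequal(paste(called$sample, called$gene),
                  paste(co$truth$silenced$sample, co$truth$silenced$gene))
  # germline truth = cascade survivors
  res <- suppressWarnings(run_cascade(co$germline_candidates))
  expect_setequal(res$survivors$variant_id, co$truth$germline_survivors)
  # exposure truth rows sum to one
  expect_equal(unname(rowSums(co$truth$exposures)),
               rep(1, nrow(co$truth$exposures)))
})

test_that("each cascade rule has a dedicated sole-violator among the candidates", {
  co <- simulate_cohort(sim_config(n_samples = 4, seed = 2,
                                   mutations_per_sample = 30L))
  cand <- co$germline_candidates
  violators <- cand[startsWith(cand$variant_id, "V_"), ]
  expect_equal(nrow(violators), 10L)
  for (i in seq_len(nrow(violators))) {
    res <- suppressWarnings(run_cascade(violators[i, , drop = FALSE]))
    rules <- res$trace[, c("quality", "context", "population", "function",
                           "truncation", "panel")]
    expect_equal(sum(!unlist(rules)), 1L, info = violators$variant_id[i])
  }
})
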