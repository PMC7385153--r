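clean_rec <- function(...) {
  r <- hrdpipe:::.clean_germline_record("v1", "s1", "BRCA2")
  mods <- list(...)
  for (f in names(mods)) r[[f]] <- mods[[f]]
  r
}

test_that("quality rules use strict thresholds and the somatic label", {
  expect_true(quality_filter(clean_rec())$pass)
  r <- quality_filter(clean_rec(total_depth = 9L))
  expect_false(r$pass); expect_equal(r$reason, "depth")
  expect_true(quality_filter(clean_rec(total_depth = 10L))$pass)
  r <- quality_filter(clean_rec(variant_count = 4L))
  expect_false(r$pass); expect_equal(r$reason, "variant_count")
  # VAF of exactly 0.08 passes (strict <)
  expect_true(quality_filter(clean_rec(vaf = 0.08))$pass)
  expect_false(quality_filter(clean_rec(vaf = 0.079))$pass)
  r <- quality_filter(clean_rec(caller_label = "somatic"))
  expect_false(r$pass); expect_equal(r$reason, "somatic_label")
  expect_error(quality_filter(clean_rec(vaf = NA)), "missing")
})

test_that("context rules: homopolymer proximity, inclusive mapq difference, read ends", {
  r <- context_filters(clean_rec(mapq_ref_mean = 60, mapq_alt_mean = 30))
  expect_false(r$pass); expect_equal(r$reason, "mapq_difference")
  expect_true(context_filters(clean_rec(mapq_alt_mean = 31))$pass)
  r <- context_filters(clean_rec(flank_sequence = "CAAAAACTAGCTA"))
  expect_false(r$pass); expect_equal(r$reason, "homopolymer")
  # run of four is not a homopolymer under the default run length of five
  expect_true(context_filters(clean_rec(flank_sequence = "CAAAACTTAGCTA"))$pass)
  # run of five beyond the 3 bp window passes
  expect_true(context_filters(clean_rec(
    flank_sequence = "AAAAACGTCGTACGTCG"))$pass)
  r <- context_filters(clean_rec(median_read_position_fraction = 0.05))
  expect_false(r$pass); expect_equal(r$reason, "read_end")
  r <- context_filters(clean_rec(median_read_position_fraction = 0.97))
  expect_false(r$pass)
  # precomputed flags take precedence over raw evidence
  expect_false(context_filters(clean_rec(homopolymer_flag = TRUE))$pass)
  expect_false(context_filters(clean_rec(read_end_flag = TRUE))$pass)
  # absent evidence passes with a warning
  bare <- clean_rec()
  bare$flank_sequence <- NA
  bare$mapq_ref_mean <- NA
  bare$median_read_position_fraction <- NA
  msgs <- capture_warnings(r <- context_filters(bare))
  expect_length(msgs, 3L)
  expect_true(all(grepl("evidence", msgs)))
  expect_true(r$pass)
})

test_that("population filter is inclusive at 1% and treats missing frequency as rare", {
  expect_false(population_filter(clean_rec(population_af = 0.01))$pass)
  expect_true(population_filter(clean_rec(population_af = 0.009))$pass)
  expect_true(population_filter(clean_rec(population_af = NA))$pass)
})

test_that("functional-region filter keeps exonic and splicing calls only", {
  for (region in c("intergenic", "intronic", "UTR3", "UTR5", "upstream",
                   "downstream", "ncRNA_exonic")) {
    expect_false(function_filter(clean_rec(func_region = region))$pass,
                 info = region)
  }
  expect_true(function_filter(clean_rec(func_region = "exonic"))$pass)
  expect_true(function_filter(clean_rec(func_region = "splicing"))$pass)
  expect_error(function_filter(clean_rec(func_region = "promoter")),
               "unknown")
})

test_that("truncation selector keeps hotspots, nonsense, frameshifts and splice sites", {
  expect_false(truncation_selector(clean_rec(exonic_class = "missense"))$pass)
  expect_true(truncation_selector(clean_rec(exonic_class = "missense",
                                            clinvar_hotspot = TRUE))$pass)
  expect_true(truncation_selector(clean_rec(
    exonic_class = "frameshift_indel"))$pass)
  expect_true(truncation_selector(clean_rec(exonic_class = "nonsense"))$pass)
  expect_true(truncation_selector(clean_rec(
    exonic_class = "unknown", func_region = "splicing"))$pass)
  expect_false(truncation_selector(clean_rec(
    exonic_class = "synonymous"))$pass)
})

test_that("panel extraction is case-insensitive and configurable", {
  recs <- rbind(clean_rec(), clean_rec(gene = "tp53"), clean_rec(gene = "brca1"))
  recs$gene <- c("BRCA2", "TP53", "brca1")
  kept <- ddr_panel_extract(recs)
  expect_setequal(kept$gene, c("BRCA2", "brca1"))
  expect_equal(nrow(ddr_panel_extract(recs[0, ])), 0L)
  expect_equal(nrow(ddr_panel_extract(recs, panel = "TP53")), 1L)
})

test_that("the cascade fixture leaves exactly one survivor with a full trace", {
  fix <- germline_fixture()
  res <- suppressWarnings(run_cascade(fix$records))
  expect_equal(nrow(res$survivors), 1L)
  expect_equal(res$survivors$variant_id, fix$survivor_id)
  surv_trace <- res$trace[res$trace$variant_id == fix$survivor_id, ]
  expect_true(all(unlist(surv_trace[, c("quality", "context", "population",
                                        "function", "truncation", "panel")])))
  expect_equal(surv_trace$final_status, "pass")
  failed <- res$trace[res$trace$final_status == "fail", ]
  expect_true(all(!is.na(failed$first_failing_rule)))
})

test_that("survivors equal the intersection of per-rule pass sets", {
  fix <- germline_fixture()
  recs <- fix$records
  pass_sets <- list(
    quality = vapply(seq_len(nrow(recs)), function(i)
      quality_filter(recs[i, ])$pass, logical(1)),
    context = vapply(seq_len(nrow(recs)), function(i)
      suppressWarnings(context_filters(recs[i, ])$pass), logical(1)),
    population = vapply(seq_len(nrow(recs)), function(i)
      population_filter(recs[i, ])$pass, logical(1)),
    func = vapply(seq_len(nrow(recs)), function(i)
      function_filter(recs[i, ])$pass, logical(1)),
    trunc = vapply(seq_len(nrow(recs)), function(i)
      truncation_selector(recs[i, ])$pass, logical(1)),
    panel = toupper(recs$gene) %in% ddr_panel())
  expected <- recs$variant_id[Reduce(`&`, pass_sets)]
  res <- suppressWarnings(run_cascade(recs))
  expect_setequal(res$survivors$variant_id, expected)
  # conjunction: shuffling record order never changes the survivor set
  set.seed(5)
  shuffled <- recs[sample(nrow(recs)), ]
  res2 <- suppressWarnings(run_cascade(shuffled))
  expect_setequal(res2$survivors$variant_id, expected)
})

test_that("relaxing any threshold never shrinks the survivor set", {
  fix <- germline_fixture()
  base <- suppressWarnings(run_cascade(fix$records))$survivors$variant_id
  relaxed <- list(list(min_depth = 5), list(min_count = 3),
                  list(min_vaf = 0.05), list(max_af = 0.05),
                  list(max_mapq_diff = 50), list(read_end_fraction = 0.02),
                  list(homopolymer_run = 7L))
  for (cfg in relaxed) {
    surv <- suppressWarnings(run_cascade(fix$records,
                                         config = cfg))$survivors$variant_id
    expect_true(all(base %in% surv), info = names(cfg))
    expect_gte(length(surv), length(base))
  }
})
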