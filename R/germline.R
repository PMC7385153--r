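## Germline truncating-variant filter cascade over a DNA damage response
## gene panel. The cascade removes (in order): low-quality calls, calls in
## problematic sequence context, common population variants and variants
## without protein-level consequence, then keeps only truncating variants
## and subsets to the gene panel. All rules are conjunctive, so the
## survivor set does not depend on rule order.

#' The 11-gene DNA damage response germline panel
#' @return character vector of gene symbols.
#' @export
ddr_panel <- function() {
  c("ATM", "BAP1", "BRCA1", "BRCA2", "BRIP1", "CDK12", "CHEK2", "NBN",
    "PALB2", "POLQ", "RAD51C")
}

.func_fail_regions <- c("intergenic", "intronic", "UTR3", "UTR5",
                        "upstream", "downstream")
.func_known_regions <- c("exonic", "splicing", .func_fail_regions)

# does a flank sequence contain a homopolymer run of >= run_len within
# window bp of the variant site? `flank_sequence` is centered on the
# variant base (odd length).
.near_homopolymer <- function(flank_sequence, run_len = 5L, window = 3L) {
  fs <- toupper(flank_sequence)
  n <- nchar(fs)
  center <- (n + 1L) %/% 2L
  r <- rle(strsplit(fs, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$lengths >= run_len & r$values %in% c("A", "C", "G", "T"))
  any(starts[runs] <= center + window & ends[runs] >= center - window)
}

#' Quality filter for germline variant candidates
#'
#' Fails a candidate when read depth < 10, supporting variant reads < 5,
#' variant allele fraction < 0.08, or the caller labelled it somatic.
#'
#' @param record one-row data.frame (or list) with `total_depth`,
#'   `variant_count`, `vaf`, `caller_label`.
#' @param min_depth,min_count,min_vaf thresholds (strict `<` fails).
#' @return list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
quality_filter <- function(record, min_depth = 10, min_count = 5,
                           min_vaf = 0.08) {
  needed <- c("total_depth", "variant_count", "vaf", "caller_label")
  miss <- needed[!needed %in% names(record) |
                   vapply(needed, function(f) is.null(record[[f]]) ||
                            (f != "caller_label" && is.na(record[[f]])),
                          logical(1))]
  if (length(miss) > 0L) {
    stop_data("quality_filter: missing field(s) %s", paste(miss, collapse = ", "))
  }
  if (record$total_depth < min_depth) return(list(pass = FALSE, reason = "depth"))
  if (record$variant_count < min_count) return(list(pass = FALSE, reason = "variant_count"))
  if (record$vaf < min_vaf) return(list(pass = FALSE, reason = "vaf"))
  if (identical(as.character(record$caller_label), "somatic")) {
    return(list(pass = FALSE, reason = "somatic_label"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Sequence-context filters for germline variant candidates
#'
#' Fails a candidate near a homopolymer run (a single-base run of at
#' least `homopolymer_run` bases within `homopolymer_window` bp of the
#' site), with an absolute reference-vs-variant mapping-quality
#' difference of at least 30, or positioned in read ends (median variant
#' position within the terminal `read_end_fraction` of reads). Each rule
#' accepts either raw evidence (`flank_sequence`,
#' `median_read_position_fraction`) or a precomputed flag
#' (`homopolymer_flag`, `read_end_flag`); when neither is present the
#' rule passes with a warning.
#'
#' @param record one-row data.frame or list.
#' @param max_mapq_diff inclusive mapping-quality difference threshold.
#' @param homopolymer_run,homopolymer_window homopolymer rule parameters.
#' @param read_end_fraction terminal fraction of the read defining "read
#'   end".
#' @return list with `pass` and `reason`.
#' @export
context_filters <- function(record, max_mapq_diff = 30,
                            homopolymer_run = 5L, homopolymer_window = 3L,
                            read_end_fraction = 0.10) {
  get <- function(f) if (f %in% names(record)) record[[f]] else NULL
  is_avail <- function(x) !is.null(x) && !is.na(x)
  # homopolymer context
  hp_flag <- get("homopolymer_flag"); flank <- get("flank_sequence")
  if (is_avail(hp_flag)) {
    if (isTRUE(as.logical(hp_flag))) return(list(pass = FALSE, reason = "homopolymer"))
  } else if (is_avail(flank)) {
    if (.near_homopolymer(flank, homopolymer_run, homopolymer_window)) {
      return(list(pass = FALSE, reason = "homopolymer"))
    }
  } else {
    warning("context_filters: no homopolymer evidence; rule passes")
  }
  # mapping-quality difference
  mr <- get("mapq_ref_mean"); ma <- get("mapq_alt_mean")
  if (is_avail(mr) && is_avail(ma)) {
    if (abs(mr - ma) >= max_mapq_diff) {
      return(list(pass = FALSE, reason = "mapq_difference"))
    }
  } else {
    warning("context_filters: no mapping-quality evidence; rule passes")
  }
  # read-end position
  re_flag <- get("read_end_flag"); medpos <- get("median_read_position_fraction")
  if (is_avail(re_flag)) {
    if (isTRUE(as.logical(re_flag))) return(list(pass = FALSE, reason = "read_end"))
  } else if (is_avail(medpos)) {
    if (medpos <= read_end_fraction || medpos >= 1 - read_end_fraction) {
      return(list(pass = FALSE, reason = "read_end"))
    }
  } else {
    warning("context_filters: no read-position evidence; rule passes")
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Population-frequency filter
#'
#' Fails known-common variants: population minor allele frequency at or
#' above `max_af` (default 1%). A missing frequency is treated as rare
#' (the filter removes known-common variants only).
#'
#' @param record one-row data.frame or list with `population_af`.
#' @param max_af inclusive threshold.
#' @return list with `pass` and `reason`.
#' @export
population_filter <- function(record, max_af = 0.01) {
  af <- if ("population_af" %in% names(record)) record$population_af else NA
  if (!is.null(af) && !is.na(af) && af >= max_af) {
    return(list(pass = FALSE, reason = "common_variant"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Functional-region filter
#'
#' Keeps variants that can affect protein function: exonic and splicing
#' calls pass; intergenic, intronic, UTR, upstream, downstream and
#' noncoding-RNA calls fail.
#'
#' @param record one-row data.frame or list with `func_region`.
#' @return list with `pass` and `reason`.
#' @export
function_filter <- function(record) {
  fr <- record$func_region
  if (is.null(fr) || is.na(fr)) stop_data("function_filter: func_region missing")
  fr <- as.character(fr)
  if (fr %in% c("exonic", "splicing")) return(list(pass = TRUE, reason = NA_character_))
  if (fr %in% .func_fail_regions || startsWith(fr, "ncRNA")) {
    return(list(pass = FALSE, reason = "noncoding_region"))
  }
  stop_data("function_filter: unknown func_region '%s'", fr)
}

#' Truncating-variant selector
#'
#' Keeps variants likely to disable the protein: ClinVar-annotated
#' hotspots, nonsense substitutions, frameshift indels and splice-site
#' variants. Everything else (missense, synonymous, in-frame indels)
#' fails.
#'
#' @param record one-row data.frame or list with `exonic_class`,
#'   `func_region` and `clinvar_hotspot`.
#' @return list with `pass` and `reason`.
#' @export
truncation_selector <- function(record) {
  hotspot <- isTRUE(as.logical(record$clinvar_hotspot))
  cls <- as.character(record$exonic_class)
  splice <- identical(as.character(record$func_region), "splicing")
  if (hotspot || splice || (length(cls) == 1L && !is.na(cls) &&
                            cls %in% c("nonsense", "frameshift_indel"))) {
    return(list(pass = TRUE, reason = NA_character_))
  }
  list(pass = FALSE, reason = "not_truncating")
}

#' Subset variants to a gene panel
#'
#' @param records data.frame of variant records with a `gene` column.
#' @param panel character vector of gene symbols (default [ddr_panel()]).
#' @return the row subset with `toupper(gene)` in the panel.
#' @export
ddr_panel_extract <- function(records, panel = ddr_panel()) {
  check_columns(records, "gene", "variant table")
  records[toupper(records$gene) %in% toupper(panel), , drop = FALSE]
}

#' Run the full germline filter cascade
#'
#' Applies quality, context, population, functional-region and truncation
#' rules, then the gene-panel subset, recording every rule outcome per
#' variant. Rules are conjunctive: the survivor set is invariant to rule
#' order; the trace reflects the order above.
#'
#' @param records data.frame of candidate variant records (one row per
#'   variant) with the fields the individual filters inspect, plus
#'   `sample` and `gene`.
#' @param panel gene panel (default [ddr_panel()]; `NULL` skips the panel
#'   step).
#' @param config optional named list overriding filter parameters
#'   (`min_depth`, `min_count`, `min_vaf`, `max_mapq_diff`,
#'   `homopolymer_run`, `homopolymer_window`, `read_end_fraction`,
#'   `max_af`).
#' @return list with `survivors` (row subset of `records`) and `trace`
#'   (data.frame: one row per record with per-rule pass/fail,
#'   `final_status`, `first_failing_rule`).
#' @export
run_cascade <- function(records, panel = ddr_panel(), config = list()) {
  cfg <- utils::modifyList(
    list(min_depth = 10, min_count = 5, min_vaf = 0.08, max_mapq_diff = 30,
         homopolymer_run = 5L, homopolymer_window = 3L,
         read_end_fraction = 0.10, max_af = 0.01),
    config)
  n <- nrow(records)
  rules <- c("quality", "context", "population", "function", "truncation",
             "panel")
  trace <- as.data.frame(matrix(TRUE, n, length(rules)),
                         stringsAsFactors = FALSE)
  names(trace) <- rules
  first_fail <- rep(NA_character_, n)
  fail_reason <- rep(NA_character_, n)
  in_panel <- if (is.null(panel)) rep(TRUE, n)
              else toupper(records$gene) %in% toupper(panel)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    res <- list(
      quality = quality_filter(rec, cfg$min_depth, cfg$min_count, cfg$min_vaf),
      context = context_filters(rec, cfg$max_mapq_diff, cfg$homopolymer_run,
                                cfg$homopolymer_window, cfg$read_end_fraction),
      population = population_filter(rec, cfg$max_af),
      `function` = function_filter(rec),
      truncation = truncation_selector(rec),
      panel = list(pass = in_panel[i],
                   reason = if (in_panel[i]) NA_character_ else "not_in_panel"))
    for (r in rules) trace[i, r] <- res[[r]]$pass
    fails <- rules[!vapply(rules, function(r) res[[r]]$pass, logical(1))]
    if (length(fails) > 0L) {
      first_fail[i] <- fails[1]
      fail_reason[i] <- res[[fails[1]]]$reason
    }
  }
  final <- apply(trace, 1, all)
  trace$final_status <- ifelse(final, "pass", "fail")
  trace$first_failing_rule <- first_fail
  trace$fail_reason <- fail_reason
  if ("variant_id" %in% names(records)) {
    trace <- cbind(variant_id = records$variant_id, trace)
  }
  list(survivors = records[final, , drop = FALSE], trace = trace)
}
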