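## End-to-end orchestration: simulate (or ingest) a cohort, build the
## mutation catalog, refit signature exposures, score and classify HRD,
## run the germline cascade and silencing calls, compute per-sample
## scores, and assemble the cohort report tables.

#' Run the full HRD identification pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort:
#' consensus filtering and catalog construction, hypermutant exclusion,
#' exposure refitting (and optionally de novo extraction with singleton
#' handling), scar scoring and top-quantile HRD classification, the
#' germline filter cascade, silencing calls, per-sample scores (RPS,
#' IFN-gamma), and the report tables: subtype x first-signature
#' distribution, HRD/signature/germline overlap sets, DNA-damage-response
#' alteration tallies, and the carrier-group differential-expression
#' contrast.
#'
#' @param config a [sim_config()]; ignored when `cohort` is supplied.
#' @param cohort optionally, an existing `synthetic_cohort`.
#' @param outdir optional directory; when given, every stage output is
#'   written as TSV/JSON and check-summed.
#' @param reference_signatures profiles the refit uses (default
#'   [default_true_signatures()]).
#' @param extract also run de novo extraction (adds runtime).
#' @param n_restarts,k_max extraction parameters (see
#'   [extract_signatures()]).
#' @param imported_hrd optional data.frame with `sample` and `hrd_score`:
#'   published scores used instead of computing scar components (the
#'   import path; required when the cohort carries no segments).
#' @param hrd_quantile top fraction classified as HRD (default 0.10).
#' @param max_snv hypermutant exclusion threshold.
#' @param exposure_floor refit reporting floor.
#' @return a `pipeline_result`: list with `cohort_frame`, `catalog`,
#'   `exposures`, `hrd_scores`, `hrd_classification`, `germline`,
#'   `silencing`, `report` (list of tables), `extraction` (or `NULL`),
#'   `excluded_hypermutants`, `truth`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL, outdir = NULL,
                         reference_signatures = default_true_signatures(),
                         extract = FALSE, n_restarts = 50L, k_max = 10L,
                         imported_hrd = NULL,
                         hrd_quantile = 0.10, max_snv = 5800L,
                         exposure_floor = 0.06) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(cohort)) {
    cohort <- stage("simulate", simulate_cohort(config))
  }
  samples <- cohort$catalog$samples

  consensus <- stage("consensus_filter", consensus_filter(cohort$maf, 2L))
  catalog <- stage("catalog",
                   build_catalog(consensus, cohort$reference,
                                 samples = samples))
  hm <- stage("hypermutants", exclude_hypermutants(catalog, max_snv))
  catalog_kept <- hm$catalog

  exposures <- stage("refit",
                     refit_exposures(catalog_kept, reference_signatures,
                                     floor = exposure_floor))

  extraction <- NULL
  if (extract) {
    extraction <- stage("extract",
                        extract_signatures(catalog_kept,
                                           n_restarts = n_restarts,
                                           k_max = k_max,
                                           seed = cohort$config$seed))
  }

  scars <- stage("scars", {
    if (!is.null(imported_hrd)) {
      check_columns(imported_hrd, c("sample", "hrd_score"), "imported HRD table")
      idx <- match(catalog_kept$samples, imported_hrd$sample)
      if (anyNA(idx)) stop_data("imported HRD scores missing for some samples")
      do.call(rbind, lapply(idx, function(i) {
        hrd_sum(imported = imported_hrd$hrd_score[i],
                sample = imported_hrd$sample[i])
      }))
    } else if (is.null(cohort$segments)) {
      stop_data("no segments in cohort and no imported HRD scores supplied")
    } else {
      hrd_scores(cohort$segments, cohort$genome_meta,
                 samples = catalog_kept$samples)
    }
  })
  scores <- stats::setNames(scars$hrd_sum, scars$sample)
  hrd_class <- stage("classify", classify_by_quantile(scores, hrd_quantile))

  germline <- stage("germline", run_cascade(cohort$germline_candidates))
  silencing <- stage("silencing",
                     silencing_calls(cohort$methylation, cohort$fpkm))

  rps_score <- stage("rps", rps(cohort$fpkm))
  rps_beta_score <- rps_beta(cohort$fpkm)
  ifng <- stage("ifng", ifng_signature(cohort$fpkm))

  kept <- catalog_kept$samples
  ann <- cohort$annotations[match(kept, cohort$annotations$sample), ]
  non_silent <- stage("burden", {
    ns <- table(factor(consensus$sample[
      consensus$variant_classification != "Silent"], levels = kept))
    as.integer(ns)
  })
  sil_by_sample <- vapply(kept, function(sm) {
    g <- silencing$gene[silencing$sample == sm & silencing$silenced %in% TRUE]
    paste(sort(g), collapse = ",")
  }, character(1))

  cohort_frame <- data.frame(
    sample = kept,
    pam50_subtype = ann$pam50_subtype,
    brca1_germline = ann$brca1_germline,
    brca2_germline = ann$brca2_germline,
    hrd_score = unname(scores[kept]),
    hrd_class = hrd_class$is_hrd_top[match(kept, hrd_class$sample)],
    first_signature = exposures$first_signature,
    non_silent_mutation_count = non_silent,
    rps = unname(rps_score[kept]),
    rps_beta = unname(rps_beta_score[kept]),
    ifng_score = unname(ifng[kept]),
    silenced_genes = unname(sil_by_sample),
    stringsAsFactors = FALSE)
  acts <- exposures$activities
  colnames(acts) <- paste0("activity_", colnames(acts))
  cohort_frame <- cbind(cohort_frame, as.data.frame(acts))
  rownames(cohort_frame) <- NULL

  report <- stage("report",
                  .build_report(cohort_frame, germline, silencing, cohort))

  result <- structure(
    list(cohort_frame = cohort_frame, catalog = catalog_kept,
         exposures = exposures, hrd_scores = scars,
         hrd_classification = hrd_class, germline = germline,
         silencing = silencing, report = report, extraction = extraction,
         excluded_hypermutants = hm$excluded, truth = cohort$truth),
    class = "pipeline_result")

  if (!is.null(outdir)) {
    stage("write", .write_pipeline_outputs(result, cohort, outdir))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d samples; %d HRD-classified; %d germline survivor(s)\n",
              nrow(x$cohort_frame), sum(x$cohort_frame$hrd_class),
              nrow(x$germline$survivors)))
  invisible(x)
}

# report tables mirroring the cohort-level result objects
.build_report <- function(frame, germline, silencing, cohort) {
  subtype_signature <- as.data.frame.matrix(
    table(frame$pam50_subtype, frame$first_signature))
  overlaps <- overlap_sets(
    stats::setNames(frame$first_signature == "BRCA", frame$sample),
    stats::setNames(frame$hrd_class, frame$sample),
    stats::setNames(frame$brca1_germline, frame$sample),
    stats::setNames(frame$brca2_germline, frame$sample))
  germ_tally <- as.data.frame(
    table(gene = germline$survivors$gene), stringsAsFactors = FALSE)
  sil_ok <- silencing$silenced %in% TRUE
  sil_tally <- as.data.frame(
    table(gene = silencing$gene[sil_ok]), stringsAsFactors = FALSE)
  deg <- NULL
  b1 <- frame$sample[frame$brca1_germline]
  b2 <- frame$sample[frame$brca2_germline]
  if (length(b1) > 0L && length(b2) > 0L) {
    deg <- select_degs(cohort$fpkm, b1, b2)
  }
  list(subtype_signature = subtype_signature,
       overlaps = overlaps,
       germline_tally = germ_tally,
       silencing_tally = sil_tally,
       deg_brca1_vs_brca2 = deg)
}

.write_pipeline_outputs <- function(result, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(result$cohort_frame, p("cohort_frame.tsv"))
  write_catalog(result$catalog, p("catalog.tsv"))
  write_tsv(data.frame(sample = result$exposures$samples,
                       result$exposures$activities, check.names = FALSE),
            p("exposures.tsv"))
  write_tsv(result$hrd_scores, p("hrd_scores.tsv"))
  write_tsv(result$hrd_classification, p("hrd_classification.tsv"))
  write_tsv(result$germline$survivors, p("germline_survivors.tsv"))
  write_tsv(result$germline$trace, p("germline_trace.tsv"))
  write_tsv(result$silencing, p("silencing_calls.tsv"))
  write_tsv(cbind(subtype = rownames(result$report$subtype_signature),
                  result$report$subtype_signature),
            p("report_subtype_signature.tsv"))
  jsonlite::write_json(
    list(intersections = as.list(result$report$overlaps$intersections)),
    p("report_overlaps.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(result$report$germline_tally, p("report_germline_tally.tsv"))
  write_tsv(result$report$silencing_tally, p("report_silencing_tally.tsv"))
  if (!is.null(result$report$deg_brca1_vs_brca2)) {
    write_tsv(result$report$deg_brca1_vs_brca2, p("report_deg.tsv"))
  }
  files <- list.files(outdir, full.names = TRUE)
  sums <- tools::md5sum(files)
  jsonlite::write_json(as.list(stats::setNames(unname(sums),
                                               basename(files))),
                       p("checksums.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Membership and intersection counts of the four HRD-related sets
#'
#' The four sets are: dominant-BRCA-signature tumors, HRD-classified
#' tumors, BRCA1 germline carriers, BRCA2 germline carriers. Reports
#' per-sample membership and the count of samples inside every non-empty
#' combination of the sets (intersection of the named sets, ignoring the
#' others).
#'
#' @param first_signature,hrd_class,brca1_germline,brca2_germline named
#'   logical vectors over the same sample ids.
#' @return list with `membership` (data.frame) and `intersections`
#'   (named integer vector, names like `"signature3+hrd_top"`).
#' @export
overlap_sets <- function(first_signature, hrd_class, brca1_germline,
                         brca2_germline) {
  sets <- list(signature3 = first_signature, hrd_top = hrd_class,
               brca1 = brca1_germline, brca2 = brca2_germline)
  ids <- names(sets[[1]])
  for (s in sets) {
    if (is.null(names(s)) || !identical(sort(names(s)), sort(ids))) {
      stop_data("overlap_sets: sample ids are misaligned across sets")
    }
  }
  membership <- data.frame(sample = ids,
                           lapply(sets, function(s) unname(s[ids])),
                           stringsAsFactors = FALSE)
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(names(sets), k, simplify = FALSE)), recursive = FALSE)
  intersections <- vapply(combos, function(cmb) {
    sum(Reduce(`&`, lapply(sets[cmb], function(s) s[ids])))
  }, numeric(1))
  names(intersections) <- vapply(combos, paste, character(1), collapse = "+")
  list(membership = membership, intersections = intersections)
}
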