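## Promoter hypermethylation and epigenetic-silencing calls from
## methylation beta values coupled with expression.

#' Summarize promoter-probe methylation
#'
#' Aggregates probe-level beta values flagged as promoter probes into a
#' single per-gene value. The default is the mean, which stays on the
#' `[0, 1]` beta scale that the hypermethylation threshold is defined on;
#' `mode = "sum"` is provided for compatibility with summed-probe
#' conventions but can exceed 1 for multi-probe promoters.
#'
#' @param probes data.frame with `probe_beta` and logical `in_promoter`.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return summarized value, or `NA` (missing-data marker) when no
#'   promoter probe is present.
#' @export
summarize_promoter <- function(probes, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  check_columns(probes, c("probe_beta", "in_promoter"), "probe table")
  b <- probes$probe_beta[probes$in_promoter]
  if (length(b) == 0L) return(NA_real_)
  if (mode == "mean") mean(b) else sum(b)
}

#' Call promoter hypermethylation and epigenetic silencing
#'
#' A gene is hypermethylated in a sample when its summarized promoter
#' beta is at least `beta_cut` (inclusive), and epigenetically silenced
#' when additionally its expression is below `fpkm_cut` (strict): the
#' two-channel definition requires both the epigenetic mark and the
#' transcriptional consequence. Missing inputs yield `NA` calls, which
#' downstream tallies exclude.
#'
#' @param beta_summary numeric vector of summarized promoter beta values.
#' @param fpkm matched numeric vector of expression values.
#' @param beta_cut hypermethylation threshold (default 0.75, inclusive).
#' @param fpkm_cut silencing expression threshold (default 1.0, strict
#'   `<`).
#' @param sample,gene optional id vectors carried into the output.
#' @return data.frame with `sample`, `gene`, `beta_summary`,
#'   `expressed_fpkm`, `hypermethylated`, `silenced`.
#' @export
#' @examples
#' call_silencing(c(0.75, 0.74, 0.9), c(0.5, 0.5, 1.0))
call_silencing <- function(beta_summary, fpkm, beta_cut = 0.75,
                           fpkm_cut = 1.0, sample = NA_character_,
                           gene = NA_character_) {
  if (length(beta_summary) != length(fpkm)) {
    stop_data("beta and expression vectors differ in length")
  }
  hyper <- beta_summary >= beta_cut
  silenced <- hyper & fpkm < fpkm_cut
  missing <- is.na(beta_summary) | is.na(fpkm)
  hyper[missing] <- NA
  silenced[missing] <- NA
  data.frame(sample = sample, gene = gene, beta_summary = beta_summary,
             expressed_fpkm = fpkm, hypermethylated = hyper,
             silenced = silenced, stringsAsFactors = FALSE)
}

#' Silencing calls for a cohort methylation table
#'
#' @param methylation data.frame with `sample`, `gene`, `beta_summary`.
#' @param expr genes x samples FPKM matrix.
#' @param ... thresholds passed to [call_silencing()].
#' @return data.frame of per-(sample, gene) calls; pairs without matched
#'   expression are `NA` and excluded from tallies.
#' @export
silencing_calls <- function(methylation, expr, ...) {
  check_columns(methylation, c("sample", "gene", "beta_summary"),
                "methylation table")
  fpkm <- rep(NA_real_, nrow(methylation))
  ok <- methylation$gene %in% rownames(expr) &
    methylation$sample %in% colnames(expr)
  fpkm[ok] <- expr[cbind(methylation$gene[ok], methylation$sample[ok])]
  call_silencing(methylation$beta_summary, fpkm, ...,
                 sample = methylation$sample, gene = methylation$gene)
}
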