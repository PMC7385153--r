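#!/usr/bin/env Rscript
# DNA-damage-response gene alterations: the germline truncating-variant
# filter cascade over the 11-gene panel, and epigenetic-silencing calls
# from promoter methylation coupled with expression.

source("analysis/00_config.R")

cohort <- simulate_cohort(analysis_config())

res <- suppressWarnings(run_cascade(cohort$germline_candidates))
message("Cascade: ", nrow(cohort$germline_candidates), " candidates in, ",
        nrow(res$survivors), " truncating panel variants survive.")
write_result(res$survivors, "04_germline_survivors.tsv")
write_result(res$trace, "04_germline_trace.tsv")

drop_reasons <- table(res$trace$first_failing_rule[
  res$trace$final_status == "fail"])
write_result(as.data.frame(drop_reasons), "04_first_failing_rule.tsv")
message("First failing rule among removed candidates: ",
        paste(sprintf("%s:%d", names(drop_reasons), drop_reasons),
              collapse = ", "))

gene_tally <- as.data.frame(table(gene = res$survivors$gene))
write_result(gene_tally, "04_survivors_by_gene.tsv")

calls <- silencing_calls(cohort$methylation, cohort$fpkm)
silenced <- calls[calls$silenced %in% TRUE, ]
hyper_only <- sum(calls$hypermethylated %in% TRUE) - nrow(silenced)
message("Silencing: ", nrow(silenced), " silenced gene-sample pairs (beta >= 0.75 and FPKM < 1); ",
        hyper_only, " hypermethylated-but-expressed pair(s).")
write_result(silenced, "04_silencing_calls.tsv")
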