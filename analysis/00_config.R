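# Shared settings for the analysis scripts: one cohort configuration,
# simulated deterministically wherever a script needs it.
library(hrdpipe)

ANALYSIS_SEED <- 101L

analysis_config <- function() {
  sim_config(n_samples = 200L, seed = ANALYSIS_SEED)
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

write_result <- function(df, name) {
  path <- file.path(results_dir(), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("  wrote ", path)
}
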