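#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate code with a locally seeded RNG
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# stop() with a consistent prefix naming the offending field/value
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration [%s]: %s", field, msg), call. = FALSE)
}

stop_data <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

# require named columns on a data.frame
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_data("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", "))
  }
  invisible(df)
}

# derive a stream-specific 32-bit sub-seed from a master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 977L + as.integer(stream) * 7919L) %% 2147483647L
}

#' Normalize chromosome names
#'
#' Harmonizes the "chr1" / "1" dialects found in MAF and segment files.
#'
#' @param x character vector of chromosome names.
#' @param style `"strip"` removes a leading "chr", `"add"` prepends it,
#'   `"none"` leaves names untouched.
#' @return character vector of normalized names.
#' @export
normalize_chromosomes <- function(x, style = c("strip", "add", "none")) {
  style <- match.arg(style)
  x <- as.character(x)
  if (style == "none") return(x)
  bare <- sub("^chr", "", x, ignore.case = TRUE)
  if (style == "strip") bare else paste0("chr", bare)
}

# write a data.frame as plain TSV (the interchange format used throughout)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
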