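## 96-trinucleotide mutation catalogs (COSMIC channel ordering).

#' The 96 COSMIC trinucleotide mutation contexts
#'
#' Channel order is the COSMIC convention: the six pyrimidine-reference
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each crossed with the 16
#' combinations of 5' and 3' flanking bases in alphabetical order, written
#' as e.g. `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
#' @examples
#' head(trinucleotide_contexts())
trinucleotide_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))
  }))
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# coerce a reference (named character vector or Biostrings::DNAStringSet)
# to a named character vector of chromosome sequences
.as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else if (is.character(reference) && !is.null(names(reference))) {
    toupper(reference)
  } else {
    stop_data("reference must be a named character vector or DNAStringSet")
  }
}

#' Pyrimidine-normalized trinucleotide context of a substitution
#'
#' Looks up the bases flanking a single-nucleotide substitution in the
#' reference and returns its channel among the 96 COSMIC contexts. When the
#' reference base is a purine, base and flanks are reverse-complemented so
#' every substitution is expressed relative to the pyrimidine strand.
#'
#' @param chrom chromosome name (must match a reference sequence name).
#' @param pos 1-based position of the substituted base.
#' @param ref,alt single reference / alternate bases.
#' @param reference named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return one of the 96 context strings, or `NA_character_` (with a
#'   warning) when the site has no 5' or 3' neighbour.
#' @export
#' @examples
#' trinucleotide_context("s", 2, "C", "T", c(s = "ACGTA"))
trinucleotide_context <- function(chrom, pos, ref, alt, reference) {
  reference <- .as_reference(reference)
  if (!chrom %in% names(reference)) {
    stop_data("chromosome '%s' not present in reference", chrom)
  }
  seqlen <- nchar(reference[[chrom]])
  if (pos < 1L || pos > seqlen) {
    stop_data("position %s:%d outside reference (length %d)", chrom, pos, seqlen)
  }
  if (pos == 1L || pos == seqlen) {
    warning(sprintf("site %s:%d lacks a flanking base; skipped", chrom, pos))
    return(NA_character_)
  }
  tri <- toupper(substr(reference[[chrom]], pos - 1L, pos + 1L))
  ref <- toupper(ref); alt <- toupper(alt)
  if (substr(tri, 2, 2) != ref) {
    stop_data("reference mismatch at %s:%d (reference has %s, record says %s)",
              chrom, pos, substr(tri, 2, 2), ref)
  }
  if (ref %in% c("A", "G")) {
    tri <- .revcomp(tri)
    ref <- .complement(ref)
    alt <- .complement(alt)
  }
  paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
}

# vectorized internal version used by build_catalog; returns NA for edge
# sites (warned about by the caller) and errors on reference mismatch
.contexts_vectorized <- function(chrom, pos, ref, alt, reference) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(reference)) {
      stop_data("chromosome '%s' not present in reference", ch)
    }
    seqstr <- reference[[ch]]
    seqlen <- nchar(seqstr)
    bad <- pos[idx] < 1L | pos[idx] > seqlen
    if (any(bad)) {
      stop_data("position %s:%d outside reference (length %d)",
                ch, pos[idx][bad][1], seqlen)
    }
    edge <- pos[idx] == 1L | pos[idx] == seqlen
    keep <- idx[!edge]
    if (length(keep) == 0L) next
    p <- pos[keep]
    tri <- substring(seqstr, p - 1L, p + 1L)
    mid <- substr(tri, 2, 2)
    mism <- mid != ref[keep]
    if (any(mism)) {
      j <- keep[mism][1]
      stop_data("reference mismatch at %s:%d (reference has %s, record says %s)",
                ch, pos[j], substr(tri[mism][1], 2, 2), ref[j])
    }
    r <- ref[keep]; a <- alt[keep]
    flip <- r %in% c("A", "G")
    tri[flip] <- .revcomp(tri[flip])
    r[flip] <- .complement(r[flip])
    a[flip] <- .complement(a[flip])
    out[keep] <- paste0(substr(tri, 1, 1), "[", r, ">", a, "]",
                        substr(tri, 3, 3))
  }
  out
}

#' Keep mutations supported by a minimum number of variant callers
#'
#' Consensus filtering over the caller annotations of a somatic mutation
#' table: a mutation is retained when its caller set has at least
#' `min_callers` members. The TCGA-style convention of requiring support
#' from two of Mutect, MuSE, SomaticSniper and VarScan corresponds to the
#' default `min_callers = 2`.
#'
#' @param mutations data.frame with at least a `callers` column; callers
#'   may be a list-column of character vectors or strings with `,`/`;`/`|`
#'   separators.
#' @param min_callers minimum caller-set size (>= 1).
#' @return the input data.frame, row-subset in original order.
#' @export
consensus_filter <- function(mutations, min_callers = 2L) {
  if (min_callers < 1L) stop_config("min_callers", "must be >= 1")
  check_columns(mutations, "callers", "mutation table")
  n <- caller_count(mutations$callers)
  mutations[n >= min_callers, , drop = FALSE]
}

# number of distinct callers per record
caller_count <- function(callers) {
  if (is.list(callers)) {
    vapply(callers, function(x) length(unique(x[nzchar(x)])), integer(1))
  } else {
    vapply(strsplit(as.character(callers), "[,;|]"), function(x) {
      x <- trimws(x)
      length(unique(x[nzchar(x)]))
    }, integer(1))
  }
}

#' Build a sample x 96 trinucleotide catalog
#'
#' Tallies consensus-filtered single-nucleotide variants into the 96
#' COSMIC contexts per sample. Non-SNV records (indels, multi-nucleotide
#' substitutions) are dropped with a message; sites at sequence edges are
#' skipped with a warning. Samples listed in `samples` but absent from the
#' table are kept as zero rows.
#'
#' @param mutations data.frame with columns `sample`, `chrom`, `pos`,
#'   `ref`, `alt` (1-based positions, MAF convention).
#' @param reference named character vector of chromosome sequences or a
#'   [Biostrings::DNAStringSet].
#' @param samples optional character vector fixing the row set/order.
#' @param chrom_style chromosome-name normalization applied to both the
#'   mutation table and the reference names (see [normalize_chromosomes()]).
#' @return a `trinuc_catalog`: list with `samples`, integer `counts`
#'   matrix (samples x 96) and `context_order`.
#' @export
build_catalog <- function(mutations, reference, samples = NULL,
                          chrom_style = c("none", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  check_columns(mutations, c("sample", "chrom", "pos", "ref", "alt"),
                "mutation table")
  reference <- .as_reference(reference)
  if (chrom_style != "none") {
    mutations$chrom <- normalize_chromosomes(mutations$chrom, chrom_style)
    names(reference) <- normalize_chromosomes(names(reference), chrom_style)
  }
  contexts <- trinucleotide_contexts()
  if (is.null(samples)) samples <- unique(as.character(mutations$sample))
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, contexts))
  if (nrow(mutations) > 0L) {
    is_snv <- nchar(mutations$ref) == 1L & nchar(mutations$alt) == 1L &
      mutations$ref %in% c("A", "C", "G", "T") &
      mutations$alt %in% c("A", "C", "G", "T") &
      mutations$ref != mutations$alt
    if (any(!is_snv)) {
      message(sprintf("build_catalog: dropped %d non-SNV record(s)",
                      sum(!is_snv)))
    }
    snv <- mutations[is_snv, , drop = FALSE]
    if (nrow(snv) > 0L) {
      ctx <- .contexts_vectorized(as.character(snv$chrom), as.integer(snv$pos),
                                  toupper(snv$ref), toupper(snv$alt), reference)
      if (anyNA(ctx)) {
        warning(sprintf("build_catalog: skipped %d edge site(s) without flanks",
                        sum(is.na(ctx))))
      }
      keep <- !is.na(ctx) & as.character(snv$sample) %in% samples
      tab <- table(factor(as.character(snv$sample)[keep], levels = samples),
                   factor(ctx[keep], levels = contexts))
      counts <- counts + unclass(tab)
    }
  }
  structure(list(samples = samples, counts = counts,
                 context_order = contexts),
            class = "trinuc_catalog")
}

#' @export
print.trinuc_catalog <- function(x, ...) {
  cat(sprintf("trinuc_catalog: %d sample(s) x 96 contexts, %d SNVs total\n",
              length(x$samples), sum(x$counts)))
  invisible(x)
}

#' Exclude hypermutated samples from a catalog
#'
#' Removes samples whose total catalogued SNV count reaches `max_snv`
#' (inclusive), the exclusion applied to ultra-mutated tumors before
#' signature extraction.
#'
#' @param catalog a `trinuc_catalog`.
#' @param max_snv exclusion threshold; samples with row sum >= `max_snv`
#'   are removed. Default 5800.
#' @return list with elements `catalog` (filtered) and `excluded`
#'   (character vector of removed sample ids).
#' @export
exclude_hypermutants <- function(catalog, max_snv = 5800L) {
  stopifnot(inherits(catalog, "trinuc_catalog"))
  totals <- rowSums(catalog$counts)
  drop <- totals >= max_snv
  out <- catalog
  out$samples <- catalog$samples[!drop]
  out$counts <- catalog$counts[!drop, , drop = FALSE]
  list(catalog = out, excluded = catalog$samples[drop])
}

#' Subset a catalog to a set of samples
#' @param catalog a `trinuc_catalog`.
#' @param samples sample ids to keep (order preserved as given).
#' @return a `trinuc_catalog`.
#' @export
subset_catalog <- function(catalog, samples) {
  stopifnot(inherits(catalog, "trinuc_catalog"))
  missing <- setdiff(samples, catalog$samples)
  if (length(missing) > 0L) {
    stop_data("samples not in catalog: %s", paste(missing, collapse = ", "))
  }
  structure(list(samples = samples,
                 counts = catalog$counts[samples, , drop = FALSE],
                 context_order = catalog$context_order),
            class = "trinuc_catalog")
}

#' Write / read a catalog as TSV (96 context rows, samples as columns)
#' @param catalog a `trinuc_catalog`.
#' @param path file path.
#' @return `path` (write) or a `trinuc_catalog` (read).
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(context = catalog$context_order,
                   t(catalog$counts), check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv(path)
  contexts <- trinucleotide_contexts()
  if (!identical(df$context, contexts)) {
    stop_data("catalog file does not follow the 96-context COSMIC ordering")
  }
  counts <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(counts) <- "integer"
  colnames(counts) <- contexts
  structure(list(samples = rownames(counts), counts = counts,
                 context_order = contexts),
            class = "trinuc_catalog")
}
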