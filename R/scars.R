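## Genomic-scar HRD components (LOH, TAI, LST) from allele-specific
## copy-number segments, and the recombination proficiency score (RPS).
##
## The three component definitions follow the standard published scar
## algorithms (large non-whole-chromosome LOH; allelic imbalance extending
## to a telomere without crossing the centromere; large-scale transitions
## between big adjacent segments after small-segment smoothing). All
## length parameters are exposed as arguments. LST counts are raw
## breakpoint counts: no ploidy-dependent offset is subtracted.

# validate one sample's segment table and sort by (chrom, start)
.check_segments <- function(segments) {
  check_columns(segments, c("chrom", "start", "end", "major_cn", "minor_cn"),
                "segment table")
  if (nrow(segments) == 0L) return(segments)
  if (any(segments$start > segments$end)) {
    stop_data("segment with start > end")
  }
  if (any(segments$major_cn < 0 | segments$minor_cn < 0)) {
    stop_data("negative copy number in segment table")
  }
  if (any(segments$minor_cn > segments$major_cn)) {
    stop_data("minor_cn exceeds major_cn; allele columns must be ordered")
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop_data("overlapping segments on chromosome %s", ch)
    }
  }
  segments
}

.seg_len <- function(segments) segments$end - segments$start + 1

# genome_meta: data.frame(chrom, length, centro_start, centro_end)
.check_genome <- function(genome_meta) {
  check_columns(genome_meta, c("chrom", "length", "centro_start", "centro_end"),
                "genome metadata")
  genome_meta
}

#' Count large loss-of-heterozygosity segments
#'
#' LOH scar events: segments with minor copy number 0 that are longer
#' than `min_len` and do not span an entire chromosome (whole-chromosome
#' LOH reflects aneuploidy, not recombination-repair failure).
#'
#' @param segments one sample's segments: data.frame with `chrom`,
#'   `start`, `end` (1-based inclusive bp), `major_cn`, `minor_cn`.
#' @param genome_meta data.frame with `chrom`, `length`, `centro_start`,
#'   `centro_end`.
#' @param min_len minimum length in bp (default 15 Mb); events must be
#'   strictly longer.
#' @return integer count.
#' @export
count_loh <- function(segments, genome_meta, min_len = 15e6) {
  segments <- .check_segments(segments)
  genome_meta <- .check_genome(genome_meta)
  if (nrow(segments) == 0L) return(0L)
  chrlen <- stats::setNames(genome_meta$length, genome_meta$chrom)
  is_loh <- segments$minor_cn == 0
  long_enough <- .seg_len(segments) > min_len
  whole <- segments$start == 1 & segments$end == chrlen[segments$chrom]
  sum(is_loh & long_enough & !whole, na.rm = TRUE)
}

#' Count telomeric allelic-imbalance segments
#'
#' TAI scar events: allelic-imbalance segments (major != minor copy
#' number) longer than `min_len` that extend to a chromosome end and do
#' not cross the centromere.
#'
#' @inheritParams count_loh
#' @param min_len minimum length in bp (default 11 Mb), strict.
#' @return integer count.
#' @export
count_tai <- function(segments, genome_meta, min_len = 11e6) {
  segments <- .check_segments(segments)
  genome_meta <- .check_genome(genome_meta)
  if (any(is.na(genome_meta$centro_start)) || any(is.na(genome_meta$centro_end))) {
    stop_config("genome_meta", "centromere intervals are required for TAI")
  }
  if (nrow(segments) == 0L) return(0L)
  meta <- genome_meta[match(segments$chrom, genome_meta$chrom), ]
  if (anyNA(meta$length)) {
    stop_data("segment chromosome missing from genome metadata")
  }
  imbalanced <- segments$major_cn != segments$minor_cn
  long_enough <- .seg_len(segments) > min_len
  at_end <- segments$start == 1 | segments$end == meta$length
  crosses_centro <- segments$start <= meta$centro_end &
    segments$end >= meta$centro_start
  # a whole-chromosome segment necessarily crosses the centromere, so the
  # centromere rule already excludes it
  sum(imbalanced & long_enough & at_end & !crosses_centro)
}

# split a sample's segments into chromosome-arm pieces at the centromere
# midpoint; returns segments with an added `arm` column
.split_arms <- function(segments, genome_meta) {
  meta <- genome_meta[match(segments$chrom, genome_meta$chrom), ]
  mid <- floor((meta$centro_start + meta$centro_end) / 2)
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, , drop = FALSE]
    m <- mid[i]
    if (s$end <= m) {
      s$arm <- paste0(s$chrom, "p"); pieces[[length(pieces) + 1L]] <- s
    } else if (s$start > m) {
      s$arm <- paste0(s$chrom, "q"); pieces[[length(pieces) + 1L]] <- s
    } else {
      p <- s; p$end <- m; p$arm <- paste0(s$chrom, "p")
      q <- s; q$start <- m + 1; q$arm <- paste0(s$chrom, "q")
      pieces[[length(pieces) + 1L]] <- p
      pieces[[length(pieces) + 1L]] <- q
    }
  }
  do.call(rbind, pieces)
}

#' Count large-scale state transitions
#'
#' LST scar events: breakpoints between adjacent segments in different
#' allele-specific copy-number states, where both segments are at least
#' `min_seg` long and the gap between them is at most `max_gap`, counted
#' per chromosome arm. Before counting, segments shorter than
#' `smooth_below` are removed and adjacent same-state segments merged
#' (small-segment smoothing).
#'
#' @inheritParams count_loh
#' @param min_seg minimum flanking-segment length (default 10 Mb,
#'   inclusive).
#' @param max_gap maximum inter-segment gap (default 3 Mb).
#' @param smooth_below segments shorter than this are smoothed away
#'   (default 3 Mb).
#' @return integer count.
#' @export
count_lst <- function(segments, genome_meta, min_seg = 10e6, max_gap = 3e6,
                      smooth_below = 3e6) {
  segments <- .check_segments(segments)
  genome_meta <- .check_genome(genome_meta)
  if (nrow(segments) == 0L) return(0L)
  armed <- .split_arms(segments, genome_meta)
  n_lst <- 0L
  for (arm in unique(armed$arm)) {
    s <- armed[armed$arm == arm, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    # smoothing: drop sub-threshold segments, then merge same-state runs
    s <- s[.seg_len(s) >= smooth_below, , drop = FALSE]
    if (nrow(s) > 1L) {
      merged <- s[1, , drop = FALSE]
      for (i in 2:nrow(s)) {
        last <- nrow(merged)
        if (s$major_cn[i] == merged$major_cn[last] &&
            s$minor_cn[i] == merged$minor_cn[last]) {
          merged$end[last] <- s$end[i]
        } else {
          merged <- rbind(merged, s[i, , drop = FALSE])
        }
      }
      s <- merged
    }
    if (nrow(s) < 2L) next
    len <- .seg_len(s)
    for (i in seq_len(nrow(s) - 1L)) {
      gap <- s$start[i + 1L] - s$end[i] - 1
      state_change <- s$major_cn[i] != s$major_cn[i + 1L] ||
        s$minor_cn[i] != s$minor_cn[i + 1L]
      if (state_change && len[i] >= min_seg && len[i + 1L] >= min_seg &&
          gap <= max_gap) {
        n_lst <- n_lst + 1L
      }
    }
  }
  n_lst
}

#' Per-sample HRD scar score
#'
#' Sums the three scar components computed from segments, or passes an
#' imported published score through with a source flag. Computed and
#' imported scores are never silently mixed: supplying both with
#' disagreeing values is an error.
#'
#' @param segments one sample's segment data.frame, or `NULL` when only
#'   an imported score is available.
#' @param genome_meta genome metadata (required with `segments`).
#' @param imported optional imported HRD score (single number).
#' @param sample sample id carried into the record.
#' @param loh_min,tai_min,lst_min_seg,lst_max_gap,lst_smooth component
#'   length parameters, in bp (see the individual counters).
#' @return data.frame with `sample`, `loh_count`, `tai_count`,
#'   `lst_count`, `hrd_sum`, `source` (`"computed"` or `"imported"`;
#'   component counts are `NA` for imported scores).
#' @export
hrd_sum <- function(segments = NULL, genome_meta = NULL, imported = NULL,
                    sample = NA_character_, loh_min = 15e6, tai_min = 11e6,
                    lst_min_seg = 10e6, lst_max_gap = 3e6, lst_smooth = 3e6) {
  if (is.null(segments) && is.null(imported)) {
    stop_data("either segments or an imported HRD score must be supplied")
  }
  if (!is.null(segments)) {
    loh <- count_loh(segments, genome_meta, loh_min)
    tai <- count_tai(segments, genome_meta, tai_min)
    lst <- count_lst(segments, genome_meta, lst_min_seg, lst_max_gap, lst_smooth)
    computed <- loh + tai + lst
    if (!is.null(imported) && imported != computed) {
      stop_data("imported HRD score (%s) conflicts with computed score (%s) for sample %s",
                imported, computed, sample)
    }
    data.frame(sample = sample, loh_count = loh, tai_count = tai,
               lst_count = lst, hrd_sum = computed, source = "computed",
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample = sample, loh_count = NA_integer_,
               tai_count = NA_integer_, lst_count = NA_integer_,
               hrd_sum = imported, source = "imported",
               stringsAsFactors = FALSE)
  }
}

#' HRD scar scores for a whole cohort
#'
#' @param segments segment data.frame with a `sample` column.
#' @param genome_meta genome metadata.
#' @param samples optional id vector fixing the output rows (samples with
#'   no segments get zero counts).
#' @param ... length parameters passed to [hrd_sum()].
#' @return data.frame of per-sample [hrd_sum()] records.
#' @export
hrd_scores <- function(segments, genome_meta, samples = NULL, ...) {
  check_columns(segments, "sample", "segment table")
  if (is.null(samples)) samples <- unique(segments$sample)
  out <- lapply(samples, function(sm) {
    hrd_sum(segments[segments$sample == sm, , drop = FALSE],
            genome_meta, sample = sm, ...)
  })
  do.call(rbind, out)
}

.rps_genes <- c("RIF1", "PARPBP", "RAD51", "XRCC5")

# pull the four RPS gene expression values for every sample
.rps_inputs <- function(expr) {
  missing <- setdiff(.rps_genes, rownames(expr))
  if (length(missing) > 0L) {
    stop_data("expression matrix lacks RPS gene(s): %s",
              paste(missing, collapse = ", "))
  }
  expr[.rps_genes, , drop = FALSE]
}

#' Recombination proficiency score
#'
#' `RPS = -(RIF1 + PARPBP + RAD51 + XRCC5)`, the negated sum of the
#' expression (FPKM) of four genes governing the choice between
#' homologous recombination and error-prone end-joining repair. Lower
#' (more negative) scores indicate higher expression of these genes.
#'
#' @param expr genes x samples expression matrix (FPKM, non-negative)
#'   containing the four RPS genes in its rownames.
#' @return named numeric vector of per-sample scores (always <= 0 for
#'   non-negative expression).
#' @export
#' @examples
#' m <- matrix(c(2, 3, 4, 1), 4, 1,
#'             dimnames = list(c("RIF1", "PARPBP", "RAD51", "XRCC5"), "s1"))
#' rps(m)  # -10
rps <- function(expr) {
  x <- .rps_inputs(expr)
  -colSums(x)
}

# weights of the trained (beta) variant of the score; they sum to 1
.rps_beta_weights <- c(RIF1 = 0.2171423, PARPBP = 0.1946173,
                       RAD51 = 0.2783017, XRCC5 = 0.3099387)

#' Weighted recombination proficiency score
#'
#' The coefficient-weighted variant:
#' `RPS_beta = -(0.2171423 RIF1 + 0.1946173 PARPBP + 0.2783017 RAD51 +
#' 0.3099387 XRCC5)`. The four coefficients sum to exactly 1, so uniform
#' unit expression yields -1.
#'
#' @inheritParams rps
#' @return named numeric vector of per-sample scores.
#' @export
rps_beta <- function(expr) {
  x <- .rps_inputs(expr)
  -colSums(x * .rps_beta_weights[rownames(x)])
}

#' Read an imported HRD score table (sample, hrd_score TSV)
#' @param path file path.
#' @return data.frame of [hrd_sum()] records with source `"imported"`.
#' @export
read_hrd_scores <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("sample", "hrd_score"), "HRD score table")
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    hrd_sum(imported = df$hrd_score[i], sample = df$sample[i])
  }))
}
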