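## Synthetic TCGA-like cohort generator with a ground-truth ledger.
## Every downstream stage (catalog, signatures, scars, germline,
## silencing, statistics, classification) can be exercised against known
## truth without external data.

#' Default synthetic genome geometry
#'
#' Six chromosomes of 100-160 Mb with stated centromere intervals. Six
#' (rather than the minimal three) keeps enough telomeres and arm space
#' to place group-level scar burdens without saturating the geometry.
#'
#' @return data.frame with `chrom`, `length`, `centro_start`,
#'   `centro_end` (bp).
#' @export
synthetic_genome <- function() {
  mids <- c(80, 70, 60, 60, 50, 45) * 1e6
  data.frame(chrom = paste0("chr", 1:6),
             length = c(160, 150, 140, 130, 120, 100) * 1e6,
             centro_start = mids - 1.5e6,
             centro_end = mids + 1.5e6,
             stringsAsFactors = FALSE)
}

.sim_groups <- c("BRCA1mut", "BRCA2mut", "HRDwt", "nonHRD")
.pam50_levels <- c("Basal", "Her2", "LumA", "LumB", "Normal")

.default_mixtures <- function() {
  hrd <- c(CpG = 0.15, APOBEC = 0.10, BRCA = 0.65, MSI = 0.10)
  non <- c(CpG = 0.50, APOBEC = 0.30, BRCA = 0.10, MSI = 0.10)
  rbind(BRCA1mut = hrd, BRCA2mut = hrd, HRDwt = hrd, nonHRD = non)
}

.default_scar_rates <- function() {
  rbind(BRCA1mut = c(loh = 12, tai = 6, lst = 10),
        BRCA2mut = c(loh = 10, tai = 5, lst = 9),
        HRDwt    = c(loh = 9,  tai = 5, lst = 8),
        nonHRD   = c(loh = 2,  tai = 1, lst = 2))
}

.default_subtype_probs <- function() {
  rbind(BRCA1mut = c(0.75, 0.05, 0.05, 0.10, 0.05),
        BRCA2mut = c(0.25, 0.10, 0.30, 0.30, 0.05),
        HRDwt    = c(0.50, 0.15, 0.10, 0.20, 0.05),
        nonHRD   = c(0.08, 0.10, 0.45, 0.25, 0.12))
}

.deg_genes_b2 <- sprintf("DEGB2_%03d", 1:20)
.deg_genes_b1 <- sprintf("DEGB1_%03d", 1:10)

.default_fold_changes <- function() {
  hrd_shifts <- c(stats::setNames(rep(0.7, 4), .rps_genes),
                  stats::setNames(rep(1.0, 6), .ifng_genes))
  list(BRCA1mut = c(stats::setNames(rep(2, 10), .deg_genes_b1), hrd_shifts),
       BRCA2mut = c(stats::setNames(rep(2, 20), .deg_genes_b2), hrd_shifts),
       HRDwt = hrd_shifts)
}

#' Build and validate a simulation configuration
#'
#' Defaults describe a breast-cancer-like cohort of 200 tumors: four
#' groups (BRCA1/BRCA2 germline carriers, BRCA-wild-type HRD, and
#' non-HRD), four mutational processes with HRD groups dominated by the
#' BRCA-signature, group-specific genomic-scar burdens, expression shifts
#' for the recombination-proficiency and immune genes plus planted
#' differentially expressed gene sets, and coupled
#' promoter-methylation/expression silencing events.
#'
#' @param n_samples cohort size (>= 2).
#' @param seed integer master seed; all randomness derives from it.
#' @param group_sizes named integer vector over
#'   `BRCA1mut/BRCA2mut/HRDwt/nonHRD` summing to `n_samples`; default
#'   proportions 5/6/9/80%.
#' @param signature_mixtures group x signature matrix of mean mixture
#'   weights (rows sum to 1).
#' @param true_signatures signature x 96 profile matrix.
#' @param exposure_concentration Dirichlet concentration of per-sample
#'   weights around the group mean (smaller = more sample-to-sample
#'   spread).
#' @param mutations_per_sample single count or `c(min, max)` range.
#' @param caller_decoys single-caller decoy mutation rows added per
#'   sample (removed by consensus filtering).
#' @param scar_rate_params group x 3 matrix of expected LOH/TAI/LST
#'   counts.
#' @param scar_mode `"stochastic"` draws per-sample scar counts Poisson;
#'   `"deterministic"` places exactly the configured counts.
#' @param scar_decoys also place non-qualifying decoy segments.
#' @param expr_fold_changes named list: group -> named vector of log2
#'   expression shifts.
#' @param expr_sigma log2-scale expression noise SD.
#' @param n_background_genes unshifted filler genes.
#' @param silencing_fraction fraction of samples with a coupled
#'   beta >= 0.75 / FPKM < 1 silencing event at `silencing_gene`.
#' @param silencing_gene gene receiving silencing events.
#' @param subtype_probs group x 5 PAM50 subtype probability matrix.
#' @param genome genome geometry (see [synthetic_genome()]).
#' @param context_seq_len length of the synthetic context reference
#'   sequence generated per chromosome, bp.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 200L, seed = 1L, group_sizes = NULL,
                       signature_mixtures = .default_mixtures(),
                       true_signatures = default_true_signatures(),
                       exposure_concentration = 2,
                       mutations_per_sample = c(500L, 2000L),
                       caller_decoys = 3L,
                       scar_rate_params = .default_scar_rates(),
                       scar_mode = c("stochastic", "deterministic"),
                       scar_decoys = TRUE,
                       expr_fold_changes = .default_fold_changes(),
                       expr_sigma = 0.5, n_background_genes = 500L,
                       silencing_fraction = 0.05,
                       silencing_gene = "RAD51C",
                       subtype_probs = .default_subtype_probs(),
                       genome = synthetic_genome(),
                       context_seq_len = 60000L) {
  scar_mode <- match.arg(scar_mode)
  if (!is.numeric(n_samples) || n_samples < 2L) {
    stop_config("n_samples", "must be >= 2")
  }
  n_samples <- as.integer(n_samples)
  if (is.null(group_sizes)) {
    props <- c(BRCA1mut = 0.05, BRCA2mut = 0.06, HRDwt = 0.09, nonHRD = 0.80)
    group_sizes <- floor(props * n_samples)
    group_sizes["nonHRD"] <- n_samples - sum(group_sizes[1:3])
  }
  if (sum(group_sizes) != n_samples) {
    stop_config("group_sizes", "must sum to n_samples")
  }
  groups <- names(group_sizes)[group_sizes > 0]
  if (!all(groups %in% rownames(signature_mixtures))) {
    stop_config("signature_mixtures", "missing rows for some groups")
  }
  if (any(signature_mixtures < 0)) {
    stop_config("signature_mixtures", "weights must be non-negative")
  }
  if (any(abs(rowSums(signature_mixtures) - 1) > 1e-9)) {
    stop_config("signature_mixtures", "rows must sum to 1 within 1e-9")
  }
  if (ncol(signature_mixtures) != nrow(true_signatures)) {
    stop_config("signature_mixtures",
                "column count must match number of true signatures")
  }
  if (any(abs(rowSums(true_signatures) - 1) > 1e-6)) {
    stop_config("true_signatures", "profiles must sum to 1")
  }
  if (!all(groups %in% rownames(scar_rate_params))) {
    stop_config("scar_rate_params", "missing rows for some groups")
  }
  if (length(mutations_per_sample) == 1L) {
    mutations_per_sample <- rep(mutations_per_sample, 2L)
  }
  if (mutations_per_sample[1] < 1L) {
    stop_config("mutations_per_sample", "must be positive")
  }
  .check_genome(genome)
  centro_span <- genome$centro_end - genome$centro_start + 1
  if (any(genome$length <= 2 * centro_span) ||
      any(genome$centro_start <= 1) ||
      any(genome$centro_end >= genome$length)) {
    stop_config("genome", "chromosome lengths must exceed twice the centromere span, with the centromere interior")
  }
  if (silencing_fraction < 0 || silencing_fraction > 1) {
    stop_config("silencing_fraction", "must be in [0, 1]")
  }
  structure(list(n_samples = n_samples, seed = as.integer(seed),
                 group_sizes = group_sizes,
                 signature_mixtures = signature_mixtures,
                 true_signatures = true_signatures,
                 exposure_concentration = exposure_concentration,
                 mutations_per_sample = as.integer(mutations_per_sample),
                 caller_decoys = as.integer(caller_decoys),
                 scar_rate_params = scar_rate_params,
                 scar_mode = scar_mode, scar_decoys = scar_decoys,
                 expr_fold_changes = expr_fold_changes,
                 expr_sigma = expr_sigma,
                 n_background_genes = as.integer(n_background_genes),
                 silencing_fraction = silencing_fraction,
                 silencing_gene = silencing_gene,
                 subtype_probs = subtype_probs, genome = genome,
                 context_seq_len = as.integer(context_seq_len)),
            class = "sim_config")
}

# ---- context reference and trinucleotide position index ----------------

.random_reference <- function(genome, seq_len) {
  stats::setNames(
    vapply(seq_len(nrow(genome)), function(i) {
      paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
            collapse = "")
    }, character(1)),
    genome$chrom)
}

# position lists per trinucleotide (center base at the reported position)
.trinuc_index <- function(reference) {
  idx <- list()
  for (ch in names(reference)) {
    chars <- strsplit(reference[[ch]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    tri <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
    by_tri <- split(2:(n - 1L), tri)
    for (t in names(by_tri)) {
      idx[[t]] <- rbind(idx[[t]],
                        data.frame(chrom = ch, pos = by_tri[[t]],
                                   stringsAsFactors = FALSE))
    }
  }
  idx
}

# realize `count` genomic sites for one pyrimidine context, using either
# strand representation of the site
.draw_sites <- function(context, count, tri_index) {
  f5 <- substr(context, 1, 1); ref <- substr(context, 3, 3)
  alt <- substr(context, 5, 5); f3 <- substr(context, 7, 7)
  pyr_tri <- paste0(f5, ref, f3)
  pur_tri <- .revcomp(pyr_tri)
  pool_pyr <- tri_index[[pyr_tri]]
  pool_pur <- if (pur_tri != pyr_tri) tri_index[[pur_tri]] else NULL
  n_pyr <- if (is.null(pool_pyr)) 0L else nrow(pool_pyr)
  n_pur <- if (is.null(pool_pur)) 0L else nrow(pool_pur)
  if (n_pyr + n_pur == 0L) {
    stop_data("context reference contains no site for trinucleotide %s", pyr_tri)
  }
  pick <- sample.int(n_pyr + n_pur, count, replace = TRUE)
  on_pyr <- pick <= n_pyr
  out <- data.frame(chrom = character(count), pos = integer(count),
                    ref = character(count), alt = character(count),
                    stringsAsFactors = FALSE)
  if (any(on_pyr)) {
    rows <- pool_pyr[pick[on_pyr], ]
    out$chrom[on_pyr] <- rows$chrom; out$pos[on_pyr] <- rows$pos
    out$ref[on_pyr] <- ref; out$alt[on_pyr] <- alt
  }
  if (any(!on_pyr)) {
    rows <- pool_pur[pick[!on_pyr] - n_pyr, ]
    out$chrom[!on_pyr] <- rows$chrom; out$pos[!on_pyr] <- rows$pos
    out$ref[!on_pyr] <- .complement(ref); out$alt[!on_pyr] <- .complement(alt)
  }
  out
}

.caller_names <- c("mutect", "muse", "somaticsniper", "varscan")

.consensus_caller_combos <- function() {
  combos <- character(0)
  for (k in 2:4) {
    cmb <- utils::combn(.caller_names, k, simplify = FALSE)
    combos <- c(combos, vapply(cmb, paste, character(1), collapse = ";"))
  }
  combos
}

# ---- scar segment placement -------------------------------------------

# arm inventory: interstitial spans and telomere anchors
.arm_table <- function(genome) {
  rbind(
    data.frame(chrom = genome$chrom, arm = "p", lo = 1,
               hi = genome$centro_start - 1, telo = "start",
               stringsAsFactors = FALSE),
    data.frame(chrom = genome$chrom, arm = "q", lo = genome$centro_end + 1,
               hi = genome$length, telo = "end", stringsAsFactors = FALSE))
}

# place one sample's qualifying segments (and decoys); returns the
# segment data.frame plus the realized scar counts
.place_sample_segments <- function(genome, loh_n, tai_n, lst_n, decoys,
                                   deterministic) {
  margin <- 4e6
  arms <- .arm_table(genome)
  arms <- arms[sample.int(nrow(arms)), ]
  # telomeres on small arms first, preserving large arms for long features
  arms <- arms[order(arms$hi - arms$lo), ]
  segs <- list()
  add <- function(chrom, start, end, major, minor) {
    segs[[length(segs) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
  }
  # telomeric allelic imbalance: consume distinct telomeres
  placed_tai <- 0L
  arms$tai_used <- FALSE
  for (i in seq_len(nrow(arms))) {
    if (placed_tai >= tai_n) break
    span <- arms$hi[i] - arms$lo[i] + 1
    max_len <- span - margin - 1e6
    if (max_len < 12e6) next
    len <- if (deterministic) 20e6 else stats::runif(1, 13e6, min(26e6, max_len))
    len <- min(len, max_len)
    if (arms$telo[i] == "start") {
      add(arms$chrom[i], 1, round(len), 2L, 1L)
      arms$lo[i] <- round(len) + margin
    } else {
      add(arms$chrom[i], arms$hi[i] - round(len) + 1, arms$hi[i], 2L, 1L)
      arms$hi[i] <- arms$hi[i] - round(len) - margin
    }
    arms$tai_used[i] <- TRUE
    placed_tai <- placed_tai + 1L
  }
  # interstitial features: LOH blocks, LST chains, decoys
  arms$cur <- pmax(arms$lo + margin, 0)
  arms$stop <- arms$hi - margin
  features <- list()
  for (j in seq_len(loh_n)) {
    len <- if (deterministic) 18e6 else stats::runif(1, 16e6, 24e6)
    features[[length(features) + 1L]] <-
      list(widths = round(len), majors = 1L, minors = 0L, kind = "loh")
  }
  rem <- lst_n
  while (rem > 0L) {
    b <- min(3L, rem); rem <- rem - b
    nseg <- b + 1L
    majors <- rep(c(1L, 2L), length.out = nseg)
    minors <- rep(1L, nseg)
    features[[length(features) + 1L]] <-
      list(widths = rep(12e6, nseg), majors = majors, minors = minors,
           kind = "lst", breaks = b)
  }
  if (decoys) {
    features <- c(features, list(
      list(widths = 10e6, majors = 1L, minors = 0L, kind = "decoy"),
      list(widths = 30e6, majors = 3L, minors = 1L, kind = "decoy"),
      list(widths = c(8e6, 8e6), majors = c(2L, 3L), minors = c(2L, 3L),
           kind = "decoy"),
      list(widths = 2e6, majors = 5L, minors = 5L, kind = "decoy")))
  }
  placed <- c(loh = 0L, tai = placed_tai, lst = 0L)
  # best-fit decreasing keeps long chains placeable after fragmentation
  features <- features[order(-vapply(features, function(f) sum(f$widths),
                                     numeric(1)))]
  for (f in features) {
    total <- sum(f$widths)
    free <- arms$stop - arms$cur + 1
    slot <- which(free >= total + margin)
    if (length(slot) == 0L) next  # geometry saturated; truth = placed
    i <- slot[which.min(free[slot])]
    at <- arms$cur[i]
    for (s in seq_along(f$widths)) {
      add(arms$chrom[i], at, at + f$widths[s] - 1, f$majors[s], f$minors[s])
      at <- at + f$widths[s]
    }
    arms$cur[i] <- at + margin
    if (f$kind == "loh") placed["loh"] <- placed["loh"] + 1L
    if (f$kind == "lst") placed["lst"] <- placed["lst"] + f$breaks
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  list(segments = segs, counts = placed)
}

# ---- main generator ----------------------------------------------------

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates, from a single seed: a context reference sequence; a
#' MAF-style somatic mutation table whose trinucleotide contexts are
#' drawn multinomially from per-sample signature mixtures (plus
#' single-caller decoy rows that consensus filtering must remove);
#' allele-specific copy-number segments carrying exactly the placed
#' LOH/TAI/LST scar events plus non-qualifying decoys; a gene x sample
#' FPKM matrix with group-wise shifts; promoter methylation with coupled
#' silencing events; germline variant candidates including one
#' sole-violator per cascade rule and clean truncating panel variants for
#' the carrier groups; sample annotations; and a truth ledger recording
#' every generated quantity.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort`: list with `catalog` (true context
#'   tallies as a `trinuc_catalog`), `maf`, `segments`, `genome_meta`,
#'   `germline_candidates`, `fpkm`, `methylation`, `annotations`,
#'   `reference` (named character), `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_config("config", "must be created by sim_config()")
  }
  cohort <- with_seed(config$seed, .simulate_cohort_impl(config))
  cohort
}

.simulate_cohort_impl <- function(config) {
  n <- config$n_samples
  samples <- sprintf("S%0*d", max(4L, nchar(n)), seq_len(n))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  names(groups) <- samples

  # reference and trinucleotide index
  reference <- .random_reference(config$genome, config$context_seq_len)
  tri_index <- .trinuc_index(reference)

  # per-sample exposures and mutation counts
  sig_names <- rownames(config$true_signatures)
  k <- length(sig_names)
  exposures <- matrix(0, n, k, dimnames = list(samples, sig_names))
  conc <- config$exposure_concentration
  for (i in seq_len(n)) {
    alpha <- conc * config$signature_mixtures[groups[i], ]
    pos <- alpha > 0
    g <- rep(0, k)
    g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    exposures[i, ] <- g / sum(g)
  }
  mrange <- config$mutations_per_sample
  m <- if (mrange[1] == mrange[2]) rep(mrange[1], n) else
    sample(seq(mrange[1], mrange[2]), n, replace = TRUE)
  names(m) <- samples

  # context draws and MAF realization
  contexts <- trinucleotide_contexts()
  counts <- matrix(0L, n, 96L, dimnames = list(samples, contexts))
  combos <- .consensus_caller_combos()
  maf_parts <- vector("list", n)
  vc_levels <- c("Missense_Mutation", "Nonsense_Mutation", "Silent")
  non_silent <- stats::setNames(integer(n), samples)
  for (i in seq_len(n)) {
    p <- as.vector(exposures[i, ] %*% config$true_signatures)
    cnt <- as.integer(stats::rmultinom(1, m[i], p))
    counts[i, ] <- cnt
    sites <- do.call(rbind, lapply(which(cnt > 0L), function(ci) {
      .draw_sites(contexts[ci], cnt[ci], tri_index)
    }))
    vc <- sample(vc_levels, nrow(sites), replace = TRUE,
                 prob = c(0.75, 0.10, 0.15))
    non_silent[i] <- sum(vc != "Silent")
    rows <- data.frame(sample = samples[i], sites,
                       variant_classification = vc,
                       callers = sample(combos, nrow(sites), replace = TRUE),
                       stringsAsFactors = FALSE)
    if (config$caller_decoys > 0L) {
      dctx <- sample.int(96L, config$caller_decoys, replace = TRUE)
      dec <- do.call(rbind, lapply(dctx, function(ci) {
        .draw_sites(contexts[ci], 1L, tri_index)
      }))
      rows <- rbind(rows, data.frame(
        sample = samples[i], dec,
        variant_classification = sample(vc_levels, config$caller_decoys,
                                        replace = TRUE, prob = c(0.75, 0.10, 0.15)),
        callers = sample(.caller_names, config$caller_decoys, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    maf_parts[[i]] <- rows
  }
  maf <- do.call(rbind, maf_parts)
  rownames(maf) <- NULL

  # scar segments
  deterministic <- config$scar_mode == "deterministic"
  seg_parts <- vector("list", n)
  scar_truth <- data.frame(sample = samples, loh = 0L, tai = 0L, lst = 0L,
                           stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rates <- config$scar_rate_params[groups[i], ]
    want <- if (deterministic) round(rates) else stats::rpois(3, rates)
    res <- .place_sample_segments(config$genome, want[1], want[2], want[3],
                                  config$scar_decoys, deterministic)
    seg <- res$segments
    if (!is.null(seg) && nrow(seg) > 0L) {
      seg_parts[[i]] <- cbind(sample = samples[i], seg,
                              stringsAsFactors = FALSE)
    }
    scar_truth[i, c("loh", "tai", "lst")] <- as.integer(res$counts)
  }
  segments <- do.call(rbind, seg_parts)
  rownames(segments) <- NULL
  scar_truth$hrd_sum <- scar_truth$loh + scar_truth$tai + scar_truth$lst

  # expression
  genes <- unique(c(.deg_genes_b1, .deg_genes_b2, .rps_genes, .ifng_genes,
                    ddr_panel(),
                    sprintf("BG%04d", seq_len(config$n_background_genes))))
  base_log2 <- stats::setNames(stats::rnorm(length(genes), 3, 1), genes)
  shift <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  for (g in names(config$expr_fold_changes)) {
    cols <- samples[groups == g]
    if (length(cols) == 0L) next
    fc <- config$expr_fold_changes[[g]]
    fc <- fc[names(fc) %in% genes]
    shift[names(fc), cols] <- shift[names(fc), cols] + fc
  }
  noise <- matrix(stats::rnorm(length(genes) * n, 0, config$expr_sigma),
                  length(genes), n)
  fpkm <- 2^(base_log2 + shift + noise)
  dimnames(fpkm) <- list(genes, samples)

  # methylation with coupled silencing events
  panel <- ddr_panel()
  meth <- expand.grid(sample = samples, gene = panel,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meth$beta_summary <- pmin(stats::rbeta(nrow(meth), 2, 10), 0.70)
  n_sil <- round(config$silencing_fraction * n)
  sil_samples <- if (n_sil > 0L) sample(samples, n_sil) else character(0)
  silenced_truth <- data.frame(sample = character(0), gene = character(0),
                               stringsAsFactors = FALSE)
  for (sm in sil_samples) {
    row <- meth$sample == sm & meth$gene == config$silencing_gene
    meth$beta_summary[row] <- stats::runif(1, 0.78, 0.95)
    fpkm[config$silencing_gene, sm] <- stats::runif(1, 0.05, 0.9)
    silenced_truth <- rbind(silenced_truth,
                            data.frame(sample = sm,
                                       gene = config$silencing_gene,
                                       stringsAsFactors = FALSE))
  }
  # hypermethylated-but-expressed decoy
  decoy_sample <- setdiff(samples, sil_samples)[1]
  if (!is.na(decoy_sample)) {
    row <- meth$sample == decoy_sample & meth$gene == "BRCA1"
    meth$beta_summary[row] <- 0.85
    fpkm["BRCA1", decoy_sample] <- max(2, fpkm["BRCA1", decoy_sample])
  }
  hyper_truth <- meth[meth$beta_summary >= 0.75, c("sample", "gene")]
  rownames(hyper_truth) <- NULL

  # germline candidates
  germ <- .germline_candidates(samples, groups)

  # annotations
  subtype <- character(n)
  for (i in seq_len(n)) {
    subtype[i] <- sample(.pam50_levels, 1,
                         prob = config$subtype_probs[groups[i], ])
  }
  annotations <- data.frame(
    sample = samples, pam50_subtype = subtype,
    brca1_germline = unname(groups == "BRCA1mut"),
    brca2_germline = unname(groups == "BRCA2mut"),
    stringsAsFactors = FALSE)

  truth <- list(groups = groups,
                exposures = exposures,
                mutation_counts = m,
                non_silent_counts = non_silent,
                scar_counts = scar_truth,
                deg_genes = unlist(lapply(
                  config$expr_fold_changes,
                  function(fc) names(fc)[startsWith(names(fc), "DEG")]),
                  use.names = FALSE),
                silenced = silenced_truth,
                hypermethylated = hyper_truth,
                germline_survivors = germ$survivor_ids,
                true_signatures = config$true_signatures)

  catalog <- structure(list(samples = samples, counts = counts,
                            context_order = contexts),
                       class = "trinuc_catalog")
  structure(list(catalog = catalog, maf = maf, segments = segments,
                 genome_meta = config$genome,
                 germline_candidates = germ$records, fpkm = fpkm,
                 methylation = meth, annotations = annotations,
                 reference = reference, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d somatic mutation rows, %d segments\n",
              length(x$catalog$samples), nrow(x$maf),
              if (is.null(x$segments)) 0L else nrow(x$segments)))
  print(table(x$truth$groups))
  invisible(x)
}

# ---- germline candidate construction ----------------------------------

# a clean record template passing every rule
.clean_germline_record <- function(variant_id, sample, gene,
                                   exonic_class = "nonsense",
                                   func_region = "exonic") {
  data.frame(variant_id = variant_id, sample = sample, gene = gene,
             chrom = "chr2", pos = 1000L, ref = "C", alt = "T",
             total_depth = 60L, variant_count = 25L, vaf = 0.42,
             caller_label = "germline",
             flank_sequence = "ACGTACGTACGTA",
             mapq_ref_mean = 60, mapq_alt_mean = 58,
             median_read_position_fraction = 0.5,
             population_af = 1e-4,
             func_region = func_region, exonic_class = exonic_class,
             clinvar_hotspot = FALSE, stringsAsFactors = FALSE)
}

#' Germline filter-cascade fixture
#'
#' Eleven candidate variants: ten sole-violators — each clean except for
#' exactly one cascade rule (depth, supporting reads, VAF, somatic label,
#' homopolymer context, mapping-quality difference, read-end position,
#' population frequency, noncoding region, non-truncating class) — plus
#' one clean truncating panel variant, the single expected survivor.
#'
#' @param sample sample id attached to the records.
#' @return list with `records` (data.frame) and `survivor_id`.
#' @export
germline_fixture <- function(sample = "FIX001") {
  recs <- list()
  mk <- function(id, gene, ...) {
    r <- .clean_germline_record(id, sample, gene)
    mods <- list(...)
    for (f in names(mods)) r[[f]] <- mods[[f]]
    recs[[length(recs) + 1L]] <<- r
  }
  mk("V_depth", "ATM", total_depth = 8L, variant_count = 5L, vaf = 0.625)
  mk("V_count", "BAP1", variant_count = 4L, vaf = 0.10, total_depth = 40L)
  mk("V_vaf", "BRIP1", total_depth = 100L, variant_count = 7L, vaf = 0.07)
  mk("V_somatic", "CDK12", caller_label = "somatic")
  mk("V_homopolymer", "CHEK2", flank_sequence = "CAAAAACTAGCTA")
  mk("V_mapq", "NBN", mapq_ref_mean = 60, mapq_alt_mean = 25)
  mk("V_readend", "PALB2", median_read_position_fraction = 0.05)
  mk("V_common", "POLQ", population_af = 0.02)
  mk("V_region", "RAD51C", func_region = "intronic",
     exonic_class = "unknown", clinvar_hotspot = TRUE)
  mk("V_class", "BRCA1", exonic_class = "missense")
  mk("V_clean", "BRCA2", exonic_class = "nonsense")
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, survivor_id = "V_clean")
}

# cohort candidates: the fixture violators plus one clean truncating
# variant per carrier sample
.germline_candidates <- function(samples, groups) {
  fix <- germline_fixture(sample = samples[1])
  violators <- fix$records[fix$records$variant_id != fix$survivor_id, ]
  parts <- list(violators)
  survivor_ids <- character(0)
  carriers <- names(groups)[groups %in% c("BRCA1mut", "BRCA2mut")]
  for (sm in carriers) {
    gene <- if (groups[[sm]] == "BRCA1mut") "BRCA1" else "BRCA2"
    cls <- if (gene == "BRCA1") "nonsense" else "frameshift_indel"
    id <- paste0("G_", sm)
    parts[[length(parts) + 1L]] <-
      .clean_germline_record(id, sm, gene, exonic_class = cls)
    survivor_ids <- c(survivor_ids, id)
  }
  records <- do.call(rbind, parts)
  rownames(records) <- NULL
  list(records = records, survivor_ids = survivor_ids)
}

# ---- cohort writer -----------------------------------------------------

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits MAF-like TSV, segment TSV, FPKM TSV (genes x samples),
#' methylation TSV, germline candidate TSV, annotation TSV, genome
#' metadata TSV, the context reference FASTA, the true-tally catalog TSV
#' and the truth ledger JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv(cohort$maf, p("somatic_mutations.maf.tsv"))
  write_tsv(cohort$segments, p("ascn_segments.tsv"))
  write_tsv(data.frame(gene = rownames(cohort$fpkm), cohort$fpkm,
                       check.names = FALSE), p("fpkm.tsv"))
  write_tsv(cohort$methylation, p("methylation.tsv"))
  write_tsv(cohort$germline_candidates, p("germline_candidates.tsv"))
  write_tsv(cohort$annotations, p("annotations.tsv"))
  write_tsv(cohort$genome_meta, p("genome_meta.tsv"))
  write_catalog(cohort$catalog, p("true_catalog.tsv"))
  ref <- Biostrings::DNAStringSet(cohort$reference)
  Biostrings::writeXStringSet(ref, p("reference.fa"))
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
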