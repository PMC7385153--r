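## Reference signature matrix (synthetic stand-in for the published
## 30-signature v2 set) and the default truth signatures used by the
## cohort simulator.

# channels (indices into the 96-context order) matching a predicate
.channels <- function(sub = NULL, five = NULL, three = NULL) {
  ctx <- trinucleotide_contexts()
  keep <- rep(TRUE, 96L)
  if (!is.null(sub)) keep <- keep & substr(ctx, 3, 5) %in% sub
  if (!is.null(five)) keep <- keep & substr(ctx, 1, 1) %in% five
  if (!is.null(three)) keep <- keep & substr(ctx, 7, 7) %in% three
  which(keep)
}

# profile concentrated on `channels` over a uniform background
.peak_profile <- function(channels, peak_mass = 0.85) {
  p <- rep((1 - peak_mass) / 96, 96L)
  p[channels] <- p[channels] + peak_mass / length(channels)
  p / sum(p)
}

#' Synthetic 30-signature reference matrix (COSMIC v2 layout)
#'
#' A deterministic, fully synthetic stand-in for the published v2
#' reference set: 30 probability profiles over the 96 COSMIC contexts,
#' with domain-shaped profiles for the ids this pipeline interprets
#' (1 = CpG C>T deamination, 2/13 = APOBEC C>T / C>G at TpC, 3 = broad
#' near-flat BRCA/HRD profile, 5 = T>C-dominated, 6 = MSI-like,
#' 8 = C>A-dominated, 10 = POLE-like TpCpT) and generic pseudo-random
#' profiles for the remaining ids. The profiles are NOT the published
#' frequencies; they reproduce the matching semantics (id layout,
#' etiology labels) for fully synthetic analyses.
#'
#' @return 30 x 96 matrix; rows named `COSMIC_1` ... `COSMIC_30`, each row
#'   a probability vector over [trinucleotide_contexts()].
#' @export
synthetic_cosmic_v2 <- function() {
  ctx <- trinucleotide_contexts()
  profiles <- matrix(NA_real_, nrow = 30L, ncol = 96L,
                     dimnames = list(paste0("COSMIC_", 1:30), ctx))
  # CpG deamination: C>T with 3' G
  profiles[1, ] <- .peak_profile(.channels("C>T", three = "G"), 0.80)
  # APOBEC: TpC context; each of the pair carries a minority of the
  # partner substitution, as the two processes co-occur
  apo_ct <- .peak_profile(.channels("C>T", five = "T"), 0.90)
  apo_cg <- .peak_profile(.channels("C>G", five = "T"), 0.90)
  profiles[2, ] <- 0.72 * apo_ct + 0.28 * apo_cg
  profiles[13, ] <- 0.28 * apo_ct + 0.72 * apo_cg
  # BRCA/HRD: broad, nearly flat with a mild C>G/C>T tilt
  brca <- rep(1, 96L)
  brca[.channels(c("C>G", "C>T"))] <- 1.6
  profiles[3, ] <- brca / sum(brca)
  # clock-like T>C
  profiles[5, ] <- .peak_profile(.channels("T>C"), 0.75)
  # MSI-like: C>T at GpC plus T>C at ApT-flanked sites
  msi <- .peak_profile(.channels("C>T", five = "G"), 0.55) +
    .peak_profile(.channels("T>C", five = "A", three = "T"), 0.35)
  profiles[6, ] <- msi / sum(msi)
  # C>A-dominated
  profiles[8, ] <- .peak_profile(.channels("C>A"), 0.70)
  # POLE-like: sharp T[C>A]T + T[C>G]T
  pole <- .channels("C>A", five = "T", three = "T")
  pole2 <- .channels("C>G", five = "T", three = "T")
  profiles[10, ] <- .peak_profile(c(pole, pole2), 0.92)
  # remaining ids: generic deterministic pseudo-random profiles
  for (s in setdiff(1:30, c(1, 2, 3, 5, 6, 8, 10, 13))) {
    profiles[s, ] <- with_seed(20000L + s, {
      g <- stats::rgamma(96L, shape = 0.5)
      g / sum(g)
    })
  }
  profiles
}

# human-readable etiologies for the ids the analysis interprets
.cosmic_etiology <- c(COSMIC_1 = "C > T CpG", COSMIC_2 = "APOBEC",
                      COSMIC_3 = "BRCA", COSMIC_5 = "clock-like",
                      COSMIC_6 = "MSI", COSMIC_8 = "C > A",
                      COSMIC_10 = "POLE", COSMIC_13 = "APOBEC")

#' Default truth signatures for the cohort simulator
#'
#' Four well-separated processes mirroring the composition of a
#' breast-cancer-like cohort: CpG deamination, APOBEC (the normalized
#' mean of the two APOBEC reference profiles), a broad BRCA/HRD profile
#' and an MSI-like profile.
#'
#' @return 4 x 96 matrix with rows `CpG`, `APOBEC`, `BRCA`, `MSI`.
#' @export
default_true_signatures <- function() {
  ref <- synthetic_cosmic_v2()
  apobec <- (ref["COSMIC_2", ] + ref["COSMIC_13", ]) / 2
  out <- rbind(CpG = ref["COSMIC_1", ], APOBEC = apobec / sum(apobec),
               BRCA = ref["COSMIC_3", ], MSI = ref["COSMIC_6", ])
  colnames(out) <- trinucleotide_contexts()
  out
}

#' Read / write a signature matrix TSV (96 context rows, signatures as columns)
#' @param mat k x 96 signature matrix (rows sum to 1).
#' @param path file path.
#' @return `path` (write) or a k x 96 matrix (read).
#' @export
write_signature_matrix <- function(mat, path) {
  df <- data.frame(context = colnames(mat), t(mat), check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(path) {
  df <- read_tsv(path)
  contexts <- trinucleotide_contexts()
  if (!identical(df$context, contexts)) {
    stop_data("signature file does not follow the 96-context COSMIC ordering")
  }
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- contexts
  mat
}
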