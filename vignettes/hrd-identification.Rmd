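---
title: "Identifying homologous recombination deficiency from mutational signatures, genomic scars and germline variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying homologous recombination deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumors that have lost homologous recombination (HR), the high-fidelity
double-strand-break repair pathway, respond differently to DNA-damaging
therapy. Germline *BRCA1*/*BRCA2* truncation is the canonical cause, but
many HR-deficient ("BRCAness") tumors carry no BRCA mutation, and many
tumors whose mutational portrait resembles the BRCA-associated signature
are not convincingly HR deficient. This package implements, as one
tested pipeline, the complementary read-outs used to triangulate HRD in
a breast-cancer-like cohort:

1. **Mutational signatures** — a 96-trinucleotide catalog per tumor,
   de novo signature extraction with consensus over restarts, and
   refitting against a reference signature set.
2. **Genomic scars** — counts of large loss-of-heterozygosity segments
   (LOH), telomeric allelic imbalance (TAI) and large-scale state
   transitions (LST) from allele-specific copy number; their sum is the
   HRD score, classified by top decile or fixed cutoff and evaluated by
   ROC against germline BRCA status.
3. **Recombination proficiency score (RPS)** — a negatively signed
   (optionally coefficient-weighted) sum of *RIF1*, *PARPBP*, *RAD51*
   and *XRCC5* expression.
4. **Germline truncating variants** — a ten-rule filter cascade over
   candidate calls, then an 11-gene DNA-damage-response panel.
5. **Epigenetic silencing** — promoter hypermethylation coupled with
   loss of expression.
6. **Group statistics** — rank-sum comparisons (pairwise and
   one-vs-rest), BH-FDR differential expression, an IFN-γ six-gene
   score, Tukey outlier handling and a burden-vs-activity linear fit.

Everything runs against a synthetic cohort generator with a ground-truth
ledger, so each stage is testable end to end without external data.

## Mutation catalogs

Somatic single-nucleotide variants are kept when at least two callers
support them (`consensus_filter()`, default 2 of
Mutect/MuSE/SomaticSniper/VarScan labels), then tallied into the 96
COSMIC channels: six pyrimidine-reference substitutions crossed with the
5′ and 3′ flanking bases, purine-reference records reverse-complemented
(`trinucleotide_context()`). Indels and multi-nucleotide records are
dropped with a logged count; sites without both flanks are skipped with
a warning. Samples whose catalogued SNV total reaches 5,800 are excluded
as hypermutants before extraction (`exclude_hypermutants()`); the
threshold is inclusive.

Coordinates are 1-based inclusive everywhere (MAF convention);
`normalize_chromosomes()` bridges the "chr1"/"1" dialects.

## De novo extraction

`extract_signatures()` fits Kullback–Leibler NMF by multiplicative
updates, starting every restart from `k_max = 10` components. Component
count selection is by automatic relevance determination: each component
carries a relevance weight recomputed from its total mass, and the
inverse relevance enters the update denominators as an adaptive penalty.
Duplicated or unsupported components are driven toward zero and pruned
(during fitting below 0.1% of attributed activity; the converged call
keeps components at or above 1%). A plain activity-share prune without
the adaptive penalty does not work: multiplicative updates happily carry
duplicated components indefinitely, and a flat L1 penalty is indifferent
to splitting one process across two components. The adaptive penalty is
what makes the restart votes concentrate.

Fifty random restarts each vote for their converged component count; the
modal count must win at least 60% of restarts (configurable quorum),
otherwise extraction aborts with the vote table. Consensus profiles are
per-signature centroids of the winning restarts after cosine matching,
renormalized.

**Singleton rule.** A signature dominated by one sample is an artifact
of a single ultra-mutated tumor, not a cohort-level process.
`flag_singleton_signature()` flags any signature whose largest single
contributor reaches 50% (inclusive) of its total activity; dominance is
judged on *absolute* attributed mutations (per-sample exposure × sample
burden), not on per-sample fractions — an ultra-mutated tumor at 70%
exposure carries far more of the signature's mutations than an average
tumor at 70%. The pipeline contract is to exclude the flagged sample and
re-run extraction.

## Exposure refitting

`refit_exposures()` projects each sample's frequency vector onto
reference profiles by non-negative least squares (Lawson–Hanson, via
`pracma::lsqnonneg`). Normalized contributions below 0.06 are zeroed and
the rest renormalized — a reporting floor, reflecting that small fitted
contributions are not interpretable; the unfloored solution is also
returned. Because of the floor, the default generator mixtures use
weights that are either 0 or ≥ 0.10: a planted weight below the floor
would be structurally unrecoverable, which would make recovery checks
meaningless rather than informative. The reconstruction cosine is
reported per sample; it can never fall below the best single-signature
cosine (adding components never hurts the fit).

The bundled reference (`synthetic_cosmic_v2()`,
`inst/extdata/cosmic_v2_synthetic.tsv`) is a **fully synthetic
stand-in** for the published 30-signature v2 set: same layout, same ids,
domain-shaped profiles for the ids this analysis interprets (1 CpG
deamination, 2/13 APOBEC, 3 broad BRCA/HRD, 5 clock-like, 6 MSI, 8 C>A,
10 POLE-like) and deterministic generic profiles for the rest. It
reproduces the *matching semantics* — including the merged
"APOBEC (COSMIC 2 + 13)" label when the two best matches are that pair
and both cosines reach the 0.8 report floor — but its numbers are not
the published frequencies, and matches against it say nothing about
real tumors.

## Genomic scars

The three scar components follow the standard published scar
algorithms, with every length parameter exposed:

| component | rule | default |
|---|---|---|
| LOH | minor copy number 0, longer than `min_len`, not spanning a whole chromosome | 15 Mb |
| TAI | allelic imbalance (major ≠ minor) longer than `min_len`, reaching a chromosome end, not crossing the centromere | 11 Mb |
| LST | breakpoints between adjacent segments in different states, both ≥ `min_seg`, gap ≤ `max_gap`, after removing segments < `smooth_below` and merging same-state neighbours, per arm | 10 / 3 / 3 Mb |

Arms are derived by splitting at the centromere midpoint. LST is
reported as a raw breakpoint count: the ploidy-dependent offset some
published variants subtract is **not** applied, so computed scores and
imported published scores live on different scales. `hrd_sum()`
therefore carries a `source` flag (`computed`/`imported`) and refuses to
reconcile conflicting values silently; imported scores (the "≥ 57 is the
top decile" scale) pass through unchanged.

`rps()` and `rps_beta()` implement the two printed equations; the four
beta coefficients (0.2171423, 0.1946173, 0.2783017, 0.3099387) sum to
exactly 1, so uniform unit expression gives −1. Both scores are linear
and non-positive on non-negative expression, and *lower* values mean
higher repair-gene expression — in ROC comparisons against carrier
status the RPS enters negated.

## Germline filter cascade

Ten conjunctive rules, applied in a fixed order for the trace but
order-invariant in effect. Thresholds quoted from the upstream caller
conventions: depth < 10, supporting reads < 5 ("variant count" in caller
terminology is read as supporting-read count), VAF < 0.08 (all strict),
somatic label, homopolymer context, |mapping-quality difference| ≥ 30
(inclusive), read-end position, population allele frequency ≥ 1%
(inclusive; missing frequency passes — the rule removes *known*-common
variants), noncoding region, non-truncating class. Truncating means:
ClinVar hotspot, nonsense, frameshift indel, or splice-site. The
survivors are then subset to the 11-gene DDR panel (`ddr_panel()`).

Two rules are under-specified upstream and get explicit, configurable
stand-ins: *near homopolymer* means a single-base run of ≥ 5 within 3 bp
of the site, and *read end* means a median variant position within the
terminal 10% of reads. Both accept either raw evidence (flank sequence,
read-position fraction) or a precomputed flag; a record with no evidence
for a context rule passes it with a warning rather than being silently
dropped.

## Silencing

A gene-sample pair is hypermethylated when its summarized promoter β
reaches 0.75 (inclusive) and silenced when additionally FPKM < 1
(strict). Promoter summarization defaults to the **mean** of promoter
probes even though the upstream description says "sum": a β threshold of
0.75 is only meaningful on the [0, 1] scale, and a multi-probe sum
exceeds it trivially. Sum mode is available for fidelity
(`summarize_promoter(mode = "sum")`), flagged as living on a different
scale. Missing inputs yield `NA` calls, excluded from tallies; silenced
⇒ hypermethylated by construction.

## Statistics

- Rank-sum tests: exact null when both groups are ≤ 50 and tie-free,
  otherwise the tie-corrected normal approximation with continuity
  correction. One-vs-rest requires ≥ 3 groups. A vectorized
  normal-approximation path (`select_degs()`) handles genome-wide
  testing; it is cross-checked against `wilcox.test` in the tests.
- DEG selection: fold change of group means, BH adjustment over all
  tested genes, selected iff |log2 FC| > 1.5 **and** adjusted p < 0.05
  (strict `<`, following the figure-legend convention over the "≤" in
  the text; configurable). Genes with zero mean in both groups are
  dropped; a zero mean in exactly one group gives an infinite fold
  change — reported, flagged `degenerate_fc`, never selected.
- IFN-γ score: mean of the six immune genes on the log2(FPKM + 1) scale
  by default (raw-FPKM option); "the man of the expression" in the
  source description is read as "the mean".
- Tukey fences: quartiles by linear interpolation of order statistics
  (R type 7), outliers strictly outside Q1 − 1.5 IQR / Q3 + 1.5 IQR.
- Burden-vs-activity: subset to signature activity ≥ 0.5, Tukey-clean
  the burden, ordinary least squares, R² and F-test p.

## Classification and ROC

Higher score always predicts the positive class. The top-quantile rule
finds the smallest score whose at-or-above fraction does not exceed the
quantile and never splits tied scores — with heavily tied integer scores
the realized HRD fraction can land below the nominal 10%, which is the
correct conservative behaviour. The fixed-cutoff rule is inclusive
(score ≥ 57 on the imported scale). `roc_curve()` evaluates every unique
score plus sentinels, integrates AUC by trapezoid (equal to the
Mann–Whitney statistic with ties counted half), and picks the best
cutoff by maximum sensitivity + specificity with ties resolved toward
the lowest threshold (screening favours sensitivity; the tie is
logged).

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate, with known truth: four
groups (BRCA1/BRCA2 carriers, BRCA-wild-type HRD, non-HRD; default
10/12/18/160 of 200), per-sample signature exposures drawn Dirichlet
around group mixtures (concentration 2), multinomial context draws of
500–2000 mutations realized as MAF rows against a generated context
reference, single-caller decoy rows for the consensus filter,
group-level scar burdens placed as geometrically valid segments plus
non-qualifying decoys, log-normal expression (σ = 0.5 log2 units) with
planted fold changes, coupled β/expression silencing events with a
hypermethylated-but-expressed decoy, and a germline candidate table
containing one sole-violator per cascade rule plus clean truncating
variants for every carrier.

Design points worth knowing:

- **Per-sample exposure variation is essential, not cosmetic.** With
  group-constant mixtures the exposure matrix has rank equal to the
  number of groups and four signatures are unidentifiable — NMF then
  finds deviance-optimal rank-2 factorizations that match nothing. The
  Dirichlet spread (with its near-pure anchor samples) is what makes
  extraction recoverable, and it is also what real cohorts look like.
- **Genome geometry.** Six chromosomes of 100–160 Mb with stated
  centromere intervals: enough telomeres (12) and arm space that
  Poisson draws of the default TAI rates never saturate the geometry.
  Segment placement is best-fit decreasing; if a draw ever exceeds
  capacity the truth ledger records what was actually placed, so truth
  recounts stay exact in both deterministic and stochastic modes.
- **Two coordinate scales.** Context sequences are compact (60 kb per
  chromosome) while segment coordinates use the declared Mb lengths.
  Catalog code never reads the genome metadata and scar code never
  reads the FASTA, so the scales never meet; this keeps the generator
  fast and the whole cohort a few MB of text.
- **What it does not emulate:** read-level data, clonality and
  replication timing, ploidy structure, probe-level methylation noise,
  linkage between mutation burden and signature activity (off by
  default), or the published scar-score scale. Passing tests therefore
  demonstrate algorithmic correctness on data with known generating
  process — not clinical validity on real tumors.

## Problem sizes and numerical choices

The shipped analyses and tests use: 200-sample cohorts at 500–2000
mutations for extraction/refit checks (50 restarts, start k = 10);
1000 random ≤ 50-segment tables for scar-oracle equivalence; 500
replicates for DEG null calibration (1000 genes, 25 vs 25) and for the
binormal ROC check; 50 replicates for DEG recovery. NMF restarts run at
most 2000 multiplicative updates with a relative deviance tolerance of
1e-8 checked every 25 iterations; NNLS is exact; BH uses
`stats::p.adjust`; exact rank-sum enumeration is delegated to
`stats::wilcox.test`. Ties: argmax exposure ties go to the
lexicographically first signature name (logged); ROC cutoff ties to the
lowest threshold (logged); quantile classification keeps tie groups
whole.

## Known limitations

- The reference signature matrix is synthetic; naming against it is a
  semantics check, not a biological claim.
- LST has no ploidy correction, so computed HRD sums are not on the
  published pan-cancer scale; the `source` flag keeps the two apart.
- The germline cascade consumes caller/annotator *outputs*; it does not
  re-run variant calling or annotation, and its two context rules use
  explicit stand-in definitions where the upstream description is
  silent.
- PAM50 subtype and germline carrier status are ingested annotations,
  never inferred.
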