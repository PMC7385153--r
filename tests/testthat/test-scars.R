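genome1 <- data.frame(chrom = "c1", length = 100e6,
                      centro_start = 48.5e6, centro_end = 51.5e6,
                      stringsAsFactors = FALSE)

seg_row <- function(start, end, major, minor, chrom = "c1") {
  data.frame(chrom = chrom, start = start, end = end, major_cn = major,
             minor_cn = minor, stringsAsFactors = FALSE)
}

test_that("LOH counting requires length, minor-allele loss and a partial chromosome", {
  expect_equal(count_loh(seg_row(20e6, 40e6 - 1, 1, 0), genome1), 1L)
  expect_equal(count_loh(seg_row(1, 100e6, 1, 0), genome1), 0L)
  expect_equal(count_loh(seg_row(20e6, 30e6 - 1, 1, 0), genome1), 0L)
  # exactly 15 Mb is not enough (strictly greater)
  expect_equal(count_loh(seg_row(20e6, 20e6 + 15e6 - 1, 1, 0), genome1), 0L)
  expect_equal(count_loh(seg_row(20e6, 40e6, 2, 1), genome1), 0L)
})

test_that("TAI counting requires imbalance, telomeric contact and centromere clearance", {
  # 30 Mb imbalanced, ends at the p telomere, clear of the centromere
  expect_equal(count_tai(seg_row(1, 30e6, 2, 1), genome1), 1L)
  # same segment made interstitial
  expect_equal(count_tai(seg_row(2, 30e6, 2, 1), genome1), 0L)
  # spans the centromere from the telomere
  expect_equal(count_tai(seg_row(1, 60e6, 2, 1), genome1), 0L)
  # balanced or short segments do not count
  expect_equal(count_tai(seg_row(1, 30e6, 2, 2), genome1), 0L)
  expect_equal(count_tai(seg_row(1, 11e6, 2, 1), genome1), 0L)
  # q-telomere contact counts too
  expect_equal(count_tai(seg_row(70e6, 100e6, 3, 1), genome1), 1L)
  nocen <- genome1
  nocen$centro_start <- NA
  expect_error(count_tai(seg_row(1, 30e6, 2, 1), nocen), "centromere")
})

test_that("LST counting smooths small segments and requires two large neighbours", {
  two <- rbind(seg_row(1e6, 13e6 - 1, 2, 1), seg_row(13e6, 25e6 - 1, 1, 1))
  expect_equal(count_lst(two, genome1), 1L)
  short <- rbind(seg_row(1e6, 13e6 - 1, 2, 1), seg_row(13e6, 21e6 - 1, 1, 1))
  expect_equal(count_lst(short, genome1), 0L)
  three <- rbind(seg_row(1e6, 13e6 - 1, 2, 1),
                 seg_row(13e6, 25e6 - 1, 1, 1),
                 seg_row(25e6, 37e6 - 1, 2, 1))
  expect_equal(count_lst(three, genome1), 2L)
  # a 2 Mb interruption between equal states is smoothed into one segment
  smoothed <- rbind(seg_row(1e6, 13e6 - 1, 2, 1),
                    seg_row(13e6, 15e6 - 1, 5, 0),
                    seg_row(15e6, 27e6 - 1, 2, 1))
  expect_equal(count_lst(smoothed, genome1), 0L)
  # a gap above 3 Mb breaks adjacency
  gapped <- rbind(seg_row(1e6, 13e6 - 1, 2, 1), seg_row(17e6, 29e6, 1, 1))
  expect_equal(count_lst(gapped, genome1), 0L)
  # transitions across the centromere midpoint do not count
  across <- rbind(seg_row(35e6, 49.9e6, 2, 1), seg_row(49.9e6 + 1, 65e6, 1, 1))
  expect_equal(count_lst(across, genome1), 0L)
})

test_that("scar counters agree exactly with brute-force enumeration on random tables", {
  set.seed(99)
  genome <- synthetic_genome()
  for (rep in 1:150) {
    seg <- random_segment_table(sample(3:50, 1), genome)
    expect_equal(count_loh(seg, genome), oracle_loh(seg, genome))
    expect_equal(count_tai(seg, genome), oracle_tai(seg, genome))
    expect_equal(count_lst(seg, genome), oracle_lst(seg, genome))
  }
})

test_that("hrd_sum adds components, passes imports through, and flags conflicts", {
  co <- simulate_cohort(sim_config(
    n_samples = 2, seed = 41, group_sizes = c(nonHRD = 2L),
    scar_rate_params = matrix(c(10, 5, 8), 1, 3,
                              dimnames = list("nonHRD", NULL)),
    scar_mode = "deterministic", scar_decoys = FALSE,
    mutations_per_sample = 20L))
  seg <- co$segments[co$segments$sample == co$catalog$samples[1], ]
  rec <- hrd_sum(seg, co$genome_meta, sample = "x")
  expect_equal(rec$hrd_sum, 23L)
  expect_equal(rec$hrd_sum, rec$loh_count + rec$tai_count + rec$lst_count)
  expect_equal(rec$source, "computed")

  imp <- hrd_sum(imported = 57, sample = "y")
  expect_equal(imp$hrd_sum, 57)
  expect_equal(imp$source, "imported")
  expect_error(hrd_sum(seg, co$genome_meta, imported = 99, sample = "x"),
               "conflict")

  empty <- hrd_sum(seg[0, ], co$genome_meta, sample = "z")
  expect_equal(unlist(empty[c("loh_count", "tai_count", "lst_count",
                              "hrd_sum")], use.names = FALSE),
               c(0L, 0L, 0L, 0L))
})

test_that("hrd scores are invariant to segment order and additive over chromosomes", {
  set.seed(7)
  genome <- synthetic_genome()
  seg <- random_segment_table(40, genome)
  base <- c(count_loh(seg, genome), count_tai(seg, genome),
            count_lst(seg, genome))
  perm <- seg[sample(nrow(seg)), ]
  expect_equal(c(count_loh(perm, genome), count_tai(perm, genome),
                 count_lst(perm, genome)), base)
  by_chrom <- sapply(unique(seg$chrom), function(ch) {
    s <- seg[seg$chrom == ch, ]
    count_loh(s, genome) + count_tai(s, genome) + count_lst(s, genome)
  })
  expect_equal(sum(by_chrom), sum(base))
})

test_that("segment validation rejects malformed tables", {
  expect_error(count_loh(seg_row(10, 5, 1, 0), genome1), "start > end")
  expect_error(count_loh(seg_row(10, 20e6, 1, 2), genome1), "minor_cn")
  overlapping <- rbind(seg_row(1e6, 20e6, 2, 1), seg_row(10e6, 30e6, 2, 1))
  expect_error(count_loh(overlapping, genome1), "overlapping")
})

test_that("RPS identities: plain sum, printed beta coefficients, linearity", {
  m <- matrix(c(2, 3, 4, 1), 4, 1,
              dimnames = list(c("RIF1", "PARPBP", "RAD51", "XRCC5"), "s1"))
  expect_equal(unname(rps(m)), -10)
  zero <- m; zero[] <- 0
  expect_equal(unname(rps(zero)), 0)
  ones <- m; ones[] <- 1
  expect_equal(unname(rps_beta(ones)), -1)
  unit <- m; unit[] <- 0; unit["RIF1", ] <- 1
  expect_equal(unname(rps_beta(unit)), -0.2171423)
  set.seed(3)
  for (i in 1:20) {
    m[] <- runif(4, 0, 50)
    expect_lte(rps(m)[1], 0)
    expect_lte(rps_beta(m)[1], 0)
    expect_equal(unname(rps_beta(m * 10)), unname(rps_beta(m) * 10))
    expect_equal(unname(rps(m * 3)), unname(rps(m) * 3))
  }
  no_gene <- m[1:3, , drop = FALSE]
  expect_error(rps(no_gene), "XRCC5")
})
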