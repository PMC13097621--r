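# Small-RNA size filtering, stranded counting, CPM and coverage.

mk_reads <- function(lens) {
  tibble::tibble(qname = paste0("r", seq_along(lens)), chrom = "TE1",
                 start = 0L, end = lens, strand = "+", mapq = 255L,
                 read_len = lens)
}

test_that("size filter keeps the inclusive 20-35 nt window", {
  got <- size_filter(mk_reads(c(19L, 20L, 35L, 36L)))
  expect_equal(got$read_len, c(20L, 35L))
  expect_equal(nrow(size_filter(mk_reads(integer(0)))), 0)
  expect_equal(nrow(size_filter(mk_reads(rep(10:45, each = 100)))),
               16 * 100)
  expect_error(size_filter(mk_reads(25L), min_len = 30, max_len = 20),
               "min_len")
})

test_that("stranded counting by family conserves reads", {
  aln <- tibble::tibble(
    qname = paste0("r", 1:130),
    chrom = c(rep("Springer", 100), rep("copia", 30)),
    start = 0L, end = 25L,
    strand = c(rep("+", 75), rep("-", 25), rep("+", 10), rep("-", 20)),
    mapq = 255L, read_len = 25L)
  tab <- count_by_feature_strand(aln, c("Springer", "copia", "gypsy1"))
  sp <- tab[tab$family == "Springer", ]
  expect_equal(sp$sense, 75)
  expect_equal(sp$antisense, 25)
  expect_equal(sp$sense_fraction, 75)
  expect_true(is.na(tab$sense_fraction[tab$family == "gypsy1"]))
  expect_equal(sum(tab$sense + tab$antisense), nrow(aln))
  expect_warning(count_by_feature_strand(aln, "Springer"), "unknown")
})

test_that("CPM normalization is exact and conserves the library", {
  tab <- tibble::tibble(family = c("a", "b"), sense = c(5L, 15L),
                        antisense = 0L,
                        sense_fraction = 100)
  got <- cpm_normalize(tab, 20)
  expect_equal(got$sense_cpm, c(250000, 750000))
  expect_equal(sum(got$total_cpm), 1e6)
  one <- cpm_normalize(tibble::tibble(family = "x", sense = 10L,
                                      antisense = 0L,
                                      sense_fraction = 100), 10)
  expect_equal(one$sense_cpm, 1e6)
  big <- cpm_normalize(tibble::tibble(family = "x", sense = 37000L,
                                      antisense = 0L,
                                      sense_fraction = 100), 3.7e6)
  expect_equal(big$sense_cpm, 10000)
  expect_error(cpm_normalize(tab, 0), "denominator")
})

test_that("CPM is invariant under duplicating reads and the denominator", {
  tab <- tibble::tibble(family = "a", sense = 40L, antisense = 10L,
                        sense_fraction = 80)
  doubled <- dplyr::mutate(tab, sense = sense * 2L,
                           antisense = antisense * 2L)
  expect_equal(cpm_normalize(tab, 100)$total_cpm,
               cpm_normalize(doubled, 200)$total_cpm)
})

test_that("sense-bias comparison and top-k ranking behave", {
  a <- tibble::tibble(family = c("x", "y"), sense = c(90L, 10L),
                      antisense = c(10L, 90L),
                      sense_fraction = c(90, 10))
  b <- tibble::tibble(family = c("x", "z"), sense = c(20L, 5L),
                      antisense = c(80L, 5L),
                      sense_fraction = c(20, 50))
  cmp <- sense_bias_ranking(a, b)
  expect_equal(cmp$delta[cmp$family == "x"], 70)
  expect_true(is.na(cmp$delta[cmp$family == "y"]))
  same <- sense_bias_ranking(a, a)
  expect_true(all(same$delta == 0))
  ranked <- top_k_by_total(bind_rows(a, b), k = 2)
  expect_equal(nrow(ranked), 2)
  expect_equal(ranked$family[1], "x")
  expect_error(top_k_by_total(a, k = 0), "k")
})

test_that("planted sense fractions are recovered across read depths", {
  planted <- c(Springer = 0.9, copia = 0.5, gypsy1 = 0.1)
  errs <- sapply(c(500, 2500, 10000), function(depth) {
    cfg <- sim_config(smrna = list(
      sense_fraction = planted,
      consensus_len = c(Springer = 7546, copia = 5146, gypsy1 = 6405),
      n_reads = depth, len_range = c(23, 29)))
    sim <- simulate_te_dataset(cfg, seed = 100 + depth)
    tab <- count_by_feature_strand(sim$smrna, names(planted))
    max(abs(tab$sense_fraction / 100 - planted[tab$family]))
  })
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("per-position coverage scales aligned bases to CPM", {
  aln <- tibble::tibble(qname = "r1", chrom = "TE1", start = 0L, end = 25L,
                        strand = "+", mapq = 255L, read_len = 25L)
  cov <- per_position_coverage(aln, "TE1", 100, denominator = 50)
  expect_equal(cov$sense[1:25], rep(1e6 / 50, 25))
  expect_equal(cov$sense[26:100], rep(0, 75))
  expect_equal(sum(cov$sense + cov$antisense), 25 * 1e6 / 50)
  zero <- per_position_coverage(aln[0, ], "TE1", 100, denominator = 50)
  expect_true(all(zero$sense == 0) && all(zero$antisense == 0))
  over <- dplyr::mutate(aln, end = 120L)
  expect_message(
    clipped <- per_position_coverage(over, "TE1", 100, denominator = 50),
    "clipped")
  expect_equal(sum(clipped$sense > 0), 100)
})

test_that("coverage bedGraph export round-trips through the reader", {
  aln <- tibble::tibble(qname = c("r1", "r2"), chrom = "TE1",
                        start = c(0L, 50L), end = c(25L, 75L),
                        strand = c("+", "-"), mapq = 255L, read_len = 25L)
  cov <- per_position_coverage(aln, "TE1", 100, denominator = 100)
  prefix <- withr::local_tempfile()
  paths <- write_consensus_coverage(cov, prefix)
  sense <- read_bedgraph(paste0(prefix, ".sense.bedgraph"))
  expect_equal(sense$start, 0)
  expect_equal(sense$end, 25)
  expect_equal(sense$value, 1e6 / 100)
})
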