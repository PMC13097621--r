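# Occupancy, enrichment, synteny and junction presence calls.

iv <- function(starts, ends, chrom = "c") {
  tibble::tibble(chrom = chrom, start = starts, end = ends)
}

test_that("occupancy merges intervals before summing", {
  got <- occupancy(iv(c(0, 50), c(100, 150)), 1000)
  expect_equal(got$covered_bases, 150)
  expect_equal(got$fraction, 0.15)
  expect_equal(occupancy(iv(integer(0), integer(0)), 1000)$fraction, 0)
  tiling <- occupancy(iv(c(0, 500), c(500, 1000)), 1000)
  expect_equal(tiling$fraction, 1)
  expect_error(occupancy(iv(0, 2000), 1000), "beyond")
})

test_that("occupancy is invariant to order and to splitting intervals", {
  a <- iv(c(10, 200), c(120, 300))
  split_a <- iv(c(200, 60, 10), c(300, 120, 60))
  expect_equal(occupancy(a, 1000), occupancy(split_a, 1000))
})

test_that("enrichment works in both modes with degenerate baselines", {
  a <- iv(0, 30); b <- iv(0, 10)
  occ <- te_enrichment(a, b, 1000, 1000, mode = "occupancy")
  expect_equal(occ$enrichment, 3)
  self <- te_enrichment(a, a, 1000, 1000, mode = "occupancy")
  expect_equal(self$enrichment, 1)
  # reciprocal product is 1 in occupancy mode
  ab <- te_enrichment(a, b, 1000, 2000, mode = "occupancy")
  ba <- te_enrichment(b, a, 2000, 1000, mode = "occupancy")
  expect_equal(ab$enrichment * ba$enrichment, 1)
  # copy-number mode counts full-length copies
  copies_a <- iv(seq(0, by = 10000, length.out = 36),
                 seq(0, by = 10000, length.out = 36) + 7546)
  copies_b <- iv(0, 7546)
  cn <- te_enrichment(copies_a, copies_b, mode = "copy_number",
                      min_len = 7500)
  expect_equal(cn$enrichment, 36)
  none <- te_enrichment(copies_a, iv(0, 100), mode = "copy_number",
                        min_len = 7500)
  expect_true(none$undefined)
  expect_equal(none$enrichment, Inf)
})

test_that("syntenic fraction uses the union of clipped blocks", {
  region <- tibble::tibble(chrom = "t", start = 0, end = 1000)
  full <- tibble::tibble(qname = "q", qlen = 1000, qstart = 0, qend = 1000,
                         strand = "+", tname = "t", tlen = 1000,
                         tstart = 0, tend = 1000, n_match = 1000,
                         block_len = 1000, mapq = 60,
                         class = NA_character_)
  expect_equal(syntenic_fraction(region, full)$syntenic_pct, 100)
  partial <- dplyr::bind_rows(
    dplyr::mutate(full, tstart = 0, tend = 300),
    dplyr::mutate(full, tstart = 100, tend = 529),
    dplyr::mutate(full, tstart = 100, tend = 529))  # duplicate: union once
  got <- syntenic_fraction(region, partial)
  expect_equal(got$syntenic_pct, 52.9)
  expect_equal(got$non_syntenic_pct, 47.1)
  expect_equal(got$syntenic_pct + got$non_syntenic_pct, 100)
  # rearranged-class blocks are excluded
  rearr <- dplyr::mutate(full, class = "rearranged")
  expect_equal(syntenic_fraction(region, rearr)$syntenic_pct, 0)
  expect_error(syntenic_fraction(
    tibble::tibble(chrom = "t", start = 5, end = 5), full), "region")
})

test_that("coverage profile is flat for uniform reads, bimodal for a duplication", {
  withr::local_seed(42)
  region <- tibble::tibble(chrom = "r", start = 0, end = 20000)
  n <- 10000   # 50x at 100 nt reads
  starts <- floor(runif(n, 0, 19900))
  aln <- tibble::tibble(chrom = "r", start = starts, end = starts + 100)
  prof <- region_coverage_profile(aln, region, bin = 500)
  expect_lt(coverage_cv(prof), 0.1)
  none <- region_coverage_profile(aln[0, ], region, bin = 500,
                                  normalizer = 1)
  expect_true(all(none$value == 0))
  # 2x duplication over half the region doubles read density there
  extra_starts <- floor(runif(n / 2, 10000, 19900))
  dup <- dplyr::bind_rows(aln, tibble::tibble(chrom = "r",
                                              start = extra_starts,
                                              end = extra_starts + 100))
  prof_dup <- region_coverage_profile(dup, region, bin = 500)
  expect_gt(coverage_cv(prof_dup), coverage_cv(prof) * 2)
  lo <- mean(prof_dup$value[prof_dup$bin_start < 9000])
  hi <- mean(prof_dup$value[prof_dup$bin_start > 11000])
  expect_gt(hi / lo, 1.7)
  expect_error(region_coverage_profile(aln, region, bin = 0), "bin")
})

test_that("junction support requires both junctions with full overhang", {
  ins <- tibble::tibble(id = "i1", chrom = "c", start = 1000L, end = 9000L)
  spanning <- tibble::tibble(chrom = "c",
                             start = c(985L, 8985L), end = c(1015L, 9015L))
  got <- junction_support(ins, spanning, min_overhang = 10)
  expect_equal(got$verdict, "preexisting")
  expect_equal(got$left_support, 1)
  # 5-nt overhang does not support at min_overhang 10
  short <- tibble::tibble(chrom = "c", start = c(995L, 8995L),
                          end = c(1005L, 9005L))
  expect_equal(junction_support(ins, short)$verdict, "novel")
  expect_equal(junction_support(ins, short[0, ])$verdict, "novel")
  # removing one junction's reads flips the verdict unless relaxed
  left_only <- spanning[1, ]
  expect_equal(junction_support(ins, left_only)$verdict, "novel")
  expect_equal(junction_support(ins, left_only,
                                require_both = FALSE)$verdict,
               "preexisting")
  expect_error(junction_support(ins, spanning, min_overhang = 0),
               "min_overhang")
})

test_that("synthetic junction reads call all planted insertions preexisting", {
  sim <- small_sim(seed = 23)
  calls <- junction_support(sim$insertions, sim$dna_alignments)
  expect_true(all(calls$verdict == "preexisting"))
  # dropping reads near one junction flips that insertion to novel
  victim <- sim$insertions[1, ]
  pruned <- dplyr::filter(sim$dna_alignments,
                          !(chrom == victim$chrom &
                              start < victim$start + 10 &
                              end > victim$start - 10))
  calls2 <- junction_support(victim, pruned)
  expect_equal(calls2$verdict, "novel")
})
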