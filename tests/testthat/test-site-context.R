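# Motif-array positions, metaprofiles and random controls.

test_that("array positions map to [0,1] with unassigned counted apart", {
  arrays <- tibble::tibble(chrom = "c", start = c(1000, 5000),
                           end = c(2000, 6000))
  points <- tibble::tibble(chrom = "c", pos = c(1500, 5500, 9000))
  got <- insertion_position_in_motif_array(points, arrays)
  expect_equal(got$positions$rel[1:2], c(0.5, 0.5))
  expect_equal(got$n_unassigned, 1)
  mid_bin <- got$histogram[got$histogram$bin_lo < 0.5 &
                             got$histogram$bin_hi >= 0.5, ]
  expect_equal(sum(mid_bin$n), 2)
  expect_error(insertion_position_in_motif_array(points, arrays[0, ]),
               "empty")
})

test_that("planted Beta(3,3) relative positions are recovered", {
  cfg <- sim_config(n_genes = 160, n_exonic = 10, n_intronic_forward = 80,
                    n_intronic_reverse = 60, n_intergenic = 100)
  sim <- simulate_te_dataset(cfg, seed = 77)
  expect_gte(nrow(sim$insertions), 500)
  points <- tibble::tibble(
    chrom = sim$insertions$chrom,
    pos = (sim$insertions$start + sim$insertions$end) %/% 2)
  got <- insertion_position_in_motif_array(points, sim$arrays)
  rel <- got$positions$rel[got$positions$assigned]
  ks <- suppressWarnings(stats::ks.test(rel, function(q)
    stats::pbeta(q, 3, 3)))
  expect_lt(unname(ks$statistic), 0.1)
  # central positional bias: histogram mode near the middle
  h <- got$histogram
  expect_true(abs(h$bin_lo[which.max(h$n)] - 0.5) <= 0.2)
})

test_that("metaprofile of a constant track is constant", {
  track <- tibble::tibble(chrom = "c", start = 0, end = 100000, value = 3)
  sites <- tibble::tibble(chrom = "c", pos = c(20000, 50000, 80000))
  mp <- metaprofile(sites, track, flank = 1000, bin = 10)
  expect_true(all(mp$profile$signal == 3))
  expect_equal(ncol(mp$matrix), 200)
  expect_error(metaprofile(sites, track, flank = 1005, bin = 10),
               "multiple")
  expect_error(metaprofile(sites, dplyr::mutate(track, value = NaN),
                           flank = 1000, bin = 10), "finite")
})

test_that("a delta peak upstream of oriented sites lands in the right bin", {
  peaks <- tibble::tibble(chrom = "c",
                          start = c(9900, 59900) - 5,
                          end = c(9900, 59900) + 5, value = 10)
  # plus-strand site at 10000 (peak at -100), minus-strand site at 59800
  # (peak at 59900 - 1 - 59800 = +99 in genomic, i.e. -100 in gene space)
  sites <- tibble::tibble(chrom = "c", pos = c(10000, 59800),
                          strand = c("+", "-"))
  mp <- metaprofile(sites, peaks, flank = 500, bin = 10)
  top <- mp$profile$offset[which.max(mp$profile$signal)]
  expect_lte(abs(top - (-100)), 10)
  # both rows peak at the same bin (orientation-aware flip)
  expect_equal(which.max(mp$matrix[1, ]), which.max(mp$matrix[2, ]),
               tolerance = 1)
})

test_that("metaprofile is linear in the track", {
  withr::local_seed(3)
  mk_track <- function() {
    starts <- seq(0, 99000, by = 1000)
    tibble::tibble(chrom = "c", start = starts, end = starts + 1000,
                   value = runif(length(starts), 0, 5))
  }
  t1 <- mk_track(); t2 <- mk_track()
  tsum <- dplyr::mutate(t1, value = value + t2$value)
  sites <- tibble::tibble(chrom = "c", pos = c(30000, 60000))
  m1 <- metaprofile(sites, t1, flank = 2000, bin = 20)
  m2 <- metaprofile(sites, t2, flank = 2000, bin = 20)
  ms <- metaprofile(sites, tsum, flank = 2000, bin = 20)
  expect_equal(ms$profile$signal, m1$profile$signal + m2$profile$signal,
               tolerance = 1e-9)
  avg <- metaprofile_average(list(m1, m2))
  expect_equal(avg$signal, (m1$profile$signal + m2$profile$signal) / 2)
})

test_that("random controls are seeded, in bounds, and flat on a flat track", {
  lens <- c(chr1 = 250000, chr2 = 150000)   # ~50x the window length
  c1 <- random_control(lens, n = 200, window_len = 7546, seed = 6)
  c2 <- random_control(lens, n = 200, window_len = 7546, seed = 6)
  expect_identical(c1, c2)
  expect_true(all(c1$start >= 0))
  expect_true(all(c1$end <= lens[c1$chrom]))
  expect_error(random_control(lens, n = 10, window_len = 7546), "seed")
  expect_error(random_control(c(chr1 = 100), window_len = 7546, seed = 1),
               "window")
  track <- tibble::tibble(chrom = rep(names(lens), 1),
                          start = 0, end = lens, value = 2)
  mp <- metaprofile(c1, track, flank = 2000, bin = 10)
  expect_lt(max(mp$profile$signal) / min(mp$profile$signal), 1.2)
})
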