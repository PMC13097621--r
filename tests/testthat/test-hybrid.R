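# Donor motif discovery, hybrid-splice event calling, and the
# splicing-competence test.

test_that("donor scan finds the planted donor 43 nt past the LTR", {
  fx <- make_l3_fixture()
  hits <- find_donor_motifs(fx$te_sequence, fx$ltr_end)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 43)
  expect_equal(substr(hits$heptamer, 1, 6), "GTAAGT")
})

test_that("donor scan handles empty and multiple matches, rejects non-GT", {
  expect_equal(nrow(find_donor_motifs("AAAA", 0)), 0)
  seq <- paste0(strrep("C", 50), "GTAAGTG", strrep("C", 20), "GTAAGTA")
  hits <- find_donor_motifs(seq, 10)
  expect_equal(hits$position, c(50, 77))
  expect_equal(hits$offset, c(40, 67))
  expect_error(find_donor_motifs("ACGT", 0, pattern = "ATAAGT"), "GT")
  # the weaker copia-type donor is scanned by pattern swap
  got <- find_donor_motifs(paste0(strrep("A", 30), "GTATGTT"), 0,
                           pattern = "GTATGT")
  expect_equal(got$position, 30)
})

test_that("the flagship fixture yields one event skipping exons 1-3", {
  fx <- make_l3_fixture()
  calls <- classify_insertions(fx$insertions, fx$genes)
  expect_equal(calls$class, "intronic")
  expect_equal(calls$intron_ordinal, 3L)
  ev <- call_hybrid_events(calls, fx$transcripts, fx$genes)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$skipped_exons, "1,2,3")
  expect_equal(ev$acceptor_ordinal, 4L)
  # donor sits 43 nt past the 5' LTR end on the element
  expect_equal(ev$donor_offset - fx$ltr_end, 43)
  # planted downstream distance is recovered
  d <- distance_to_downstream_exon(calls, fx$genes)
  expect_equal(d$distance_downstream, fx$true_distance)
})

test_that("canonical transcripts yield no events", {
  fx <- make_l3_fixture()
  calls <- classify_insertions(fx$insertions, fx$genes)
  canonical <- dplyr::filter(fx$transcripts,
                             transcript_id == "iso_canonical")
  expect_equal(nrow(call_hybrid_events(calls, canonical, fx$genes)), 0)
  expect_error(
    call_hybrid_events(calls,
                       dplyr::mutate(canonical, chrom = "chrZ"),
                       fx$genes),
    "chromosome")
})

test_that("planted hybrid and canonical transcripts separate perfectly", {
  sim <- small_sim(seed = 11)
  calls <- classify_insertions(sim$insertions, sim$genes)
  ev <- call_hybrid_events(calls, sim$transcripts, sim$genes)
  truth <- dplyr::distinct(
    dplyr::filter(sim$transcripts, hybrid),
    transcript_id, insertion_id)
  expect_setequal(ev$transcript_id, truth$transcript_id)
  got <- dplyr::left_join(ev, truth, by = "transcript_id")
  expect_equal(got$insertion_id.x, got$insertion_id.y)
  # per-insertion verdicts match the planted spliced flags
  v <- hybrid_verdicts(calls, ev)
  truth_flags <- sim$insertions$spliced[match(v$insertion_id,
                                              sim$insertions$id)]
  expect_equal(v$hybrid, truth_flags)
  # every donor lies inside its insertion, upstream of its acceptor
  ins <- sim$insertions[match(ev$insertion_id, sim$insertions$id), ]
  expect_true(all(ev$donor_pos >= ins$start & ev$donor_pos < ins$end))
  expect_true(all(ev$te_segment_len >= 1))
})

test_that("event calling is invariant under a constant coordinate shift", {
  sim <- small_sim(seed = 13)
  shift <- function(df, by) dplyr::mutate(df, start = start + by,
                                          end = end + by)
  calls <- classify_insertions(sim$insertions, sim$genes)
  ev <- call_hybrid_events(calls, sim$transcripts, sim$genes)
  calls2 <- classify_insertions(shift(sim$insertions, 10000),
                                shift(sim$genes, 10000))
  ev2 <- call_hybrid_events(calls2, shift(sim$transcripts, 10000),
                            shift(sim$genes, 10000))
  expect_equal(ev2$transcript_id, ev$transcript_id)
  expect_equal(ev2$donor_pos, ev$donor_pos + 10000)
  expect_equal(ev2$skipped_exons, ev$skipped_exons)
})

test_that("acceptor tolerance zero still recovers exact fixtures", {
  sim <- small_sim(seed = 17)
  calls <- classify_insertions(sim$insertions, sim$genes)
  ev <- call_hybrid_events(calls, sim$transcripts, sim$genes,
                           acceptor_tol = 0)
  expect_equal(nrow(ev),
               length(unique(sim$transcripts$transcript_id[
                 sim$transcripts$hybrid])))
})

test_that("splicing-competence test reports U, p, medians and delta", {
  res <- splicing_competence_test(c(1, 2), c(3, 4))
  expect_equal(res$mwu$U, 0)
  expect_equal(res$mwu$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$delta, 3.5 - 1.5)
  t <- tidy(res)
  expect_equal(t$median_with, 1.5)
  expect_equal(t$median_without, 3.5)
  same <- splicing_competence_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$mwu$p_value, 1)
  expect_error(splicing_competence_test(numeric(0), 1), "non-empty")
})

test_that("distance model separates spliced insertions across replicates", {
  withr::local_seed(31)
  n_rep <- 100
  sig <- logical(n_rep)
  ratios <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- simulate_splice_distances(110)
    res <- splicing_competence_test(d$distance[d$spliced],
                                    d$distance[!d$spliced])
    sig[i] <- res$mwu$p_value < 0.05
    ratios[i] <- res$median_without / res$median_with
  }
  expect_gte(mean(sig), 0.95)
  expect_equal(median(ratios), 3.6, tolerance = 0.15)
})
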