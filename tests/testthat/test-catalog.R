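# Insertion classification, composition, distances, flank liftover and
# stratification.

test_that("full-length filter applies inclusive boundaries", {
  ins <- bind_rows(toy_insertion(0, 7546), toy_insertion(0, 7499, id = "i2"),
                   toy_insertion(0, 7500, id = "i3"))
  kept <- filter_full_length(ins, min_len = 7500)
  expect_equal(kept$id, c("i1", "i3"))
  kept2 <- filter_full_length(ins, consensus_len = 7546, min_frac = 0.995)
  expect_equal(kept2$id, "i1")   # 0.995 * 7546 = 7508.3
  both <- filter_full_length(ins, consensus_len = 7546, min_len = 7400,
                             min_frac = 0.99)
  expect_equal(both$id, c("i1", "i2", "i3"))
  expect_equal(nrow(filter_full_length(ins[0, ], min_len = 1)), 0)
  expect_error(filter_full_length(ins), "min_len")
  expect_error(filter_full_length(ins, consensus_len = 0, min_frac = 0.9),
               "consensus_len")
})

test_that("classification covers intronic/exonic/intergenic with orientation", {
  genes <- toy_genes()
  # intronic forward, intron 1
  call <- classify_insertions(toy_insertion(250, 260), genes)
  expect_equal(call$class, "intronic")
  expect_equal(call$orientation, "forward")
  expect_equal(call$intron_ordinal, 1L)
  # same insertion on the minus strand is reverse
  expect_equal(
    classify_insertions(toy_insertion(250, 260, strand = "-"),
                        genes)$orientation, "reverse")
  # no gene overlap
  expect_equal(classify_insertions(toy_insertion(500, 600), genes)$class,
               "intergenic")
  # >= 1 bp exon overlap wins over intronic
  expect_equal(classify_insertions(toy_insertion(190, 210), genes)$class,
               "exonic")
  expect_error(
    classify_insertions(toy_insertion(10, 20, chrom = "chrZ"), genes),
    "chromosome")
})

test_that("intergenic calls carry no host gene or orientation", {
  call <- classify_insertions(toy_insertion(950, 980), toy_genes())
  expect_true(is.na(call$gene_id))
  expect_equal(call$orientation, "not-applicable")
})

test_that("context composition sums to one and handles empty classes", {
  genes <- toy_genes()
  calls <- classify_insertions(
    bind_rows(lapply(1:10, function(i)
      toy_insertion(200 + i, 200 + i + 5, id = paste0("i", i)))), genes)
  comp <- context_composition(calls)
  expect_equal(comp$fraction[comp$class == "intronic"], 1)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_error(context_composition(calls[0, ]), "empty")
})

test_that("genome composition partitions exonic/intronic/intergenic", {
  genes <- tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = c(100L, 350L), end = c(200L, 400L), strand = "+",
    exon_rank = 1:2)
  comp <- genome_feature_composition(genes, 1000)
  expect_equal(comp$fraction, c(0.15, 0.15, 0.70))
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
})

test_that("downstream-exon distance follows gene orientation", {
  genes <- toy_genes()
  calls <- classify_insertions(toy_insertion(250, 260), genes) |>
    distance_to_downstream_exon(genes)
  expect_equal(calls$distance_downstream, 40)
  # abutting the next exon gives zero
  calls0 <- classify_insertions(toy_insertion(250, 300), genes) |>
    distance_to_downstream_exon(genes)
  expect_equal(calls0$distance_downstream, 0)
  # mirror case on the minus-strand layout gives the same value
  callsm <- classify_insertions(
    toy_insertion(740, 750, strand = "-"), toy_genes_minus()) |>
    distance_to_downstream_exon(toy_genes_minus())
  expect_equal(callsm$distance_downstream, 40)
  # the legend-variant boundary measures to the exon 3' end
  callse <- classify_insertions(toy_insertion(250, 260), genes) |>
    distance_to_downstream_exon(genes, boundary = "end")
  expect_equal(callse$distance_downstream, 140)
  # insertion in the last intron region beyond annotation: no downstream
  genes1 <- toy_genes()
  calls_na <- classify_insertions(toy_insertion(250, 260), genes1)
  calls_na$gene_id <- "gA"; calls_na$start <- 420; calls_na$end <- 430
  out <- distance_to_downstream_exon(calls_na, genes1)
  expect_true(is.na(out$distance_downstream))
})

test_that("classification is invariant under reverse-complementing the locus", {
  sim <- small_sim(seed = 9)
  genome_len <- max(sim$genes$end) + 1000
  flip <- function(df) {
    out <- df
    out$start <- genome_len - df$end
    out$end <- genome_len - df$start
    out$strand <- ifelse(df$strand == "+", "-", "+")
    out
  }
  genes_rc <- flip(sim$genes)
  calls <- classify_insertions(sim$insertions, sim$genes) |>
    distance_to_downstream_exon(sim$genes)
  calls_rc <- classify_insertions(flip(sim$insertions), genes_rc) |>
    distance_to_downstream_exon(genes_rc)
  expect_equal(calls_rc$class, calls$class)
  expect_equal(calls_rc$orientation, calls$orientation)
  expect_equal(calls_rc$intron_ordinal, calls$intron_ordinal)
  expect_equal(calls_rc$distance_downstream, calls$distance_downstream)
})

test_that("flank liftover computes midpoints and concordance states", {
  left <- tibble::tibble(id = c("a", "b", "c", "d"),
                         chrom = c("chr1", "chr1", "chr1", "chr1"),
                         start = c(1000, 1000, 1000, 1000),
                         end = c(1100, 1100, 1100, 1100),
                         strand = "+")
  right <- tibble::tibble(id = c("a", "b", "c"),
                          chrom = c("chr1", "chr2", "chr1"),
                          start = c(1105, 1105, 6100),
                          end = c(1205, 1205, 6200),
                          strand = "+")
  got <- lift_by_flanks(left, right, max_gap = 100)
  expect_equal(got$status[got$id == "a"], "concordant")
  expect_equal(got$position[got$id == "a"], 1102L)
  expect_equal(got$status[got$id == "b"], "discordant-chrom")
  expect_equal(got$status[got$id == "c"], "discordant-gap")
  expect_equal(got$status[got$id == "d"], "unmapped")
})

test_that("liftover of flanks from the same assembly returns the site", {
  sim <- small_sim(seed = 5)
  ins <- sim$insertions
  left <- tibble::tibble(id = ins$id, chrom = ins$chrom,
                         start = ins$start - 100, end = ins$start,
                         strand = "+")
  right <- tibble::tibble(id = ins$id, chrom = ins$chrom,
                          start = ins$end, end = ins$end + 100,
                          strand = "+")
  # collapse the TE to a point: inner ends straddle the insertion span, so
  # lift against flanks re-extracted around the start point instead
  right0 <- dplyr::mutate(right, start = ins$start + 1,
                          end = ins$start + 101)
  got <- lift_by_flanks(left, right0, max_gap = 100)
  expect_true(all(got$status == "concordant"))
  expect_true(all(abs(got$position - ins$start) <= 1))
})

test_that("intron ordinal histogram counts intronic calls", {
  sim <- small_sim(seed = 7)
  calls <- classify_insertions(sim$insertions, sim$genes)
  h <- intron_position_distribution(calls)
  expect_equal(sum(h$n), sum(calls$class == "intronic" &
                               !is.na(calls$intron_ordinal)))
  truth <- table(sim$insertions$true_ordinal[
    sim$insertions$true_class == "intronic"])
  expect_equal(h$n, as.integer(truth[as.character(h$intron_ordinal)]))
})

test_that("expression stratification recovers placement bias and the null", {
  withr::local_seed(21)
  n_genes <- 2000
  expression <- tibble::tibble(gene_id = paste0("g", seq_len(n_genes)),
                               expression = rlnorm(n_genes, 3, 1))
  pick <- function(prob) tibble::tibble(
    insertion_id = paste0("i", 1:400), class = "intronic",
    gene_id = sample(expression$gene_id, 400, replace = TRUE,
                     prob = prob))
  strat_bias <- expression_stratify(pick(expression$expression),
                                    expression, n_bins = 5)
  expect_true(all(diff(strat_bias$enrichment) > 0))
  strat_null <- expression_stratify(pick(NULL), expression, n_bins = 5)
  expect_true(all(abs(strat_null$enrichment - 1) < 0.35))
  expect_error(expression_stratify(pick(NULL), expression, n_bins = 1),
               "n_bins")
})
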