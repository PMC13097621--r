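# Shared in-code fixtures. Everything is generated programmatically.

# a two-exon plus-strand gene: exons [100,200) and [300,400)
toy_genes <- function() {
  tibble::tibble(
    gene_id = "gA", transcript_id = "gA.t1", chrom = "chr1",
    start = c(100L, 300L), end = c(200L, 400L), strand = "+",
    exon_rank = 1:2)
}

# mirror-image minus-strand layout of toy_genes on a 1,000-bp chromosome:
# exons [600,700) and [800,900)
toy_genes_minus <- function() {
  tibble::tibble(
    gene_id = "gB", transcript_id = "gB.t1", chrom = "chr1",
    start = c(600L, 800L), end = c(700L, 900L), strand = "-",
    exon_rank = 2:1)
}

toy_insertion <- function(start, end, strand = "+", id = "i1",
                          chrom = "chr1") {
  tibble::tibble(id = id, chrom = chrom, start = start, end = end,
                 strand = strand, family = "Springer",
                 length = end - start, cons_start = 0L,
                 cons_end = end - start, divergence = 0)
}

# small RepeatMasker .out content with 3 Springer and 2 copia rows
rm_out_lines <- function() {
  hdr <- c("   SW  perc perc perc  query ...", "score  div. ...", "")
  rows <- c(
    "1000 1.5 0.0 0.0 chr1 10001 17546 (0) + Springer LTR/Gypsy 1 7546 (0) 1",
    "1000 2.0 0.0 0.0 chr1 20001 20500 (0) C Springer LTR/Gypsy (7046) 500 1 2",
    "1000 0.5 0.0 0.0 chr2 5001 12546 (0) + Springer LTR/Gypsy 1 7546 (0) 3",
    "1000 3.0 0.0 0.0 chr1 30001 35146 (0) + copia LTR/Copia 1 5146 (0) 4",
    "1000 1.0 0.0 0.0 chr2 40001 40800 (0) C copia LTR/Copia (4346) 800 1 5")
  c(hdr, rows)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force two-sided Mann-Whitney p-value by enumerating all rank
# assignments (independent oracle for the exact method)
mwu_permutation_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pool <- rank(c(x, y))
  u_obs <- sum(pool[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, function(s) sum(pool[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

small_sim <- function(seed = 3, ...) {
  simulate_te_dataset(
    sim_config(n_genes = 20, n_exonic = 2, n_intronic_forward = 6,
               n_intronic_reverse = 3, n_intergenic = 4, ...),
    seed = seed)
}
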