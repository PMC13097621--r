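# Writers matching the readers in io-read.R. Column orders are stable and
# writers/readers round-trip on canonical records.

#' Write TE insertions as a RepeatMasker-style `.out` file
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive convention; `-` strand is written as `C` with consensus fields
#' in the reversed order RepeatMasker uses.
#'
#' @param insertions A tibble as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @param consensus_len Named vector of consensus lengths per family (used
#'   for the "left" fields; families absent default to `cons_end`).
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(insertions, path, consensus_len = NULL) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  body <- pmap(insertions, function(id, chrom, start, end, strand, family,
                                    repeat_class, length, cons_start,
                                    cons_end, divergence, ...) {
    clen <- if (!is.null(consensus_len) && family %in% names(consensus_len))
      consensus_len[[family]] else cons_end
    left <- clen - cons_end
    if (strand == "+") {
      cons_fields <- c(cons_start + 1L, cons_end, sprintf("(%d)", left))
      ssym <- "+"
    } else {
      cons_fields <- c(sprintf("(%d)", left), cons_end, cons_start + 1L)
      ssym <- "C"
    }
    paste(1000, sprintf("%.1f", divergence), "0.0", "0.0", chrom,
          start + 1L, end, "(0)", ssym, family, repeat_class,
          cons_fields[1], cons_fields[2], cons_fields[3],
          sub(".*_", "", id))
  })
  readr::write_lines(c(hdr, unlist(body)), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes Exon tibble as returned by [read_gff3_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  genes <- arrange(genes, .data$chrom, .data$start)
  gene_rows <- genes |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  tx_rows <- genes |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    paste(chrom, src, type, start + 1L, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  lines <- "##gff-version 3"
  for (g in seq_len(nrow(gene_rows))) {
    gr <- gene_rows[g, ]
    lines <- c(lines, fmt(gr$chrom, "terewire", "gene", gr$start, gr$end,
                          gr$strand, paste0("ID=", gr$gene_id)))
    txs <- filter(tx_rows, .data$gene_id == gr$gene_id)
    for (t in seq_len(nrow(txs))) {
      tr <- txs[t, ]
      lines <- c(lines, fmt(tr$chrom, "terewire", "mRNA", tr$start, tr$end,
                            tr$strand,
                            paste0("ID=", tr$transcript_id, ";Parent=",
                                   tr$gene_id)))
      ex <- genes |>
        filter(.data$transcript_id == tr$transcript_id) |>
        arrange(.data$start)
      lines <- c(lines, fmt(ex$chrom, "terewire", "exon", ex$start, ex$end,
                            ex$strand,
                            paste0("ID=", tr$transcript_id, ":exon:",
                                   seq_len(nrow(ex)), ";Parent=",
                                   tr$transcript_id)))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write transcript models as BED12
#'
#' @param transcripts Exon tibble as returned by [read_bed12_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12_transcripts <- function(transcripts, path) {
  lines <- transcripts |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      chrom = first(.data$chrom),
      chrom_start = min(.data$start),
      chrom_end = max(.data$end),
      strand = first(.data$strand),
      n_blocks = n(),
      sizes = paste0(paste(.data$end - .data$start, collapse = ","), ","),
      starts = paste0(paste(.data$start - min(.data$start), collapse = ","),
                      ","),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$chrom_start)
  out <- with(lines, paste(chrom, chrom_start, chrom_end, transcript_id, 0,
                           strand, chrom_start, chrom_end, "0", n_blocks,
                           sizes, starts, sep = "\t"))
  readr::write_lines(out, path)
  invisible(path)
}

#' Write alignments as SAM text
#'
#' Reads are written as single-block matches (`<len>M`). A `seq` column is
#' used when present; otherwise a run of `N` of length `read_len` is
#' emitted.
#'
#' @param alignments Tibble with columns `qname`, `chrom`, `start`,
#'   `strand`, `mapq`, `read_len` and optionally `seq`.
#' @param refs Tibble with columns `name`, `length` for the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", refs$name, "\tLN:", refs$length))
  seqs <- if ("seq" %in% names(alignments)) alignments$seq else
    strrep("N", alignments$read_len)
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  body <- paste(alignments$qname, flag, alignments$chrom,
                alignments$start + 1L, alignments$mapq,
                paste0(alignments$read_len, "M"), "*", 0, 0, seqs, "*",
                sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' @param track Tibble with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_lines(
    paste(track$chrom, track$start, track$end,
          format(track$value, trim = TRUE, scientific = FALSE), sep = "\t"),
    path)
  invisible(path)
}

#' Write alignment blocks as PAF
#'
#' @param blocks Tibble as returned by [read_paf()]; a non-`NA` `class`
#'   column is emitted as a `cl:Z:` tag.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  tag <- ifelse(is.na(blocks$class), "",
                paste0("\tcl:Z:", blocks$class))
  lines <- paste0(
    paste(blocks$qname, blocks$qlen, blocks$qstart, blocks$qend,
          blocks$strand, blocks$tname, blocks$tlen, blocks$tstart,
          blocks$tend, blocks$n_match, blocks$block_len, blocks$mapq,
          sep = "\t"),
    tag)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a gene expression table
#'
#' @param expression Tibble with columns `gene_id`, `expression`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
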