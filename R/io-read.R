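# Readers for the external formats consumed by the pipeline. Everything is
# converted to the internal 0-based half-open convention on the way in.
#
# GFF3 and bedGraph go through rtracklayer; FASTA through Biostrings; CIGAR
# arithmetic through GenomicAlignments. RepeatMasker .out, SAM text, BED12
# and PAF are parsed here because the contract includes text-level
# validation (column counts, strand symbols, CIGAR ops) with errors naming
# the offending line.

#' Read a RepeatMasker annotation file
#'
#' Parses RepeatMasker `.out` output (space-delimited, three header lines)
#' into a tibble of TE insertions. 1-based inclusive query coordinates are
#' converted to 0-based half-open; the `C` strand symbol is mapped to `-`.
#' Consensus begin/end (also converted to 0-based half-open) and percent
#' divergence are retained.
#'
#' Adjacent rows of the same family on the same strand and chromosome,
#' separated by less than `merge_gap` bases, can optionally be merged into a
#' single insertion (`merge = TRUE`); LTR copies are often reported as
#' fragmented rows. With `merge = FALSE` (default) raw row counts are
#' preserved.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @param family_filter Optional repeat family name; only matching rows are
#'   returned.
#' @param merge Merge nearby same-family, same-strand fragments?
#' @param merge_gap Maximum gap (nt) between fragments merged when
#'   `merge = TRUE`.
#' @return A tibble with columns `id`, `chrom`, `start`, `end`, `strand`,
#'   `family`, `repeat_class`, `length`, `cons_start`, `cons_end`,
#'   `divergence`, sorted by (`chrom`, `start`).
#' @export
read_repeatmasker_out <- function(path, family_filter = NULL, merge = FALSE,
                                  merge_gap = 100) {
  lines <- readr::read_lines(path)
  # three header lines then blank-line-tolerant body
  body_idx <- which(seq_along(lines) > 3 & nzchar(trimws(lines)))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14 || length(f) > 16) {
      stop("malformed RepeatMasker row (", length(f), " fields) at line ", i,
           call. = FALSE)
    }
    strand_sym <- f[9]
    if (!strand_sym %in% c("+", "C")) {
      stop("unknown strand symbol '", strand_sym, "' at line ", i,
           call. = FALSE)
    }
    # consensus coords: + rows are (begin, end, left); C rows (left, end, begin)
    if (strand_sym == "+") {
      cb <- as.integer(f[12]); ce <- as.integer(f[13])
    } else {
      cb <- as.integer(f[14]); ce <- as.integer(f[13])
    }
    tibble(
      chrom = f[5],
      start = as.integer(f[6]) - 1L,
      end = as.integer(f[7]),
      strand = if (strand_sym == "C") "-" else "+",
      family = f[10],
      repeat_class = f[11],
      cons_start = cb - 1L,
      cons_end = ce,
      divergence = as.numeric(f[2])
    )
  })
  out <- if (length(rows)) list_rbind(rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), family = character(),
           repeat_class = character(), cons_start = integer(),
           cons_end = integer(), divergence = numeric())
  if (!is.null(family_filter)) out <- filter(out, .data$family %in% family_filter)
  out <- arrange(out, .data$chrom, .data$start)
  if (merge && nrow(out) > 1) out <- merge_rm_fragments(out, merge_gap)
  out |>
    mutate(length = .data$end - .data$start,
           id = paste0(.data$family, "_", row_number())) |>
    select("id", "chrom", "start", "end", "strand", "family",
           "repeat_class", "length", "cons_start", "cons_end", "divergence")
}

merge_rm_fragments <- function(out, merge_gap) {
  out |>
    group_by(.data$chrom, .data$strand, .data$family) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(grp = cumsum(c(TRUE, .data$start[-1] - .data$end[-n()] >= merge_gap))) |>
    group_by(.data$chrom, .data$strand, .data$family, .data$repeat_class,
             .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              cons_start = min(.data$cons_start),
              cons_end = max(.data$cons_end),
              divergence = mean(.data$divergence), .groups = "drop") |>
    select(-"grp") |>
    arrange(.data$chrom, .data$start)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene`/`mRNA`/`exon` features linked by `ID`/`Parent` and returns
#' one row per exon with its transcript and gene, in 0-based half-open
#' coordinates. Exon chains are sorted by genomic coordinate within each
#' transcript.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`, `exon_rank` (1-based in transcription order).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  empty <- tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), exon_rank = integer())
  if (nrow(df) == 0) return(empty)
  df$type <- as.character(df$type)
  tx <- filter(df, .data$type %in% c("mRNA", "transcript"))
  tx_parent <- setNames(map_chr(tx$Parent, ~ if (length(.x)) .x[1] else NA_character_),
                        tx$ID)
  ex <- filter(df, .data$type == "exon")
  if (nrow(ex) == 0) return(empty)
  ex_parent <- map_chr(ex$Parent, ~ if (length(.x)) .x[1] else NA_character_)
  if (any(is.na(ex_parent)) || !all(ex_parent %in% names(tx_parent))) {
    bad <- which(is.na(ex_parent) | !ex_parent %in% names(tx_parent))[1]
    stop("exon with no resolvable parent transcript: ",
         ex$ID[bad] %||% paste0("exon #", bad), call. = FALSE)
  }
  out <- tibble(
    gene_id = unname(tx_parent[ex_parent]),
    transcript_id = ex_parent,
    chrom = as.character(ex$seqnames),
    start = as.integer(ex$start) - 1L,
    end = as.integer(ex$end),
    strand = as.character(ex$strand)
  ) |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = if (first(.data$strand) == "-") n() - row_number() + 1L
           else row_number()) |>
    ungroup()
  bad <- out |>
    group_by(.data$transcript_id) |>
    summarise(ovl = any(.data$start[-1] < .data$end[-n()]) && n() > 1)
  if (any(bad$ovl)) {
    stop("overlapping exons within transcript ",
         bad$transcript_id[which(bad$ovl)[1]], call. = FALSE)
  }
  arrange(out, .data$chrom, .data$start)
}

#' Read transcript models from a BED12 file
#'
#' Each BED12 line becomes one transcript; blocks become exons in
#' 0-based half-open genomic coordinates (`blockStarts` are relative to
#' `chromStart` per the format definition).
#'
#' @param path Path to a BED12 file.
#' @return A tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `exon_rank` (transcription order), one row per exon.
#' @export
read_bed12_transcripts <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != 12) {
      stop("BED12 line ", i, " has ", length(f), " fields, expected 12",
           call. = FALSE)
    }
    chrom_start <- as.integer(f[2])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop("BED12 line ", i, ": blockCount ", n_blocks,
           " does not match blockSizes/blockStarts", call. = FALSE)
    }
    check_strand(f[6], paste0("BED12 line ", i))
    tibble(
      transcript_id = f[4],
      chrom = f[1],
      start = chrom_start + starts,
      end = chrom_start + starts + sizes,
      strand = f[6]
    )
  })
  out <- if (length(rows)) list_rbind(rows) else
    tibble(transcript_id = character(), chrom = character(),
           start = integer(), end = integer(), strand = character())
  out |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (n() > 0 && first(.data$strand) == "-")
      n() - row_number() + 1L else row_number()) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

SAM_CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

#' Read alignments from a SAM text file
#'
#' Parses primary alignment records (secondary `0x100` and supplementary
#' `0x800` records are dropped, as are unmapped reads) into a tibble.
#' Orientation is taken from the `0x10` flag bit; the aligned reference
#' span comes from the CIGAR string.
#'
#' @param path Path to a SAM file.
#' @param min_mapq Minimum mapping quality to retain (default 0; a floor of
#'   10 is appropriate for accessibility data).
#' @return A tibble with columns `qname`, `chrom`, `start`, `end` (0-based
#'   half-open reference span), `strand`, `mapq`, `read_len`.
#' @export
read_sam <- function(path, min_mapq = 0) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble(qname = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), mapq = integer(),
                  read_len = integer()))
  }
  f <- strsplit(body, "\t")
  nf <- lengths(f)
  if (any(nf < 11)) {
    stop("SAM record with ", nf[which(nf < 11)[1]],
         " fields (need >= 11) at body line ", which(nf < 11)[1],
         call. = FALSE)
  }
  flag <- as.integer(map_chr(f, 2))
  cigar <- map_chr(f, 6)
  ops_seen <- unique(unlist(stringr::str_extract_all(cigar[cigar != "*"],
                                                     "[A-Z=]")))
  bad_op <- setdiff(ops_seen, SAM_CIGAR_OPS)
  if (length(bad_op)) {
    stop("unsupported CIGAR op '", bad_op[1], "'", call. = FALSE)
  }
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  f <- f[keep]; flag <- flag[keep]; cigar <- cigar[keep]
  if (length(f) == 0) {
    return(tibble(qname = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), mapq = integer(),
                  read_len = integer()))
  }
  seqs <- map_chr(f, 10)
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  read_len <- ifelse(seqs == "*", qwidth, nchar(seqs))
  out <- tibble(
    qname = map_chr(f, 1),
    chrom = map_chr(f, 3),
    start = as.integer(map_chr(f, 4)) - 1L,
    end = as.integer(map_chr(f, 4)) - 1L + span,
    strand = ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+"),
    mapq = as.integer(map_chr(f, 5)),
    read_len = as.integer(read_len)
  )
  filter(out, .data$mapq >= min_mapq)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
}

#' Read pairwise alignment blocks from a PAF file
#'
#' Parses the 12 mandatory PAF columns (already 0-based half-open). An
#' optional `cl:Z:` tag carrying a block class (`syntenic`/`rearranged`) is
#' returned in `class` when present.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `n_match`, `block_len`,
#'   `mapq`, `class`.
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 12) {
      stop("PAF line ", i, " has ", length(f), " fields, expected >= 12",
           call. = FALSE)
    }
    if (!f[5] %in% c("+", "-")) {
      stop("unknown strand symbol '", f[5], "' at PAF line ", i, call. = FALSE)
    }
    cl <- grep("^cl:Z:", f[-(1:12)], value = TRUE)
    tibble(
      qname = f[1], qlen = as.integer(f[2]),
      qstart = as.integer(f[3]), qend = as.integer(f[4]),
      strand = f[5],
      tname = f[6], tlen = as.integer(f[7]),
      tstart = as.integer(f[8]), tend = as.integer(f[9]),
      n_match = as.integer(f[10]), block_len = as.integer(f[11]),
      mapq = as.integer(f[12]),
      class = if (length(cl)) sub("^cl:Z:", "", cl[1]) else NA_character_
    )
  })
  if (length(rows)) list_rbind(rows) else
    tibble(qname = character(), qlen = integer(), qstart = integer(),
           qend = integer(), strand = character(), tname = character(),
           tlen = integer(), tstart = integer(), tend = integer(),
           n_match = integer(), block_len = integer(), mapq = integer(),
           class = character())
}

#' Read a gene expression table
#'
#' @param path Path to a TSV with columns `gene_id` and `expression`.
#' @return A tibble with columns `gene_id`, `expression`.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "expression") %in% names(out))) {
    stop("expression table must have columns gene_id and expression",
         call. = FALSE)
  }
  select(out, "gene_id", "expression")
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
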