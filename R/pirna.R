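# Strand-resolved small-RNA quantification on TE consensus sequences:
# size filtering, sense/antisense counting, CPM normalization, sense-bias
# ranking and per-position coverage tracks.

#' Filter reads to the piRNA size range
#'
#' @param reads Alignment tibble with a `read_len` column.
#' @param min_len,max_len Inclusive size bounds (nt); defaults 20-35.
#' @return The retained subset.
#' @export
size_filter <- function(reads, min_len = 20, max_len = 35) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  filter(reads, .data$read_len >= min_len, .data$read_len <= max_len)
}

#' Count sense and antisense reads per TE family
#'
#' Alignments to TE consensus sequences (one reference per family) are
#' counted once each: forward-flag alignments as sense, reverse-flag as
#' antisense. Multi-mapping is assumed resolved upstream (one alignment per
#' read). Alignments to references not in `features` are skipped with a
#' warning.
#'
#' @param alignments Alignment tibble (as from [read_sam()]) whose `chrom`
#'   names TE families.
#' @param features Character vector of TE family names (the feature
#'   namespace; zero rows are emitted for families without reads).
#' @return A stranded count table: tibble with columns `family`, `sense`,
#'   `antisense`, `sense_fraction` (percent, `NA` when no reads).
#' @export
count_by_feature_strand <- function(alignments, features) {
  unknown <- setdiff(unique(alignments$chrom), features)
  if (length(unknown)) {
    n_skip <- sum(alignments$chrom %in% unknown)
    warning(n_skip, " alignment(s) to unknown feature(s) skipped: ",
            paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    alignments <- filter(alignments, !.data$chrom %in% unknown)
  }
  counts <- alignments |>
    group_by(family = .data$chrom) |>
    summarise(sense = sum(.data$strand == "+"),
              antisense = sum(.data$strand == "-"), .groups = "drop")
  tibble(family = features) |>
    left_join(counts, by = "family") |>
    mutate(across(c("sense", "antisense"), ~ tidyr::replace_na(.x, 0L)),
           sense_fraction = if_else(
             .data$sense + .data$antisense > 0,
             100 * .data$sense / (.data$sense + .data$antisense),
             NA_real_))
}

#' Counts-per-million normalization of a stranded count table
#'
#' `CPM = 1e6 * count / denominator`. The recommended denominator is the
#' library size: total reads retained after genome mapping and size
#' filtering ("per million mapped reads"); a consensus-mapped total may be
#' used instead.
#'
#' @param table Stranded count table from [count_by_feature_strand()].
#' @param denominator Read count (> 0) used for normalization.
#' @return `table` with `sense_cpm`, `antisense_cpm`, `total_cpm` added.
#' @export
cpm_normalize <- function(table, denominator) {
  if (length(denominator) != 1 || denominator <= 0) {
    stop("denominator must be a single value > 0", call. = FALSE)
  }
  mutate(table,
         sense_cpm = 1e6 * .data$sense / denominator,
         antisense_cpm = 1e6 * .data$antisense / denominator,
         total_cpm = 1e6 * (.data$sense + .data$antisense) / denominator)
}

#' Compare sense-fraction between two libraries
#'
#' Per-family sense percentages in two stranded count tables (e.g. ovary
#' vs cultured somatic cells) and their difference. Families absent from
#' one table get an `NA` fraction there.
#'
#' @param table_a,table_b Stranded count tables sharing a feature
#'   namespace.
#' @return A tibble with columns `family`, `sense_pct_a`, `sense_pct_b`,
#'   `delta` (`a - b`, percentage points).
#' @export
sense_bias_ranking <- function(table_a, table_b) {
  dplyr::full_join(
    select(table_a, "family", sense_pct_a = "sense_fraction"),
    select(table_b, "family", sense_pct_b = "sense_fraction"),
    by = "family"
  ) |>
    mutate(delta = .data$sense_pct_a - .data$sense_pct_b)
}

#' Top-k TE families by total read count
#'
#' @param table Stranded count table.
#' @param k Number of families to keep (> 0); ties broken by family name.
#' @return The top `k` rows, ranked by `sense + antisense` descending.
#' @export
top_k_by_total <- function(table, k = 30) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  table |>
    arrange(desc(.data$sense + .data$antisense), .data$family) |>
    head(k)
}

#' Per-position stranded coverage on a TE consensus
#'
#' Each aligned base increments its consensus position on the matching
#' strand; both arrays are scaled to counts per million
#' (`1e6 / denominator`). Alignments extending past the consensus end are
#' clipped (with a message).
#'
#' @param alignments Alignment tibble whose `chrom` names TE families.
#' @param feature TE family to profile.
#' @param consensus_len Consensus length (nt).
#' @param denominator Library size used for CPM scaling.
#' @return A `consensus_coverage` tibble with columns `position` (0-based),
#'   `sense`, `antisense` (CPM), one row per consensus position;
#'   attributes `feature`, `consensus_len`, `denominator`.
#' @export
per_position_coverage <- function(alignments, feature, consensus_len,
                                  denominator) {
  if (denominator <= 0) stop("denominator must be > 0", call. = FALSE)
  aln <- filter(alignments, .data$chrom == feature)
  clipped <- sum(aln$end > consensus_len | aln$start < 0)
  if (clipped > 0) {
    message(clipped, " alignment(s) clipped to consensus bounds for ",
            feature)
  }
  aln <- mutate(aln, start = pmax(.data$start, 0L),
                end = pmin(.data$end, as.integer(consensus_len)))
  aln <- filter(aln, .data$end > .data$start)
  cover <- function(a) {
    v <- numeric(consensus_len)
    if (nrow(a)) {
      cov <- IRanges::coverage(
        IRanges::IRanges(start = a$start + 1L, end = a$end),
        width = consensus_len)
      v <- as.numeric(cov)
    }
    v * 1e6 / denominator
  }
  out <- tibble(
    position = seq_len(consensus_len) - 1L,
    sense = cover(filter(aln, .data$strand == "+")),
    antisense = cover(filter(aln, .data$strand == "-"))
  )
  structure(out, feature = feature, consensus_len = consensus_len,
            denominator = denominator,
            class = c("consensus_coverage", class(out)))
}

#' Write a consensus coverage profile as two bedGraph tracks
#'
#' Emits `<prefix>.sense.bedgraph` and `<prefix>.antisense.bedgraph`,
#' run-length encoding constant stretches.
#'
#' @param coverage A `consensus_coverage` from [per_position_coverage()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_consensus_coverage <- function(coverage, prefix) {
  feature <- attr(coverage, "feature")
  paths <- paste0(prefix, c(".sense.bedgraph", ".antisense.bedgraph"))
  for (i in 1:2) {
    vals <- coverage[[c("sense", "antisense")[i]]]
    r <- rle(vals)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    write_bedgraph(tibble(chrom = feature, start = starts[keep],
                          end = ends[keep], value = r$values[keep]),
                   paths[i])
  }
  invisible(paths)
}
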