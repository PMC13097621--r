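# Cross-assembly genome metrics: occupancy and enrichment, syntenic
# fraction of a region, binned coverage uniformity, and junction-spanning
# presence/absence calls.

#' Genome occupancy of an interval set
#'
#' Merges (unions) the intervals and reports the fraction of the genome
#' they cover.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param genome_len Total genome length (bp).
#' @return A one-row tibble: `covered_bases`, `genome_len`, `fraction`.
#' @export
occupancy <- function(intervals, genome_len) {
  if (genome_len <= 0) stop("genome_len must be > 0", call. = FALSE)
  if (nrow(intervals) > 0) {
    check_intervals(intervals, "occupancy input")
    if (any(intervals$end > genome_len)) {
      stop("interval beyond genome_len", call. = FALSE)
    }
  }
  covered <- sum_widths(merge_intervals(intervals))
  tibble(covered_bases = covered, genome_len = genome_len,
         fraction = covered / genome_len)
}

#' Per-family genome occupancy
#'
#' @param insertions Insertion tibble with a `family` column.
#' @param genome_len Total genome length (bp).
#' @return A tibble with one row per family: `family`, `covered_bases`,
#'   `genome_len`, `fraction`.
#' @export
occupancy_by_family <- function(insertions, genome_len) {
  insertions |>
    group_by(.data$family) |>
    group_split() |>
    map(function(g) mutate(occupancy(g, genome_len), family = g$family[1],
                           .before = 1)) |>
    list_rbind()
}

#' Cross-assembly TE enrichment
#'
#' Ratio of a TE family's abundance in assembly A over assembly B, either
#' as occupancy fractions (`mode = "occupancy"`) or as counts of
#' full-length copies (`mode = "copy_number"`, full-length per
#' [filter_full_length()]). A zero baseline yields `Inf` with
#' `undefined = TRUE` rather than an error.
#'
#' @param intervals_a,intervals_b Interval tibbles for the family in each
#'   assembly.
#' @param genome_len_a,genome_len_b Assembly lengths (occupancy mode).
#' @param mode `"occupancy"` or `"copy_number"`.
#' @param consensus_len,min_len,min_frac Full-length filter parameters
#'   (copy-number mode); see [filter_full_length()].
#' @return A one-row tibble: `mode`, `value_a`, `value_b`, `enrichment`,
#'   `undefined`.
#' @export
te_enrichment <- function(intervals_a, intervals_b,
                          genome_len_a = NULL, genome_len_b = NULL,
                          mode = c("occupancy", "copy_number"),
                          consensus_len = NULL, min_len = NULL,
                          min_frac = NULL) {
  mode <- match.arg(mode)
  if (mode == "occupancy") {
    if (is.null(genome_len_a) || is.null(genome_len_b)) {
      stop("occupancy mode requires genome_len_a and genome_len_b",
           call. = FALSE)
    }
    va <- occupancy(intervals_a, genome_len_a)$fraction
    vb <- occupancy(intervals_b, genome_len_b)$fraction
  } else {
    fl <- function(x) {
      if (!"length" %in% names(x)) x$length <- x$end - x$start
      nrow(filter_full_length(x, consensus_len = consensus_len,
                              min_len = min_len, min_frac = min_frac))
    }
    va <- fl(intervals_a)
    vb <- fl(intervals_b)
  }
  undefined <- vb == 0
  tibble(mode = mode, value_a = va, value_b = vb,
         enrichment = if (undefined) Inf else va / vb,
         undefined = undefined)
}

#' Syntenic fraction of a region
#'
#' Percentage of a region covered by the union of (syntenic) alignment
#' blocks, and its complement. Blocks may come from [read_paf()]; by
#' default they are taken in target coordinates, and rows with
#' `class == "rearranged"` are excluded when a `class` column is present.
#'
#' @param region One-row tibble with `chrom`, `start`, `end` in the
#'   coordinates of the chosen assembly side.
#' @param blocks PAF block tibble.
#' @param side `"target"` or `"query"`: which side of the alignment the
#'   region lives on.
#' @return A one-row tibble: `syntenic_bases`, `region_len`,
#'   `syntenic_pct`, `non_syntenic_pct` (the two percentages sum to 100
#'   exactly).
#' @export
syntenic_fraction <- function(region, blocks, side = c("target", "query")) {
  side <- match.arg(side)
  rlen <- region$end - region$start
  if (rlen <= 0) stop("empty region", call. = FALSE)
  if ("class" %in% names(blocks)) {
    blocks <- filter(blocks, is.na(.data$class) |
                       .data$class == "syntenic")
  }
  iv <- if (side == "target") {
    tibble(chrom = blocks$tname, start = blocks$tstart, end = blocks$tend)
  } else {
    tibble(chrom = blocks$qname, start = blocks$qstart, end = blocks$qend)
  }
  clipped <- clip_to_window(iv, region$chrom, region$start, region$end)
  syn <- sum_widths(merge_intervals(clipped))
  pct <- 100 * syn / rlen
  tibble(syntenic_bases = syn, region_len = rlen, syntenic_pct = pct,
         non_syntenic_pct = 100 - pct)
}

#' Binned, normalized coverage profile over a region
#'
#' Mean per-base read depth in fixed-width bins across a region, scaled by
#' a normalizer (default: reads-per-million of the supplied alignment
#' set). The across-bin coefficient of variation summarizes uniformity.
#'
#' @param alignments Alignment tibble (as from [read_sam()]).
#' @param region One-row tibble with `chrom`, `start`, `end`.
#' @param bin Bin width (nt, >= 1).
#' @param normalizer Multiplicative factor; `NULL` uses
#'   `1e6 / nrow(alignments)`.
#' @return A `region_profile` tibble with columns `bin_start`, `bin_end`,
#'   `value`; attribute `cv` holds the coefficient of variation.
#' @export
region_coverage_profile <- function(alignments, region, bin = 1000,
                                    normalizer = NULL) {
  if (bin < 1) stop("bin must be >= 1", call. = FALSE)
  rlen <- region$end - region$start
  if (rlen <= 0) stop("empty region", call. = FALSE)
  if (is.null(normalizer)) {
    normalizer <- if (nrow(alignments) > 0) 1e6 / nrow(alignments) else 1
  }
  aln <- clip_to_window(select(alignments, "chrom", "start", "end"),
                        region$chrom, region$start, region$end)
  depth <- numeric(rlen)
  if (nrow(aln)) {
    depth <- as.numeric(IRanges::coverage(
      IRanges::IRanges(start = aln$start - region$start + 1L,
                       end = aln$end - region$start),
      width = rlen))
  }
  n_bins <- ceiling(rlen / bin)
  idx <- rep(seq_len(n_bins), each = bin, length.out = rlen)
  vals <- as.numeric(tapply(depth, idx, mean)) * normalizer
  out <- tibble(
    bin_start = region$start + (seq_len(n_bins) - 1L) * bin,
    bin_end = pmin(region$start + seq_len(n_bins) * bin, region$end),
    value = vals
  )
  cv <- if (mean(vals) > 0) sd(vals) / mean(vals) else NA_real_
  structure(out, cv = cv, class = c("region_profile", class(out)))
}

#' Coefficient of variation of a region coverage profile
#'
#' @param profile A `region_profile` from [region_coverage_profile()].
#' @return The across-bin coefficient of variation.
#' @export
coverage_cv <- function(profile) attr(profile, "cv")

#' Junction-spanning presence/absence calls for TE insertions
#'
#' A read supports the left junction of an insertion when its aligned span
#' covers `[start - min_overhang, start + min_overhang)`; the right
#' junction analogously at `end`. An insertion is called `preexisting`
#' when both junctions have at least `min_support` supporting reads
#' (`require_both = FALSE` relaxes to either junction, for truncated
#' insertions), else `novel`.
#'
#' @param insertions Insertion tibble (`id`, `chrom`, `start`, `end`).
#' @param alignments Read alignments to the insertion-bearing assembly.
#' @param min_overhang Required overhang on each side of a junction
#'   (nt, >= 1).
#' @param min_support Minimum supporting reads per junction.
#' @param require_both Require both junctions (default) or either.
#' @return A tibble: `id`, `left_support`, `right_support`, `verdict`
#'   (`preexisting` or `novel`).
#' @export
junction_support <- function(insertions, alignments, min_overhang = 10,
                             min_support = 1, require_both = TRUE) {
  if (min_overhang < 1) stop("min_overhang must be >= 1", call. = FALSE)
  count_spanning <- function(chrom, point) {
    sum(alignments$chrom == chrom &
          alignments$start <= point - min_overhang &
          alignments$end >= point + min_overhang)
  }
  out <- pmap(select(insertions, "id", "chrom", "start", "end"),
              function(id, chrom, start, end) {
    l <- count_spanning(chrom, start)
    r <- count_spanning(chrom, end)
    ok <- if (require_both) l >= min_support && r >= min_support else
      l >= min_support || r >= min_support
    tibble(id = id, left_support = l, right_support = r,
           verdict = if (ok) "preexisting" else "novel")
  })
  list_rbind(out)
}
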