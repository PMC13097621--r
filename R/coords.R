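# Internal coordinate and interval helpers. Every tibble of intervals in the
# package uses 0-based half-open [start, end) with strand in {+, -, *}.

VALID_STRANDS <- c("+", "-", "*")

check_strand <- function(strand, where = "record") {
  bad <- !strand %in% VALID_STRANDS
  if (any(bad)) {
    stop("unknown strand symbol '", strand[which(bad)[1]], "' in ", where,
         call. = FALSE)
  }
  invisible(strand)
}

check_intervals <- function(df, where = "intervals") {
  stopifnot(all(c("start", "end") %in% names(df)))
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("invalid interval (need 0 <= start < end) in ", where, call. = FALSE)
  }
  invisible(df)
}

#' Convert between 0-based half-open and 1-based inclusive coordinates
#'
#' `to_one_based()` and `to_zero_based()` shift the `start`/`end` columns of a
#' tibble between the package's internal 0-based half-open convention and the
#' 1-based inclusive convention used by GFF3, RepeatMasker and SAM. They are
#' exact inverses.
#'
#' @param x A data frame with `start` and `end` columns.
#' @return A tibble with converted coordinates.
#' @examples
#' x <- tibble::tibble(start = 100, end = 200)
#' to_zero_based(to_one_based(x))
#' @export
to_one_based <- function(x) {
  dplyr::mutate(as_tibble(x), start = .data$start + 1L)
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(x) {
  dplyr::mutate(as_tibble(x), start = .data$start - 1L)
}

# tibble -> GRanges (internal). Keeps 0-based half-open width by shifting
# start; extra columns become mcols.
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# union (merge) of intervals within each chromosome; vectorized scan over
# start-sorted intervals (cheap enough to call once per gene in loops)
merge_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  o <- order(df$chrom, df$start, df$end)
  chrom <- df$chrom[o]; start <- df$start[o]; end <- cummax_by(df$end[o],
                                                              chrom)
  # a new merged block starts where the interval does not touch the
  # running union of its predecessors on the same chromosome
  new_block <- c(TRUE, start[-1] > head(end, -1) |
                   chrom[-1] != head(chrom, -1))
  block_last <- c(new_block[-1], TRUE)
  tibble(chrom = chrom[new_block],
         start = start[new_block],
         end = end[block_last])
}

# running maximum restarted at each chromosome change
cummax_by <- function(x, by) {
  out <- x
  run_start <- c(TRUE, by[-1] != head(by, -1))
  m <- -Inf
  for (i in seq_along(x)) {
    if (run_start[i]) m <- -Inf
    m <- max(m, x[i])
    out[i] <- m
  }
  out
}

# total bases in the union of intervals
union_width <- function(df) {
  sum(merge_intervals(df)$end - merge_intervals(df)$start)
}

# intersect each interval with a single window [start, end) on window$chrom
clip_to_window <- function(df, chrom, start, end) {
  df |>
    filter(.data$chrom == !!chrom, .data$end > !!start, .data$start < !!end) |>
    mutate(start = pmax(.data$start, !!start), end = pmin(.data$end, !!end))
}
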