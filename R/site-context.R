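# Chromatin and sequence context of insertion sites: positions within
# motif/repeat arrays, site-centered accessibility metaprofiles, and
# matched random control windows.

#' Normalized insertion positions within motif arrays
#'
#' Assigns each insertion point to its containing array (or the nearest
#' array within `max_dist`, default 0 = containing only), maps the
#' position to `[0, 1]` across the array, and histograms the normalized
#' positions.
#'
#' @param points Tibble with `chrom`, `pos` (0-based points; use insertion
#'   midpoints) and optionally `id`.
#' @param arrays Tibble with `chrom`, `start`, `end` (non-empty).
#' @param max_dist Maximum distance (nt) to the nearest array for
#'   assignment.
#' @param n_bins Number of histogram bins over `[0, 1]`.
#' @return A list of class `motif_array_positions`: `positions` (tibble
#'   `chrom`, `pos`, `rel`, `assigned`), `histogram` (tibble `bin_lo`,
#'   `bin_hi`, `n`), `n_unassigned`.
#' @export
insertion_position_in_motif_array <- function(points, arrays, max_dist = 0,
                                              n_bins = 20) {
  if (nrow(arrays) == 0) stop("empty arrays", call. = FALSE)
  check_intervals(arrays, "arrays")
  rel <- rep(NA_real_, nrow(points))
  for (i in seq_len(nrow(points))) {
    a <- filter(arrays, .data$chrom == points$chrom[i])
    if (nrow(a) == 0) next
    d <- pmax(a$start - points$pos[i], points$pos[i] - (a$end - 1L), 0)
    j <- which.min(d)
    if (d[j] > max_dist) next
    p <- min(max(points$pos[i], a$start[j]), a$end[j] - 1L)
    rel[i] <- (p - a$start[j]) / (a$end[j] - a$start[j])
  }
  positions <- mutate(as_tibble(points), rel = rel,
                      assigned = !is.na(rel))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- table(cut(rel[!is.na(rel)], breaks, include.lowest = TRUE))
  hist <- tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 n = as.integer(counts))
  structure(list(positions = positions, histogram = hist,
                 n_unassigned = sum(is.na(rel))),
            class = "motif_array_positions")
}

#' Site-centered coverage metaprofile
#'
#' Resamples a coverage track into fixed bins around each site
#' (orientation-aware: rows for minus-strand sites are flipped), with
#' positions lacking data treated as zero. The mean profile is the column
#' mean over sites.
#'
#' @param sites Tibble with `chrom`, `pos` (0-based point) and optionally
#'   `strand`.
#' @param track Coverage tibble (`chrom`, `start`, `end`, `value`), e.g.
#'   from [read_bedgraph()].
#' @param flank Half-window (nt) on each side of the site; must be a
#'   multiple of `bin`.
#' @param bin Bin width (nt).
#' @return An object of class `metaprofile`: list with `matrix` (sites x
#'   bins), `profile` (tibble `offset`, `signal`; offsets are bin centers
#'   relative to the site), `flank`, `bin`, `n_sites`.
#' @export
metaprofile <- function(sites, track, flank = 5000, bin = 10) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin",
                              call. = FALSE)
  if (!all(is.finite(track$value))) {
    stop("track values must be finite", call. = FALSE)
  }
  n_bins <- 2L * as.integer(flank / bin)
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  # per-chromosome weighted coverage as an Rle; zero outside track
  covs <- map(split(track, track$chrom), function(tr) {
    IRanges::coverage(IRanges::IRanges(start = tr$start + 1L,
                                       end = tr$end),
                      weight = tr$value)
  })
  mat <- matrix(0, nrow = nrow(sites), ncol = n_bins)
  win <- 2L * flank
  for (i in seq_len(nrow(sites))) {
    cov <- covs[[sites$chrom[i]]]
    v <- numeric(win)
    if (!is.null(cov)) {
      lo <- sites$pos[i] - flank         # 0-based window start
      from <- max(lo, 0L)
      to <- min(lo + win, length(cov))
      if (to > from) {
        v[(from - lo + 1L):(to - lo)] <-
          as.numeric(S4Vectors::window(cov, start = from + 1L, end = to))
      }
    }
    row <- colMeans(matrix(v, nrow = bin))
    if (strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  offsets <- (seq_len(n_bins) - 1L) * bin - flank + bin / 2
  structure(list(matrix = mat,
                 profile = tibble(offset = offsets,
                                  signal = colMeans(mat)),
                 flank = flank, bin = bin, n_sites = nrow(sites)),
            class = "metaprofile")
}

#' Average several metaprofiles
#'
#' Arithmetic mean of the mean profiles of metaprofiles computed on the
#' same grid (e.g. per-haplotype or per-replicate profiles after
#' per-sample normalization).
#'
#' @param profiles A list of `metaprofile` objects with identical `flank`
#'   and `bin`.
#' @return A tibble `offset`, `signal`.
#' @export
metaprofile_average <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  grids <- map(profiles, ~ c(.x$flank, .x$bin))
  if (!all(map_lgl(grids, ~ identical(.x, grids[[1]])))) {
    stop("metaprofiles must share flank and bin", call. = FALSE)
  }
  sig <- Reduce(`+`, map(profiles, ~ .x$profile$signal)) / length(profiles)
  tibble(offset = profiles[[1]]$profile$offset, signal = sig)
}

#' Random control windows matched to a window length
#'
#' Samples `n` windows of length `window_len` uniformly over the given
#' chromosome lengths (chromosome chosen with probability proportional to
#' its placeable span; no overlap checking, matching the behaviour of
#' standard window-shuffling tools). Window centers serve as control
#' sites; strands are assigned at random.
#'
#' @param reference_lengths Named vector of chromosome lengths.
#' @param n Number of windows.
#' @param window_len Window length (nt), e.g. the full-length element size
#'   7,546.
#' @param seed Integer seed (mandatory).
#' @return A tibble: `chrom`, `start`, `end`, `pos` (window center),
#'   `strand`.
#' @export
random_control <- function(reference_lengths, n = 200, window_len = 7546,
                           seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ok <- reference_lengths >= window_len
  if (!any(ok)) stop("no chromosome can hold a window", call. = FALSE)
  lens <- reference_lengths[ok]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  span <- lens - window_len + 1
  chrom <- sample(names(lens), n, replace = TRUE, prob = span / sum(span))
  start <- floor(runif(n) * span[chrom])
  tibble(chrom = chrom,
         start = as.integer(start),
         end = as.integer(start + window_len),
         pos = as.integer(start + window_len %/% 2),
         strand = sample(c("+", "-"), n, replace = TRUE))
}
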