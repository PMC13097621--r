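# Position weight matrices with exact p-value calibration. Scores are
# log2 odds against a 0-order background; the null distribution of the
# score is computed exactly by dynamic programming over a discretized
# score grid (the approach used by published motif scanners), not by Monte
# Carlo. The scan and the p-value table share the same discretization, so
# looked-up p-values are exact for the discretized score.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs A 4-by-w (rows `A,C,G,T`) or w-by-4 numeric matrix of
#'   per-position base probabilities (or counts).
#' @param background Length-4 background distribution over `A,C,G,T`
#'   (summing to 1).
#' @param pseudocount Pseudo-probability added to every cell before
#'   renormalizing columns (guards against zero probabilities).
#' @return An object of class `pwm`: list with `probs` (4 x w, columns
#'   summing to 1), `background`, `width`, `pseudocount`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) == 4 && nrow(probs) != 4) probs <- t(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A,C,G,T)",
                             call. = FALSE)
  if (any(probs < 0)) stop("negative probabilities", call. = FALSE)
  probs <- sweep(probs + pseudocount, 2, colSums(probs + pseudocount), "/")
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("columns failed to normalize", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9 || length(background) != 4) {
    stop("background must be 4 probabilities summing to 1", call. = FALSE)
  }
  rownames(probs) <- DNA_BASES
  structure(list(probs = probs, background = background,
                 width = ncol(probs), pseudocount = pseudocount),
            class = "pwm")
}

#' Build an exact-match PWM from a consensus word
#'
#' Concentrates each column on the corresponding base (up to the
#' pseudocount), e.g. `pwm_from_consensus("GTAAGTG")`.
#'
#' @param word A DNA word over `A,C,G,T`.
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(word, background = rep(0.25, 4),
                               pseudocount = 1e-3) {
  bases <- strsplit(toupper(word), "")[[1]]
  if (!all(bases %in% DNA_BASES)) stop("word must be over A,C,G,T",
                                       call. = FALSE)
  m <- matrix(0, nrow = 4, ncol = length(bases),
              dimnames = list(DNA_BASES, NULL))
  m[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 1
  pwm(m, background = background, pseudocount = pseudocount)
}

#' Read a PWM from MEME minimal motif format or a 4-column TSV
#'
#' For MEME format the first motif's letter-probability matrix is used;
#' for TSV, four columns `A,C,G,T` with one row per motif position.
#'
#' @param path Input path.
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  lines <- readr::read_lines(path)
  lpm <- grep("letter-probability matrix", lines)
  if (length(lpm)) {
    rows <- list()
    for (i in seq(lpm[1] + 1, length(lines))) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) != 4 || anyNA(suppressWarnings(as.numeric(f)))) break
      rows[[length(rows) + 1]] <- as.numeric(f)
    }
    m <- do.call(rbind, rows)
  } else {
    m <- as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                   col_names = TRUE))
    if (!all(DNA_BASES %in% colnames(m))) {
      stop("PWM TSV needs columns A, C, G, T", call. = FALSE)
    }
    m <- m[, DNA_BASES, drop = FALSE]
  }
  pwm(m, background = background, pseudocount = pseudocount)
}

# integer (discretized) log2-odds score matrix: score/step rounded
pwm_int_scores <- function(x, step) {
  s <- log2(x$probs / x$background)
  round(s / step)
}

# exact null distribution of the discretized score under the background:
# list(min, probs) where probs[i] = P(int score == min + i - 1)
pwm_score_distribution <- function(x, step = 1e-3) {
  si <- pwm_int_scores(x, step)
  lo <- sum(apply(si, 2, min))
  hi <- sum(apply(si, 2, max))
  probs <- numeric(hi - lo + 1)
  # DP convolution over columns
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(x$width)) {
    col <- si[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1 + max(col)
    nxt <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- col[b] - new_lo + cur_lo
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * x$background[b]
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  list(min = cur_lo, probs = cur, step = step)
}

# p-value lookup table: pval(int_score) = P(score >= int_score)
pwm_pvalue_fun <- function(dist) {
  tail_p <- rev(cumsum(rev(dist$probs)))
  lo <- dist$min
  hi <- dist$min + length(tail_p) - 1
  function(int_score) {
    ifelse(int_score <= lo, 1,
           ifelse(int_score > hi, 0, tail_p[pmax(int_score, lo) - lo + 1]))
  }
}

#' Scan a sequence with a PWM, with exact p-value calibration
#'
#' Scores every window of the sequence (both strands by default) as the
#' sum of `log2(p_col(base) / background(base))` and assigns each window
#' the exact p-value `P(score of a random background word >= observed)`
#' from a dynamic-programming null distribution over scores discretized at
#' `step` bits (default 1e-3; the score discretization error is at most
#' `width * step / 2` bits). Windows containing `N` are skipped. Hits with
#' `p <= p_threshold` are returned sorted by position.
#'
#' @param sequence Character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param x A `pwm`.
#' @param p_threshold P-value threshold (default 1e-3).
#' @param both_strands Scan the reverse strand too?
#' @param step Score discretization step (bits).
#' @return A tibble of hits: `start`, `end` (0-based half-open), `strand`,
#'   `score` (bits, discretized), `p_value`.
#' @export
pwm_scan <- function(sequence, x, p_threshold = 1e-3, both_strands = TRUE,
                     step = 1e-3) {
  seq_chr <- toupper(as.character(sequence))
  code <- match(strsplit(seq_chr, "")[[1]], DNA_BASES)
  present <- unique(code[!is.na(code)])
  if (any(x$background[present] == 0)) {
    stop("zero background probability for a base present in the sequence; ",
         "use pseudocounts", call. = FALSE)
  }
  w <- x$width
  n <- length(code)
  if (n < w) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  score = numeric(), p_value = numeric()))
  }
  dist <- pwm_score_distribution(x, step)
  pval <- pwm_pvalue_fun(dist)
  si <- pwm_int_scores(x, step)
  scan_strand <- function(mat, strand) {
    n_win <- n - w + 1
    sc <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      b <- code[j:(j + n_win - 1)]
      ok <- ok & !is.na(b)
      v <- mat[cbind(ifelse(is.na(b), 1L, b), j)]
      sc <- sc + v
    }
    p <- pval(sc)
    keep <- ok & p <= p_threshold
    tibble(start = which(keep) - 1L, end = which(keep) - 1L + w,
           strand = strand, score = sc[keep] * step, p_value = p[keep])
  }
  hits <- scan_strand(si, "+")
  if (both_strands) {
    # reverse-complement PWM scanned on the forward sequence
    si_rc <- si[4:1, w:1, drop = FALSE]
    hits <- bind_rows(hits, scan_strand(si_rc, "-"))
  }
  arrange(hits, .data$start, .data$strand)
}

#' Exact null p-values for every word of a small PWM (enumeration oracle)
#'
#' Enumerates all `4^w` words, their (discretized) scores and exact
#' p-values. Intended for validating the dynamic-programming calibration
#' at small widths.
#'
#' @param x A `pwm` of width <= 8.
#' @param step Score discretization step (bits).
#' @return A tibble: `word`, `score_int`, `p_value`.
#' @export
pwm_enumerate <- function(x, step = 1e-3) {
  w <- x$width
  if (w > 8) stop("enumeration limited to width <= 8", call. = FALSE)
  si <- pwm_int_scores(x, step)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    sum(si[cbind(grid[i, ], seq_len(w))])
  }, numeric(1))
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(x$background[grid[i, ]])
  }, numeric(1))
  p <- vapply(scores, function(s) sum(probs[scores >= s]), numeric(1))
  tibble(
    word = apply(grid, 1, function(r) paste(DNA_BASES[r], collapse = "")),
    score_int = scores,
    p_value = p
  )
}
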