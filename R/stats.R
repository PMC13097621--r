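# Self-contained rank statistics: exact and asymptotic Mann-Whitney U,
# order-statistic medians, and a seeded percentile bootstrap. The exact null
# distribution is built by subset-sum dynamic programming over rank sums, so
# no external test implementation is involved.

#' Mann-Whitney U test (exact or normal approximation)
#'
#' Computes the two-sided Mann-Whitney U test for two independent samples.
#' `U` is reported for the first sample, using midranks for ties:
#' `U = R1 - n1 (n1 + 1) / 2`. With `method = "auto"` the exact null
#' distribution of `U` is enumerated (by dynamic programming over rank-sum
#' subsets) when there are no ties and `n1 * n2 <= 400`; otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param x,y Numeric vectors (each non-empty, all finite).
#' @param method `"auto"`, `"exact"`, or `"normal"`. `"exact"` requires
#'   tie-free data.
#' @return An object of class `mwu_test`: a list with elements `U`, `n1`,
#'   `n2`, `method`, `p_value`, `variance` (tie-corrected, normal method
#'   only). `tidy()` and `glance()` methods are provided.
#' @examples
#' mwu_test(c(1, 2), c(3, 4))
#' @export
mwu_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(c(x, y)))) {
    stop("non-finite values in input", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "exact" && ties) {
    stop("exact method requires tie-free data", call. = FALSE)
  }
  use_exact <- method == "exact" ||
    (method == "auto" && !ties && n1 * n2 <= 400)
  if (use_exact) {
    cdf <- mwu_exact_counts(n1, n2)
    total <- sum(cdf)
    lo <- sum(cdf[seq_len(u + 1)]) / total          # P(U <= u)
    hi <- sum(cdf[(u + 1):length(cdf)]) / total     # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    res <- list(U = u, n1 = n1, n2 = n2, method = "exact", p_value = p,
                variance = NA_real_)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    res <- list(U = u, n1 = n1, n2 = n2, method = "normal-approximation",
                p_value = p, variance = v)
  }
  structure(res, class = "mwu_test")
}

# counts of rank-subset sums: entry u+1 = number of n1-subsets of ranks
# 1..(n1+n2) with U = (sum of subset) - n1(n1+1)/2 = u, u in 0..n1*n2
mwu_exact_counts <- function(n1, n2) {
  n <- n1 + n2
  max_s <- sum((n2 + 1):n)   # max rank sum of an n1-subset
  # ways[k+1, s+1]: number of k-subsets of 1..v so far with rank sum s
  ways <- matrix(0, nrow = n1 + 1, ncol = max_s + 1)
  ways[1, 1] <- 1
  for (v in seq_len(n)) {
    for (k in rev(seq_len(min(v, n1)))) {
      smax <- max_s - v
      idx <- 0:smax
      ways[k + 1, idx + v + 1] <- ways[k + 1, idx + v + 1] +
        ways[k, idx + 1]
    }
  }
  counts <- ways[n1 + 1, ]
  offset <- n1 * (n1 + 1) / 2   # min rank sum
  counts[(offset + 1):(offset + n1 * n2 + 1)]
}

#' @export
print.mwu_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("  U = ", x$U, "  (n1 = ", x$n1, ", n2 = ", x$n2, ")\n", sep = "")
  cat("  two-sided p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname mwu_test
#' @param x An `mwu_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mwu_test <- function(x, ...) {
  tibble(statistic = x$U, p.value = x$p_value, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' @rdname mwu_test
#' @exportS3Method generics::glance
glance.mwu_test <- function(x, ...) tidy.mwu_test(x)

#' Sample median from order statistics
#'
#' The median of a non-empty numeric vector; for even `n`, the mean of the
#' two central order statistics.
#'
#' @param values Non-empty numeric vector.
#' @return A single number.
#' @examples
#' median_value(c(1, 2, 3, 4))
#' @export
median_value <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  s <- sort(values)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

#' Seeded percentile bootstrap confidence interval
#'
#' @param values Non-empty numeric vector.
#' @param statistic Function of a numeric vector returning one number.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed (mandatory; the caller's RNG state is
#'   preserved).
#' @return A tibble with columns `lower`, `upper`, `estimate`, `n_boot`.
#' @export
bootstrap_ci <- function(values, statistic = median_value, n_boot = 2000,
                         conf = 0.95, seed) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(values)
  stats <- vapply(seq_len(n_boot), function(i) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
  tibble(lower = qs[1], upper = qs[2], estimate = statistic(values),
         n_boot = n_boot)
}
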