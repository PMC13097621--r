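# ggplot2 helpers for the package's result types.

#' Plot a site-centered metaprofile
#'
#' @param object A `metaprofile` from [metaprofile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metaprofile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$offset, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from site (nt)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Plot stranded per-position coverage on a TE consensus
#'
#' Sense coverage is drawn above the axis, antisense below, in the
#' conventional two-sided piRNA coverage style.
#'
#' @param object A `consensus_coverage` from [per_position_coverage()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_coverage <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("sense", "antisense"),
                            names_to = "strand", values_to = "cpm")
  df$cpm <- ifelse(df$strand == "antisense", -df$cpm, df$cpm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$cpm,
                                   fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(sense = "#E69F00",
                                          antisense = "#56B4E9")) +
    ggplot2::labs(x = paste0(attr(object, "feature"),
                             " consensus position (nt)"),
                  y = "coverage (CPM)") +
    ggplot2::theme_minimal()
}

#' Bar plot of insertion context composition
#'
#' @param calls Context calls from [classify_insertions()].
#' @return A ggplot.
#' @export
plot_context_composition <- function(calls) {
  comp <- context_composition(calls)
  comp$class <- factor(comp$class,
                       levels = c("exonic", "intronic", "intergenic"))
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$class, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(exonic = "#4477AA",
                                          intronic = "#EE7733",
                                          intergenic = "grey60")) +
    ggplot2::labs(x = NULL, y = "fraction of insertions") +
    ggplot2::theme_minimal()
}

#' Dot plot of downstream-exon distances by splicing verdict
#'
#' @param verdicts Per-insertion verdicts from [hybrid_verdicts()] (with
#'   `distance_downstream` present).
#' @return A ggplot with log10-scaled distances.
#' @export
plot_splicing_distances <- function(verdicts) {
  df <- filter(verdicts, !is.na(.data$distance_downstream))
  df$group <- ifelse(df$hybrid, "hybrid splicing", "no hybrid splicing")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$distance_downstream)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "distance to downstream exon (nt)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
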