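# Host-TE hybrid-splice calling: TE-internal donor discovery on consensus
# sequences, event calling from long-read transcript models, and the
# splicing-competence distance test.

#' Find GT-type splice donor motifs on a TE sequence
#'
#' Scans the forward strand of a TE (consensus or insertion) sequence for
#' an IUPAC donor pattern and reports 0-based positions together with
#' offsets relative to the end of the 5' LTR. The canonical donor here is
#' `GTAAGT` (the heptamer context `GTAAGTG`); a weaker donor such as
#' `GTATGT` can be scanned with the same machinery.
#'
#' @param te_sequence A character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param ltr_end 0-based offset of the first base after the 5' LTR.
#' @param pattern IUPAC pattern starting with `GT`.
#' @return A tibble with columns `position` (0-based offset of the G),
#'   `heptamer` (7-nt context starting at the match), `offset`
#'   (`position - ltr_end`), sorted by position.
#' @export
find_donor_motifs <- function(te_sequence, ltr_end, pattern = "GTAAGT") {
  if (toupper(substr(pattern, 1, 2)) != "GT") {
    stop("donor pattern must start with GT", call. = FALSE)
  }
  seq <- Biostrings::DNAString(as.character(te_sequence))
  if (ltr_end < 0 || ltr_end > length(seq)) {
    stop("ltr_end outside sequence", call. = FALSE)
  }
  m <- Biostrings::matchPattern(pattern, seq, fixed = FALSE)
  pos <- Biostrings::start(m) - 1L
  hept <- vapply(pos, function(p) {
    as.character(Biostrings::subseq(seq, p + 1L,
                                    min(p + 7L, length(seq))))
  }, character(1))
  tibble(position = pos, heptamer = hept,
         offset = pos - as.integer(ltr_end)) |>
    arrange(.data$position)
}

#' Call host-TE hybrid-splicing events from long-read transcript models
#'
#' A hybrid event is emitted for a (forward intronic insertion, transcript)
#' pair when (a) the transcript's 5' end lies within the insertion interval
#' (relaxed mode: its first exon overlaps the insertion), (b) the first
#' splice junction has its donor inside the insertion and its acceptor
#' within `acceptor_tol` nt of the 5' boundary of an annotated exon of the
#' host gene, and (c) the transcript direction matches the host-gene
#' strand. Skipped exons are the annotated exons 5' of the acceptor exon
#' (ordinals on the reference isoform).
#'
#' @param calls Context calls from [classify_insertions()]; only intronic
#'   forward calls are considered.
#' @param transcripts Long-read transcript exon tibble (as from
#'   [read_bed12_transcripts()]).
#' @param genes Annotated exon tibble.
#' @param acceptor_tol Acceptor position tolerance (nt), absorbing
#'   long-read end wobble.
#' @param require_tss_in_te Require the transcript 5' end inside the TE
#'   (default); `FALSE` accepts any transcript whose first exon overlaps
#'   the TE.
#' @return A tibble of events: `insertion_id`, `transcript_id`, `gene_id`,
#'   `donor_pos` (genomic, 0-based), `donor_offset` (nt from TE 5' end),
#'   `acceptor_ordinal`, `skipped_exons` (comma-separated ordinals),
#'   `n_skipped`, `te_segment_len`.
#' @export
call_hybrid_events <- function(calls, transcripts, genes, acceptor_tol = 5,
                               require_tss_in_te = TRUE) {
  bad <- setdiff(unique(transcripts$chrom), unique(genes$chrom))
  if (length(bad)) {
    stop("transcripts on chromosome absent from the annotation: ", bad[1],
         call. = FALSE)
  }
  idx <- gene_index(genes)
  intf <- filter(calls, .data$class == "intronic",
                 .data$orientation == "forward")
  if (nrow(intf) == 0) return(empty_events())
  tx_split <- split(transcripts, transcripts$transcript_id)
  # cheap per-transcript summary so each call only examines transcripts
  # whose span overlaps the insertion
  tx_summary <- transcripts |>
    group_by(.data$transcript_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              tmin = min(.data$start), tmax = max(.data$end),
              .groups = "drop")
  events <- list()
  for (i in seq_len(nrow(intf))) {
    call <- intf[i, ]
    gid <- call$gene_id
    gstrand <- idx$spans$strand[idx$spans$gene_id == gid]
    rex <- ref_exons(idx, gid) |>
      mutate(ordinal = if (first(.data$strand) == "-")
        n() - row_number() + 1L else row_number())
    cand <- tx_summary$transcript_id[
      tx_summary$chrom == call$chrom & tx_summary$strand == gstrand &
        tx_summary$tmin < call$end & tx_summary$tmax > call$start]
    for (tx in tx_split[cand]) {
      ev <- hybrid_event_one(call, tx, gid, gstrand, rex, acceptor_tol,
                             require_tss_in_te)
      if (!is.null(ev)) events <- c(events, list(ev))
    }
  }
  if (length(events) == 0) return(empty_events())
  list_rbind(events) |> arrange(.data$insertion_id, .data$transcript_id)
}

empty_events <- function() {
  tibble(insertion_id = character(), transcript_id = character(),
         gene_id = character(), donor_pos = integer(),
         donor_offset = integer(), acceptor_ordinal = integer(),
         skipped_exons = character(), n_skipped = integer(),
         te_segment_len = integer())
}

hybrid_event_one <- function(call, tx, gid, gstrand, rex, acceptor_tol,
                             require_tss_in_te) {
  if (tx$chrom[1] != call$chrom || tx$strand[1] != gstrand) return(NULL)
  if (nrow(tx) < 2) return(NULL)
  tx <- arrange(tx, .data$start)
  plus <- gstrand == "+"
  # first exon and junction in transcription order
  first_exon <- if (plus) tx[1, ] else tx[nrow(tx), ]
  second_exon <- if (plus) tx[2, ] else tx[nrow(tx) - 1, ]
  tss <- if (plus) first_exon$start else first_exon$end - 1L
  if (require_tss_in_te) {
    if (tss < call$start || tss >= call$end) return(NULL)
  } else {
    if (first_exon$end <= call$start || first_exon$start >= call$end) {
      return(NULL)
    }
  }
  donor <- if (plus) first_exon$end else first_exon$start - 1L
  if (donor < call$start || donor >= call$end) return(NULL)
  # acceptor must sit at the 5' boundary of an annotated host exon
  acc <- if (plus) second_exon$start else second_exon$end
  bound <- if (plus) rex$start else rex$end
  d <- abs(bound - acc)
  j <- which.min(d)
  if (d[j] > acceptor_tol) return(NULL)
  acceptor_ordinal <- rex$ordinal[j]
  if (acceptor_ordinal <= 1) return(NULL)
  skipped <- sort(rex$ordinal[rex$ordinal < acceptor_ordinal])
  seg <- min(first_exon$end, call$end) - max(first_exon$start, call$start)
  offset <- if (plus) donor - call$start else (call$end - 1L) - donor
  tibble(insertion_id = call$insertion_id,
         transcript_id = tx$transcript_id[1],
         gene_id = gid,
         donor_pos = as.integer(donor),
         donor_offset = as.integer(offset),
         acceptor_ordinal = as.integer(acceptor_ordinal),
         skipped_exons = paste(skipped, collapse = ","),
         n_skipped = length(skipped),
         te_segment_len = as.integer(seg))
}

#' Per-insertion hybrid-splicing verdicts
#'
#' Joins events back onto intronic-forward calls: an insertion is scored
#' `hybrid = TRUE` when at least `min_support` distinct transcripts support
#' an event.
#'
#' @param calls Context calls.
#' @param events Event tibble from [call_hybrid_events()].
#' @param min_support Minimum number of supporting transcripts.
#' @return The intronic-forward subset of `calls` with `n_support` and
#'   `hybrid` columns added.
#' @export
hybrid_verdicts <- function(calls, events, min_support = 1) {
  support <- events |>
    distinct(.data$insertion_id, .data$transcript_id) |>
    dplyr::count(.data$insertion_id, name = "n_support")
  calls |>
    filter(.data$class == "intronic", .data$orientation == "forward") |>
    left_join(support, by = "insertion_id") |>
    mutate(n_support = tidyr::replace_na(.data$n_support, 0L),
           hybrid = .data$n_support >= min_support)
}

#' Splicing-competence distance test
#'
#' Two-sided Mann-Whitney U test comparing downstream-exon distances of
#' insertions with detected hybrid splicing against those without, with
#' group medians and their difference.
#'
#' @param distances_with Distances (nt) for insertions with hybrid
#'   splicing.
#' @param distances_without Distances (nt) for insertions without.
#' @param method Passed to [mwu_test()].
#' @return An object of class `splice_competence`: list with `mwu`
#'   (an `mwu_test`), `median_with`, `median_without`, `delta`
#'   (`median_without - median_with`), `n_with`, `n_without`. `tidy()` and
#'   `glance()` methods are provided.
#' @export
splicing_competence_test <- function(distances_with, distances_without,
                                     method = "auto") {
  if (length(distances_with) == 0 || length(distances_without) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mwu <- mwu_test(distances_with, distances_without, method = method)
  structure(list(
    mwu = mwu,
    median_with = median_value(distances_with),
    median_without = median_value(distances_without),
    delta = median_value(distances_without) - median_value(distances_with),
    n_with = length(distances_with),
    n_without = length(distances_without)
  ), class = "splice_competence")
}

#' @export
print.splice_competence <- function(x, ...) {
  cat("Splicing-competence distance test\n")
  cat("  median with splicing   :", format(x$median_with), "nt (n =",
      x$n_with, ")\n")
  cat("  median without splicing:", format(x$median_without), "nt (n =",
      x$n_without, ")\n")
  cat("  delta =", format(x$delta), "nt\n")
  print(x$mwu)
  invisible(x)
}

#' @rdname splicing_competence_test
#' @param x A `splice_competence` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.splice_competence <- function(x, ...) {
  tibble(statistic = x$mwu$U, p.value = x$mwu$p_value,
         method = x$mwu$method, median_with = x$median_with,
         median_without = x$median_without, delta = x$delta,
         n_with = x$n_with, n_without = x$n_without)
}

#' @rdname splicing_competence_test
#' @exportS3Method generics::glance
glance.splice_competence <- function(x, ...) tidy.splice_competence(x)
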