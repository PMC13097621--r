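# Insertion-context catalog: classify TE insertions against gene models,
# compute positional covariates (intron ordinal, downstream-exon distance),
# composition fractions, flank-based liftover, and positional/expression
# stratification.

#' Filter TE insertions to full-length copies
#'
#' Retains insertions whose length meets an absolute floor and/or a
#' fraction of the family consensus length (both boundaries inclusive).
#' At least one criterion must be supplied.
#'
#' @param insertions Tibble of insertions with a `length` column.
#' @param consensus_len Consensus length (nt); required when `min_frac` is
#'   given.
#' @param min_len Absolute minimum length (nt), e.g. 7500 for a 7,546-nt
#'   consensus.
#' @param min_frac Minimum fraction of `consensus_len` in `(0, 1]`.
#' @return The retained subset, same columns.
#' @export
filter_full_length <- function(insertions, consensus_len = NULL,
                               min_len = NULL, min_frac = NULL) {
  if (is.null(min_len) && is.null(min_frac)) {
    stop("supply min_len and/or min_frac", call. = FALSE)
  }
  if (!is.null(min_frac)) {
    if (is.null(consensus_len) || consensus_len <= 0) {
      stop("min_frac requires consensus_len > 0", call. = FALSE)
    }
    if (min_frac <= 0 || min_frac > 1) {
      stop("min_frac must be in (0, 1]", call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(insertions))
  if (!is.null(min_len)) keep <- keep & insertions$length >= min_len
  if (!is.null(min_frac)) {
    keep <- keep & insertions$length >= min_frac * consensus_len
  }
  insertions[keep, , drop = FALSE]
}

# per-gene summaries used by classification: span, exons split by gene,
# reference isoform (most exons, ties by transcript_id) and its introns in
# transcription order; precomputed once so classification of many
# insertions stays fast
gene_index <- function(genes) {
  spans <- genes |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              gstart = min(.data$start), gend = max(.data$end),
              .groups = "drop")
  ref_tx <- genes |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(n_exons = n(), .groups = "drop") |>
    arrange(.data$gene_id, desc(.data$n_exons), .data$transcript_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup()
  gdf <- as.data.frame(genes)
  exons_by_gene <- split(gdf[c("start", "end", "strand")], gdf$gene_id)
  ref_rows <- gdf[gdf$transcript_id %in% ref_tx$transcript_id, ]
  refex_by_gene <- lapply(
    split(ref_rows[c("start", "end", "strand")], ref_rows$gene_id),
    function(e) e[order(e$start), ])
  introns_by_gene <- lapply(refex_by_gene, function(ex) {
    m <- nrow(ex)
    if (m < 2) {
      return(data.frame(start = integer(), end = integer(),
                        ordinal = integer()))
    }
    data.frame(start = ex$end[-m], end = ex$start[-1],
               ordinal = if (ex$strand[1] == "-") rev(seq_len(m - 1)) else
                 seq_len(m - 1))
  })
  list(spans = as.data.frame(spans), exons_by_gene = exons_by_gene,
       refex_by_gene = refex_by_gene, introns_by_gene = introns_by_gene)
}

# exons of a gene's reference isoform, genomic order
ref_exons <- function(idx, gid) as_tibble(idx$refex_by_gene[[gid]])

# introns of the reference isoform with transcription-order ordinals
ref_introns <- function(idx, gid) as_tibble(idx$introns_by_gene[[gid]])

#' Classify TE insertions by genomic context and orientation
#'
#' Each insertion is called `exonic` if it overlaps at least 1 bp of any
#' exon of any isoform of an overlapping gene, `intronic` if it lies inside
#' a gene span without touching an exon, and `intergenic` otherwise.
#' Orientation is `forward` when the insertion strand equals the host-gene
#' strand (the intF configuration), `reverse` otherwise, and
#' `not-applicable` for intergenic calls. The intron ordinal (1-based,
#' 5'-to-3' in gene orientation) is the intron of the reference isoform
#' (the isoform with the most exons) containing the insertion midpoint.
#'
#' When more than one gene overlaps, the primary call goes to a gene whose
#' exon is hit, else to the gene with the shorter enclosing intron, with
#' ties broken by gene id; the `ambiguous` flag is always set in that case.
#'
#' @param insertions Tibble of insertions (`id`, `chrom`, `start`, `end`,
#'   `strand`, ...).
#' @param genes Exon tibble as from [read_gff3_genes()].
#' @return A tibble of context calls: `insertion_id`, `chrom`, `start`,
#'   `end`, `strand`, `class`, `gene_id`, `orientation`, `intron_ordinal`,
#'   `ambiguous`.
#' @export
classify_insertions <- function(insertions, genes) {
  idx <- gene_index(genes)
  known <- unique(genes$chrom)
  bad <- setdiff(unique(insertions$chrom), known)
  if (length(bad)) {
    stop("insertion on chromosome absent from annotation: ", bad[1],
         call. = FALSE)
  }
  calls <- pmap(select(insertions, "id", "chrom", "start", "end", "strand"),
                classify_one, idx = idx)
  list_rbind(calls)
}

classify_one <- function(id, chrom, start, end, strand, idx) {
  sp <- idx$spans
  ci <- which(sp$chrom == chrom & sp$gstart < end & sp$gend > start)
  base <- list(insertion_id = id, chrom = chrom, start = start, end = end,
               strand = strand)
  if (length(ci) == 0) {
    return(tibble(!!!base, class = "intergenic", gene_id = NA_character_,
                  orientation = "not-applicable",
                  intron_ordinal = NA_integer_, ambiguous = FALSE))
  }
  ambiguous <- length(ci) > 1
  cand_gid <- sp$gene_id[ci]
  cand_strand <- sp$strand[ci]
  exon_hit <- vapply(cand_gid, function(g) {
    ex <- idx$exons_by_gene[[g]]
    any(ex$start < end & ex$end > start)
  }, logical(1))
  mid <- (start + end) %/% 2
  if (any(exon_hit)) {
    k <- which(exon_hit)[order(cand_gid[exon_hit])][1]
    return(tibble(!!!base, class = "exonic", gene_id = cand_gid[k],
                  orientation = orient(strand, cand_strand[k]),
                  intron_ordinal = NA_integer_, ambiguous = ambiguous))
  }
  # intronic: pick the gene with the shortest intron enclosing the midpoint
  intron_len <- vapply(cand_gid, function(g) {
    ints <- idx$introns_by_gene[[g]]
    hit <- ints$start <= mid & mid < ints$end
    if (any(hit)) min(ints$end[hit] - ints$start[hit]) else Inf
  }, numeric(1))
  k <- order(intron_len, cand_gid)[1]
  ints <- idx$introns_by_gene[[cand_gid[k]]]
  hit <- which(ints$start <= mid & mid < ints$end)
  ordinal <- if (length(hit)) ints$ordinal[hit[1]] else NA_integer_
  tibble(!!!base, class = "intronic", gene_id = cand_gid[k],
         orientation = orient(strand, cand_strand[k]),
         intron_ordinal = as.integer(ordinal), ambiguous = ambiguous)
}

orient <- function(ins_strand, gene_strand) {
  if (ins_strand == "*") return("not-applicable")
  if (ins_strand == gene_strand) "forward" else "reverse"
}

#' Context composition of a set of calls
#'
#' Fractions of exonic / intronic / intergenic calls (summing to 1).
#'
#' @param calls Tibble of context calls from [classify_insertions()].
#' @return A tibble with columns `class`, `n`, `fraction`, one row per
#'   class (all three classes always present).
#' @export
context_composition <- function(calls) {
  if (nrow(calls) == 0) stop("empty calls", call. = FALSE)
  tibble(class = c("exonic", "intronic", "intergenic")) |>
    left_join(dplyr::count(calls, .data$class), by = "class") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           fraction = .data$n / sum(.data$n))
}

#' Genome-wide feature composition
#'
#' Partitions a genome into disjoint, exhaustive exonic / intronic /
#' intergenic compartments: exonic = union of all exons, intronic = union
#' of gene spans minus exons, intergenic = remainder.
#'
#' @param genes Exon tibble.
#' @param genome_len Total genome length (bp), or a named vector of
#'   per-chromosome lengths.
#' @return A tibble with columns `class`, `bases`, `fraction` (fractions
#'   sum to 1).
#' @export
genome_feature_composition <- function(genes, genome_len) {
  total <- sum(genome_len)
  if (total <= 0) stop("genome_len must be > 0", call. = FALSE)
  exon_bases <- sum_widths(merge_intervals(genes))
  spans <- genes |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  gene_bases <- sum_widths(merge_intervals(spans))
  intron_bases <- gene_bases - exon_bases
  tibble(
    class = c("exonic", "intronic", "intergenic"),
    bases = c(exon_bases, intron_bases, total - gene_bases)
  ) |>
    mutate(fraction = .data$bases / total)
}

sum_widths <- function(df) sum(df$end - df$start)

#' Distance from intronic-forward insertions to the nearest downstream exon
#'
#' For each intronic, forward-oriented call, the distance (nt) from the
#' insertion's 3' boundary (in gene orientation) to the 5' boundary
#' (`boundary = "start"`, default) or 3' boundary (`boundary = "end"`) of
#' the nearest downstream exon of the host gene, computed
#' mirror-symmetrically for minus-strand genes. Calls with no downstream
#' exon get `NA`.
#'
#' @param calls Context calls from [classify_insertions()].
#' @param genes Exon tibble.
#' @param boundary Which boundary of the downstream exon to measure to.
#' @return `calls` with an added `distance_downstream` column (`NA` for
#'   calls that are not intronic-forward or have no downstream exon).
#' @export
distance_to_downstream_exon <- function(calls, genes,
                                        boundary = c("start", "end")) {
  boundary <- match.arg(boundary)
  merged_by_gene <- lapply(split(as.data.frame(genes), genes$gene_id),
                           function(g) {
    m <- merge_intervals(g)
    m$strand <- g$strand[1]
    m
  })
  dist_one <- function(insertion_start, insertion_end, gene_id, class,
                       orientation) {
    if (is.na(gene_id) || class != "intronic" || orientation != "forward") {
      return(NA_real_)
    }
    ex <- merged_by_gene[[gene_id]]
    if (ex$strand[1] == "+") {
      down <- filter(ex, .data$start >= insertion_end)
      if (nrow(down) == 0) return(NA_real_)
      b <- if (boundary == "start") min(down$start) else
        down$end[which.min(down$start)]
      b - insertion_end
    } else {
      down <- filter(ex, .data$end <= insertion_start)
      if (nrow(down) == 0) return(NA_real_)
      b <- if (boundary == "start") max(down$end) else
        down$start[which.max(down$end)]
      insertion_start - b
    }
  }
  calls$distance_downstream <- pmap(
    list(calls$start, calls$end, calls$gene_id, calls$class,
         calls$orientation), dist_one) |> unlist()
  calls
}

#' Lift insertion sites between assemblies via paired flank hits
#'
#' Given the best alignment hit of the left and right 100-bp flank of each
#' insertion on a target assembly, a site is `concordant` when both flanks
#' hit the same chromosome in the same relative orientation with inner ends
#' separated by at most `max_gap` (default 100 nt, covering target-site
#' duplications); the lifted position is the floor of the midpoint between
#' the inner flank ends. Missing hits give status `unmapped`.
#'
#' @param left_hits,right_hits Tibbles with columns `id`, `chrom`, `start`,
#'   `end`, `strand` (target-assembly coordinates of the flank hits).
#' @param max_gap Maximum inner gap (nt).
#' @return A tibble with columns `id`, `target_chrom`, `position`,
#'   `target_strand`, `status` (one of `concordant`, `discordant-chrom`,
#'   `discordant-strand`, `discordant-gap`, `unmapped`).
#' @export
lift_by_flanks <- function(left_hits, right_hits, max_gap = 100) {
  ids <- union(left_hits$id, right_hits$id)
  out <- map(ids, function(i) {
    l <- filter(left_hits, .data$id == i)
    r <- filter(right_hits, .data$id == i)
    if (nrow(l) == 0 || nrow(r) == 0) {
      return(tibble(id = i, target_chrom = NA_character_,
                    position = NA_integer_, target_strand = NA_character_,
                    status = "unmapped"))
    }
    l <- l[1, ]; r <- r[1, ]
    status <- if (l$chrom != r$chrom) "discordant-chrom"
    else if (l$strand != r$strand) "discordant-strand"
    else if (abs(r$start - l$end) > max_gap) "discordant-gap"
    else "concordant"
    pos <- if (status == "concordant") (l$end + r$start) %/% 2 else
      NA_integer_
    tibble(id = i, target_chrom = l$chrom, position = as.integer(pos),
           target_strand = l$strand, status = status)
  })
  list_rbind(out)
}

#' Distribution of intronic insertions over intron ordinals
#'
#' @param calls Context calls; only intronic calls with a known ordinal are
#'   counted.
#' @return A tibble with columns `intron_ordinal`, `n` (counts sum to the
#'   number of intronic calls with a resolved ordinal).
#' @export
intron_position_distribution <- function(calls) {
  calls |>
    filter(.data$class == "intronic", !is.na(.data$intron_ordinal)) |>
    dplyr::count(.data$intron_ordinal) |>
    arrange(.data$intron_ordinal)
}

#' Stratify insertions by host-gene expression
#'
#' Bins all annotated genes into `n_bins` equal-count expression quantile
#' bins and counts genic insertions per bin. Enrichment per bin is the
#' insertion share divided by the gene share.
#'
#' @param calls Context calls (genic calls with a `gene_id` are used).
#' @param expression Tibble with `gene_id`, `expression` for all annotated
#'   genes.
#' @param n_bins Number of quantile bins (>= 2).
#' @return A tibble with columns `bin` (1 = lowest expression),
#'   `n_genes`, `n_insertions`, `enrichment`.
#' @export
expression_stratify <- function(calls, expression, n_bins = 5) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  binned <- expression |>
    mutate(bin = dplyr::ntile(.data$expression, n_bins))
  genic <- calls |>
    filter(!is.na(.data$gene_id)) |>
    left_join(select(binned, "gene_id", "bin"), by = "gene_id") |>
    filter(!is.na(.data$bin))
  per_bin <- tibble(bin = seq_len(n_bins)) |>
    left_join(dplyr::count(binned, .data$bin, name = "n_genes"),
              by = "bin") |>
    left_join(dplyr::count(genic, .data$bin, name = "n_insertions"),
              by = "bin") |>
    mutate(across(c("n_genes", "n_insertions"),
                  ~ tidyr::replace_na(.x, 0L)))
  per_bin |>
    mutate(enrichment = (.data$n_insertions / sum(.data$n_insertions)) /
             (.data$n_genes / sum(.data$n_genes)))
}
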