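# Seeded synthetic-data generator. Produces an internally consistent toy
# dataset with known ground truth for every downstream stage: a
# two-haplotype genome with genes, planted TE insertions of known class and
# orientation, distance-dependent hybrid isoforms, per-family
# sense-fraction-controlled small-RNA alignments, an accessibility peak
# upstream of each insertion, AT-rich motif arrays with planted relative
# insertion positions, junction-spanning genomic reads, and planted
# rearrangements in one piRNA-cluster-like region.

#' Default configuration for the synthetic dataset
#'
#' All counts are per haplotype. Defaults give ~300 planted insertions
#' over two haplotypes. The logistic splicing model
#' `P(spliced) = plogis(intercept - slope * (log10(d) - midpoint))`, with
#' downstream-exon distances `d` drawn log-normally
#' (`log10 d ~ N(mean_log10, sd_log10)` truncated to
#' `[10^2.3, 10^4.6]`), is calibrated so the median distance of the
#' unspliced group exceeds the spliced group by a factor of about 3.6 and
#' roughly 60% of forward intronic insertions splice.
#'
#' @param n_genes Genes per haplotype (hosts plus insertion-free genes).
#' @param n_exonic,n_intronic_forward,n_intronic_reverse,n_intergenic
#'   Planted insertions per class, per haplotype.
#' @param te_len TE element length (nt) for planted copies.
#' @param ltr_len 5' LTR length (nt).
#' @param donor_offset Donor offset (nt) downstream of the 5' LTR end.
#' @param tss_offset Transcription start offset within the 5' LTR for
#'   hybrid transcripts.
#' @param splice Logistic splicing model parameters (see above).
#' @param smrna Small-RNA model: named `sense_fraction` per family,
#'   `consensus_len` per family, `n_reads` per family, `len_range`.
#' @param accessibility Peak model: `peak_offset` (nt upstream of each
#'   insertion 5' end), `peak_width`, `peak_height`, `baseline`.
#' @param expression Host-gene expression model (`meanlog`, `sdlog`,
#'   `bias` = sample host genes proportional to expression).
#' @param cluster Rearrangement model for the cluster chromosome:
#'   `chrom_len`, `region` = c(start, end), `rearranged` = list of
#'   intervals (within the region) that are non-syntenic between
#'   haplotypes.
#' @param dna_reads Junction-read model: `depth`, `read_len`, `window`.
#' @param sequences Generate nucleotide sequences for the haplotype
#'   chromosomes (slower; annotations alone suffice for most analyses).
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 120,
                       n_exonic = 10, n_intronic_forward = 55,
                       n_intronic_reverse = 35, n_intergenic = 50,
                       te_len = 7546, ltr_len = 405, donor_offset = 43,
                       tss_offset = 100,
                       splice = list(mean_log10 = 3.675, sd_log10 = 0.475,
                                     slope = 4.2, midpoint = 3.725,
                                     intercept = 0.5),
                       smrna = list(
                         sense_fraction = c(Springer = 0.9, copia = 0.85,
                                            Transpac = 0.8, gypsy1 = 0.75,
                                            Xanthias = 0.7,
                                            HMSBeagle = 0.25, ZAM = 0.35,
                                            Idefix = 0.4, blood = 0.3,
                                            Tirant = 0.45),
                         consensus_len = c(Springer = 7546, copia = 5146,
                                           Transpac = 5249, gypsy1 = 6405,
                                           Xanthias = 5380,
                                           HMSBeagle = 7062, ZAM = 8435,
                                           Idefix = 7411, blood = 7410,
                                           Tirant = 8526),
                         n_reads = 2000, len_range = c(23, 29)),
                       accessibility = list(peak_offset = 500,
                                            peak_width = 200,
                                            peak_height = 8, baseline = 1),
                       expression = list(meanlog = 3, sdlog = 1,
                                         bias = TRUE),
                       cluster = list(chrom_len = 400000,
                                      region = c(150000, 250000),
                                      rearranged = list(
                                        c(165000, 173000),
                                        c(190000, 202000),
                                        c(225000, 245000))),
                       dna_reads = list(depth = 10, read_len = 100,
                                        window = 300),
                       sequences = FALSE) {
  cfg <- as.list(environment())
  n_hosts <- n_exonic + n_intronic_forward + n_intronic_reverse
  if (n_hosts > n_genes) {
    stop("infeasible geometry: more host insertions than genes",
         call. = FALSE)
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Draw downstream-exon distances and splicing outcomes
#'
#' The generator's logistic splicing model, exposed for direct use:
#' distances are drawn log-normally (truncated) and each insertion splices
#' with probability `plogis(intercept - slope * (log10 d - midpoint))`.
#'
#' @param n Number of forward intronic insertions.
#' @param splice Model parameters (see [sim_config()]).
#' @return A tibble: `distance` (nt), `spliced` (logical).
#' @export
simulate_splice_distances <- function(n,
                                      splice = sim_config()$splice) {
  x <- rnorm(n, splice$mean_log10, splice$sd_log10)
  x <- pmin(pmax(x, 2.3), 4.6)
  p <- plogis(splice$intercept - splice$slope * (x - splice$midpoint))
  tibble(distance = round(10^x), spliced = runif(n) < p)
}

# one gene in transcription space, mapped to genomic coordinates at g0.
# host_type in c("none", "exonic", "intf", "intr"); d = downstream gap for
# intronic hosts; ordinal = hosting intron (transcription order)
build_gene <- function(gene_id, g0, strand, cfg, host_type = "none",
                       d = NA, ordinal = NA, spliced = FALSE) {
  m <- sample(4:8, 1)
  exon_len <- sample(120:300, m, replace = TRUE)
  intron_len <- pmax(round(rlnorm(m - 1, log(800), 0.6)), 61)
  te <- NULL
  exon_slot <- NA
  if (host_type %in% c("intf", "intr")) {
    ordinal <- min(ordinal, m - 1)
    intron_len[ordinal] <- 100 + cfg$te_len + d
  } else if (host_type == "exonic") {
    exon_slot <- sample(seq_len(m), 1)
    exon_len[exon_slot] <- 200 + cfg$te_len + 200
  }
  # transcription-space exon intervals
  starts <- cumsum(c(0, head(exon_len, -1) + intron_len))
  ex_t <- tibble(t1 = starts, t2 = starts + exon_len,
                 ordinal = seq_len(m))
  L <- ex_t$t2[m]
  map_iv <- function(t1, t2) {
    if (strand == "+") c(g0 + t1, g0 + t2) else c(g0 + L - t2, g0 + L - t1)
  }
  exons <- if (strand == "+") {
    tibble(start = g0 + ex_t$t1, end = g0 + ex_t$t2,
           exon_rank = ex_t$ordinal)
  } else {
    tibble(start = g0 + L - ex_t$t2, end = g0 + L - ex_t$t1,
           exon_rank = ex_t$ordinal)
  }
  te_strand <- NA_character_
  te_iv <- NULL
  donor_t <- NA
  if (host_type %in% c("intf", "intr")) {
    te_t1 <- ex_t$t2[ordinal] + 100
    te_iv <- map_iv(te_t1, te_t1 + cfg$te_len)
    te_strand <- if (host_type == "intf") strand else
      setdiff(c("+", "-"), strand)
    donor_t <- te_t1 + cfg$ltr_len + cfg$donor_offset
  } else if (host_type == "exonic") {
    te_t1 <- ex_t$t1[exon_slot] + 200
    te_iv <- map_iv(te_t1, te_t1 + cfg$te_len)
    te_strand <- sample(c("+", "-"), 1)
  }
  hybrid <- NULL
  if (host_type == "intf" && spliced) {
    te_t1 <- ex_t$t2[ordinal] + 100
    rest <- ex_t[ex_t$ordinal > ordinal, ]
    t1s <- c(te_t1 + cfg$tss_offset, rest$t1)
    t2s <- c(donor_t, rest$t2)
    hybrid <- if (strand == "+") {
      tibble(start = g0 + t1s, end = g0 + t2s)
    } else {
      tibble(start = g0 + L - t2s, end = g0 + L - t1s)
    }
    hybrid <- arrange(hybrid, .data$start)
  }
  list(gene_id = gene_id, strand = strand, length = L, exons = exons,
       te_iv = te_iv, te_strand = te_strand, host_type = host_type,
       ordinal = if (host_type %in% c("intf", "intr")) ordinal else NA,
       d = d, spliced = spliced, hybrid = hybrid)
}

build_haplotype <- function(hap, cfg) {
  chrom <- paste0("chrA_hap", hap)
  n_hosts <- cfg$n_exonic + cfg$n_intronic_forward + cfg$n_intronic_reverse
  expr <- rlnorm(cfg$n_genes, cfg$expression$meanlog, cfg$expression$sdlog)
  prob <- if (isTRUE(cfg$expression$bias)) expr else rep(1, cfg$n_genes)
  hosts <- sample.int(cfg$n_genes, n_hosts, prob = prob)
  host_type <- rep("none", cfg$n_genes)
  host_type[hosts] <- sample(rep(c("exonic", "intf", "intr"),
                                 c(cfg$n_exonic, cfg$n_intronic_forward,
                                   cfg$n_intronic_reverse)))
  sp <- simulate_splice_distances(cfg$n_intronic_forward, cfg$splice)
  # reverse intronic insertions draw distances from the same law
  d_intr <- round(10^pmin(pmax(rnorm(cfg$n_intronic_reverse,
                                     cfg$splice$mean_log10,
                                     cfg$splice$sd_log10), 2.3), 4.6))
  # intron ordinal preference for 5'-proximal introns
  draw_ordinal <- function(n) sample(1:3, n, replace = TRUE,
                                     prob = c(0.55, 0.3, 0.15))
  i_f <- 0; i_r <- 0
  genes <- list()
  # insertions accumulate as parallel vectors (built once at the end)
  iv <- list(id = character(), start = numeric(), end = numeric(),
             strand = character(), true_class = character(),
             true_gene = character(), true_orientation = character(),
             true_ordinal = integer(), true_distance = numeric(),
             spliced = logical())
  add_ins <- function(iv, id, start, end, strand, class, gene, orientation,
                      ordinal, dist, spliced) {
    iv$id <- c(iv$id, id); iv$start <- c(iv$start, start)
    iv$end <- c(iv$end, end); iv$strand <- c(iv$strand, strand)
    iv$true_class <- c(iv$true_class, class)
    iv$true_gene <- c(iv$true_gene, gene)
    iv$true_orientation <- c(iv$true_orientation, orientation)
    iv$true_ordinal <- c(iv$true_ordinal, ordinal)
    iv$true_distance <- c(iv$true_distance, dist)
    iv$spliced <- c(iv$spliced, spliced)
    iv
  }
  pos <- 2000
  inter_left <- cfg$n_intergenic
  ins_id <- 0
  gene_order <- sample.int(cfg$n_genes)
  step <- 0
  for (gi in gene_order) {
    step <- step + 1
    ht <- host_type[gi]
    d <- NA; ordv <- NA; splv <- FALSE
    if (ht == "intf") {
      i_f <- i_f + 1; d <- sp$distance[i_f]; splv <- sp$spliced[i_f]
      ordv <- draw_ordinal(1)
    } else if (ht == "intr") {
      i_r <- i_r + 1; d <- d_intr[i_r]; ordv <- draw_ordinal(1)
    }
    gid <- sprintf("g%d_%03d", hap, gi)
    g <- build_gene(gid, pos, sample(c("+", "-"), 1), cfg, ht, d, ordv,
                    splv)
    genes[[length(genes) + 1]] <- g
    pos <- pos + g$length + sample(1500:3000, 1)
    # some intergenic gaps carry a TE
    if (inter_left > 0 &&
        runif(1) < inter_left / max(1, cfg$n_genes - step)) {
      ins_id <- ins_id + 1
      te_start <- pos + 500
      iv <- add_ins(iv, sprintf("ins%d_%03d", hap, ins_id), te_start,
                    te_start + cfg$te_len, sample(c("+", "-"), 1),
                    "intergenic", NA_character_, "not-applicable",
                    NA_integer_, NA_real_, FALSE)
      pos <- pos + 500 + cfg$te_len + 500
      inter_left <- inter_left - 1
    }
  }
  # remaining intergenic insertions appended past the last gene
  while (inter_left > 0) {
    ins_id <- ins_id + 1
    te_start <- pos + 500
    iv <- add_ins(iv, sprintf("ins%d_%03d", hap, ins_id), te_start,
                  te_start + cfg$te_len, sample(c("+", "-"), 1),
                  "intergenic", NA_character_, "not-applicable",
                  NA_integer_, NA_real_, FALSE)
    pos <- pos + 500 + cfg$te_len + 500
    inter_left <- inter_left - 1
  }
  chrom_len <- pos + 2000
  # exon and transcript rows accumulate as lists of vectors
  ex <- list(); tx <- list()
  for (g in genes) {
    m <- nrow(g$exons)
    tx_id <- paste0("tx_", g$gene_id)
    ex[[length(ex) + 1]] <- list(gene_id = rep(g$gene_id, m),
                                 transcript_id = rep(tx_id, m),
                                 start = g$exons$start,
                                 end = g$exons$end,
                                 strand = rep(g$strand, m),
                                 exon_rank = g$exons$exon_rank)
    tx[[length(tx) + 1]] <- list(transcript_id = rep(tx_id, m),
                                 start = g$exons$start,
                                 end = g$exons$end,
                                 strand = rep(g$strand, m),
                                 hybrid = rep(FALSE, m),
                                 insertion_id = rep(NA_character_, m))
    if (g$host_type != "none") {
      ins_id <- ins_id + 1
      iid <- sprintf("ins%d_%03d", hap, ins_id)
      iv <- add_ins(
        iv, iid, g$te_iv[1], g$te_iv[2], g$te_strand,
        if (g$host_type == "exonic") "exonic" else "intronic",
        g$gene_id,
        if (g$te_strand == g$strand) "forward" else "reverse",
        as.integer(g$ordinal),
        if (g$host_type == "intf") g$d else NA_real_,
        g$spliced)
      if (!is.null(g$hybrid)) {
        hm <- nrow(g$hybrid)
        tx[[length(tx) + 1]] <- list(
          transcript_id = rep(paste0("htx_", g$gene_id), hm),
          start = g$hybrid$start, end = g$hybrid$end,
          strand = rep(g$strand, hm), hybrid = rep(TRUE, hm),
          insertion_id = rep(iid, hm))
      }
    }
  }
  cat_field <- function(rows, f) unlist(map(rows, f), use.names = FALSE)
  exons <- tibble(gene_id = cat_field(ex, "gene_id"),
                  transcript_id = cat_field(ex, "transcript_id"),
                  chrom = chrom,
                  start = cat_field(ex, "start"),
                  end = cat_field(ex, "end"),
                  strand = cat_field(ex, "strand"),
                  exon_rank = cat_field(ex, "exon_rank"))
  transcripts <- tibble(transcript_id = cat_field(tx, "transcript_id"),
                        chrom = chrom,
                        start = cat_field(tx, "start"),
                        end = cat_field(tx, "end"),
                        strand = cat_field(tx, "strand"),
                        hybrid = cat_field(tx, "hybrid"),
                        insertion_id = cat_field(tx, "insertion_id"))
  list(chrom = chrom, chrom_len = chrom_len,
       genes = arrange(exons, .data$start),
       transcripts = arrange(transcripts, .data$transcript_id,
                             .data$start),
       insertions = tibble(!!!iv, chrom = chrom, family = "Springer") |>
         mutate(length = .data$end - .data$start, cons_start = 0L,
                cons_end = cfg$te_len, divergence = 0) |>
         select("id", "chrom", "start", "end", "strand", "family",
                "true_class", "true_gene", "true_orientation",
                "true_ordinal", "true_distance", "spliced", "length",
                "cons_start", "cons_end", "divergence") |>
         arrange(.data$start),
       expression = tibble(
         gene_id = sprintf("g%d_%03d", hap, seq_len(cfg$n_genes)),
         expression = expr))
}

accessibility_track <- function(insertions, chrom, chrom_len, acc) {
  site <- if_else(insertions$strand == "-", insertions$end - 1L,
                  insertions$start)
  centre <- if_else(insertions$strand == "-",
                    site + acc$peak_offset, site - acc$peak_offset)
  half <- acc$peak_width %/% 2
  peaks <- tibble(chrom = chrom,
                  start = pmax(centre - half, 0),
                  end = pmin(centre + half, chrom_len)) |>
    merge_intervals()
  if (nrow(peaks) == 0) {
    return(tibble(chrom = chrom, start = 0L, end = chrom_len,
                  value = acc$baseline))
  }
  gaps_start <- c(0L, peaks$end)
  gaps_end <- c(peaks$start, chrom_len)
  base <- tibble(chrom = chrom, start = gaps_start, end = gaps_end,
                 value = acc$baseline) |>
    filter(.data$end > .data$start)
  bind_rows(base, mutate(peaks, value = acc$baseline + acc$peak_height)) |>
    arrange(.data$start)
}

random_dna <- function(n, at_rich = FALSE) {
  prob <- if (at_rich) c(0.4, 0.1, 0.1, 0.4) else rep(0.25, 4)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# consensus with a planted donor hexamer at ltr_len + donor_offset and all
# accidental occurrences of the pattern elsewhere removed
plant_consensus <- function(len, ltr_len, donor_offset,
                            donor = "GTAAGTG") {
  s <- random_dna(len)
  repeat {
    hit <- regexpr(substr(donor, 1, 6), s, fixed = TRUE)
    if (hit < 0) break
    substr(s, hit, hit) <- "C"
  }
  pos <- ltr_len + donor_offset + 1   # 1-based
  substr(s, pos, pos + nchar(donor) - 1) <- donor
  s
}

#' Generate the synthetic dataset
#'
#' Builds the full toy dataset in memory: two haplotypes with genes and
#' planted insertions, canonical and hybrid transcript models, small-RNA
#' alignments to TE consensus sequences with per-family sense fractions,
#' an accessibility track with a peak upstream of each insertion, AT-rich
#' motif arrays with Beta(3,3) planted relative insertion positions,
#' junction-spanning genomic reads, alignment blocks between haplotypes
#' with planted non-syntenic segments in a cluster-like region, and the
#' ground-truth record. The same seed gives identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory; the caller's RNG state is
#'   preserved).
#' @return A list of class `te_sim` with elements `genome` (tibble
#'   `chrom`, `length`), `genes`, `transcripts` (with truth columns
#'   `hybrid`, `insertion_id`), `insertions` (with `true_*` truth
#'   columns), `expression`, `consensus_len`, `consensus_seq` (when
#'   `config$sequences`), `sequences` (ditto), `smrna` (alignment tibble),
#'   `library_size`, `accessibility`, `arrays`, `paf`, `dna_alignments`,
#'   `truth` (parameters incl. `seed`).
#' @export
simulate_te_dataset <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cfg <- config
  haps <- map(1:2, build_haplotype, cfg = cfg)
  genes <- list_rbind(map(haps, "genes"))
  transcripts <- list_rbind(map(haps, "transcripts")) |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (first(.data$strand) == "-")
      n() - row_number() + 1L else row_number()) |>
    ungroup()
  insertions <- list_rbind(map(haps, "insertions"))
  expression <- list_rbind(map(haps, "expression"))

  # motif arrays containing each insertion at a Beta(3,3) relative position
  arr_len <- sample(1000:2000, nrow(insertions), replace = TRUE)
  rel <- stats::rbeta(nrow(insertions), 3, 3)
  mid <- (insertions$start + insertions$end) %/% 2
  arrays <- tibble(
    chrom = insertions$chrom,
    start = pmax(mid - round(rel * arr_len), 0),
    end = pmax(mid - round(rel * arr_len), 0) + arr_len,
    insertion_id = insertions$id,
    true_rel = rel)

  # small RNA alignments to consensus
  sm <- cfg$smrna
  fams <- names(sm$sense_fraction)
  smrna <- list_rbind(map(fams, function(f) {
    n <- sm$n_reads
    len <- sample(sm$len_range[1]:sm$len_range[2], n, replace = TRUE)
    clen <- sm$consensus_len[[f]]
    start <- floor(runif(n) * (clen - len))
    tibble(qname = paste0(f, "_r", seq_len(n)), chrom = f,
           start = as.integer(start), end = as.integer(start + len),
           strand = if_else(runif(n) < sm$sense_fraction[[f]], "+", "-"),
           mapq = 255L, read_len = len)
  }))

  # accessibility per haplotype chromosome
  accessibility <- list_rbind(map(haps, function(h) {
    accessibility_track(filter(insertions, .data$chrom == h$chrom),
                        h$chrom, h$chrom_len, cfg$accessibility)
  }))

  # cluster chromosome PAF between haplotypes
  cl <- cfg$cluster
  rearr <- map(cl$rearranged, ~ tibble(start = .x[1], end = .x[2]))
  rearr <- list_rbind(rearr) |> arrange(.data$start)
  syn_start <- c(0, rearr$end)
  syn_end <- c(rearr$start, cl$chrom_len)
  syn <- tibble(start = syn_start, end = syn_end) |>
    filter(.data$end > .data$start)
  paf <- bind_rows(
    mutate(syn, strand = "+", class = "syntenic"),
    mutate(rearr, strand = "-", class = "rearranged")
  ) |>
    mutate(qname = "chrX_hap1", qlen = cl$chrom_len,
           qstart = .data$start, qend = .data$end,
           tname = "chrX_hap2", tlen = cl$chrom_len,
           tstart = .data$start, tend = .data$end,
           n_match = .data$end - .data$start,
           block_len = .data$end - .data$start, mapq = 60L) |>
    select("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
           "tstart", "tend", "n_match", "block_len", "mapq", "class") |>
    arrange(.data$qstart)

  # junction-spanning genomic reads around every insertion boundary
  dr <- cfg$dna_reads
  n_per <- ceiling(dr$depth * 2 * dr$window / dr$read_len)
  junctions <- tibble(
    id = rep(insertions$id, 2),
    chrom = rep(insertions$chrom, 2),
    point = c(insertions$start, insertions$end),
    tag = rep(c("L", "R"), each = nrow(insertions)))
  jx <- junctions[rep(seq_len(nrow(junctions)), each = n_per), ]
  s <- floor(runif(nrow(jx)) * (2 * dr$window - dr$read_len)) +
    jx$point - dr$window
  dna_alignments <- tibble(
    qname = paste0(jx$id, "_", jx$tag, "_",
                   rep(seq_len(n_per), nrow(junctions))),
    chrom = jx$chrom, start = as.integer(s),
    end = as.integer(s + dr$read_len), strand = "+", mapq = 60L,
    read_len = dr$read_len) |>
    arrange(.data$chrom, .data$start)

  genome <- bind_rows(
    tibble(chrom = map_chr(haps, "chrom"),
           length = map_dbl(haps, "chrom_len")),
    tibble(chrom = c("chrX_hap1", "chrX_hap2"),
           length = rep(cl$chrom_len, 2)))

  consensus_seq <- NULL
  sequences <- NULL
  if (isTRUE(cfg$sequences)) {
    consensus_seq <- setNames(map_chr(fams, function(f) {
      if (f == "Springer") {
        plant_consensus(sm$consensus_len[[f]], cfg$ltr_len,
                        cfg$donor_offset)
      } else {
        random_dna(sm$consensus_len[[f]])
      }
    }), fams)
    sequences <- setNames(map_chr(genome$chrom, function(ch) {
      random_dna(genome$length[genome$chrom == ch])
    }), genome$chrom)
  }

  structure(list(
    genome = genome, genes = genes, transcripts = transcripts,
    insertions = insertions, expression = expression,
    consensus_len = sm$consensus_len, consensus_seq = consensus_seq,
    sequences = sequences, smrna = smrna, library_size = nrow(smrna),
    accessibility = accessibility, arrays = arrays, paf = paf,
    dna_alignments = dna_alignments,
    truth = list(seed = seed, config = cfg,
                 sense_fraction = sm$sense_fraction,
                 peak_offset = cfg$accessibility$peak_offset,
                 rearranged = cl$rearranged,
                 cluster_region = cl$region)
  ), class = "te_sim")
}

#' Write a synthetic dataset as a file bundle
#'
#' Emits the dataset in the pipeline's contract formats: gene GFF3,
#' RepeatMasker-style `.out`, BED12 transcript models, small-RNA SAM
#' against consensus sequences, accessibility bedGraph, expression TSV,
#' haplotype PAF, genomic-read SAM, truth JSON, and (when generated)
#' haplotype and consensus FASTA. Identical seeds give byte-identical
#' bundles.
#'
#' @param sim A `te_sim` from [simulate_te_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_te_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gff3_genes(sim$genes, p("genes.gff3"))
  write_repeatmasker_out(
    mutate(sim$insertions, repeat_class = "LTR/Gypsy"),
    p("insertions.out"),
    consensus_len = sim$consensus_len)
  write_bed12_transcripts(sim$transcripts, p("transcripts.bed12"))
  write_sam(sim$smrna,
            tibble(name = names(sim$consensus_len),
                   length = unname(sim$consensus_len)),
            p("smrna_consensus.sam"))
  write_sam(sim$dna_alignments,
            tibble(name = sim$genome$chrom, length = sim$genome$length),
            p("dna_reads.sam"))
  write_bedgraph(sim$accessibility, p("accessibility.bedgraph"))
  write_expression_tsv(sim$expression, p("expression.tsv"))
  write_paf(sim$paf, p("hap1_hap2.paf"))
  readr::write_tsv(sim$genome, p("genome.tsv"))
  readr::write_tsv(select(sim$arrays, -"true_rel"), p("arrays.bed.tsv"))
  truth <- c(sim$truth,
             list(insertions = sim$insertions,
                  hybrid_transcripts = filter(sim$transcripts,
                                              .data$hybrid) |>
                    distinct(.data$transcript_id, .data$insertion_id),
                  array_rel = select(sim$arrays, "insertion_id",
                                     "true_rel")))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(sim$sequences)) {
    write_fasta(sim$sequences, p("genome.fasta"))
    write_fasta(sim$consensus_seq, p("consensus.fasta"))
  }
  invisible(dir)
}

#' Minimal fixture reproducing the flagship hybrid-splicing locus
#'
#' A four-exon gene on the plus strand with a full-length TE inserted in
#' intron 3; the TE carries the donor heptamer `GTAAGTG` 43 nt downstream
#' of its 405-nt 5' LTR. One hybrid transcript initiates within the LTR
#' and splices from the TE-internal donor to exon 4 (skipping exons 1-3);
#' one canonical transcript covers all four exons.
#'
#' @return A list: `genes`, `insertions`, `transcripts`, `te_sequence`
#'   (consensus with the planted donor), `ltr_end`, `true_distance`
#'   (insertion end to exon-4 start), `donor_offset`.
#' @export
make_l3_fixture <- function() {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20260420)
  te_len <- 7546; ltr <- 405; donor_off <- 43
  exon_len <- 200
  # exons 1..3 with short introns; intron 3 carries the TE
  e1 <- c(1000, 1200); e2 <- c(1700, 1900); e3 <- c(2500, 2700)
  te_start <- 2800
  te_end <- te_start + te_len
  d <- 1500
  e4 <- c(te_end + d, te_end + d + exon_len)
  genes <- tibble(
    gene_id = "l3mbt", transcript_id = "l3mbt_t1", chrom = "chr3R",
    start = c(e1[1], e2[1], e3[1], e4[1]),
    end = c(e1[2], e2[2], e3[2], e4[2]),
    strand = "+", exon_rank = 1:4)
  insertions <- tibble(
    id = "L3", chrom = "chr3R", start = te_start, end = te_end,
    strand = "+", family = "Springer", length = te_len,
    cons_start = 0L, cons_end = te_len, divergence = 0)
  donor_pos <- te_start + ltr + donor_off
  transcripts <- bind_rows(
    tibble(transcript_id = "iso_hybrid", chrom = "chr3R",
           start = c(te_start + 100, e4[1]),
           end = c(donor_pos, e4[2]), strand = "+", exon_rank = 1:2),
    tibble(transcript_id = "iso_canonical", chrom = "chr3R",
           start = genes$start, end = genes$end, strand = "+",
           exon_rank = 1:4))
  list(genes = genes, insertions = insertions, transcripts = transcripts,
       te_sequence = plant_consensus(te_len, ltr, donor_off),
       ltr_end = ltr, true_distance = d, donor_offset = donor_off)
}
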