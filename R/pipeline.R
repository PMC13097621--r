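# End-to-end orchestration over a file bundle: validates the
# configuration, runs the stages in dependency order, writes one summary
# TSV per figure-level statistic, and returns a reproducible run manifest.

PIPELINE_INPUTS <- c(genes = "genes.gff3", insertions = "insertions.out",
                     transcripts = "transcripts.bed12",
                     smrna = "smrna_consensus.sam",
                     dna_reads = "dna_reads.sam",
                     accessibility = "accessibility.bedgraph",
                     expression = "expression.tsv",
                     paf = "hap1_hap2.paf", genome = "genome.tsv")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or path to a YAML file) with fields
#' `input_dir` (a bundle directory as written by [write_te_dataset()]),
#' `out_dir`, `seed`, and optional analysis parameters
#' (`family`, `min_mapq`, `acceptor_tol`, `min_support`,
#' `cluster_region = c(chrom, start, end)`, `flank`, `bin`,
#' `n_random_controls`, `control_window`).
#'
#' @param config Named list or YAML path.
#' @return The normalized configuration list (invisibly errors on
#'   validation failure).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  for (field in c("input_dir", "out_dir", "seed")) {
    if (is.null(config[[field]])) {
      stop("config validation: missing field '", field, "'", call. = FALSE)
    }
  }
  missing_in <- PIPELINE_INPUTS[!file.exists(file.path(config$input_dir,
                                                       PIPELINE_INPUTS))]
  if (length(missing_in)) {
    stop("config validation: missing input file(s): ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }
  defaults <- list(family = "Springer", min_mapq = 0, acceptor_tol = 5,
                   min_support = 1, flank = 5000, bin = 10,
                   n_random_controls = 200, control_window = 7546)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

#' Run the full analysis pipeline over a file bundle
#'
#' Executes the stages in dependency order -- insertion catalog, hybrid
#' splicing, splicing-competence distance test, piRNA quantification,
#' occupancy/enrichment, insertion-site context (accessibility
#' metaprofile with random controls), and cross-assembly metrics
#' (syntenic fraction, junction presence calls) -- writing one summary TSV
#' per stage into `out_dir`. A failing stage aborts with the stage named;
#' outputs of the failing stage keep a `.partial` suffix.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_pipeline_config()].
#' @return A `run_manifest`: list with the tool version, config snapshot,
#'   input checksums, seed, per-stage output paths and row counts, and
#'   timestamps. Deterministic outputs are identical across reruns with
#'   the same manifest inputs.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  inputs <- file.path(cfg$input_dir, PIPELINE_INPUTS)
  checksums <- tools::md5sum(inputs)
  stages <- list()
  out_tsv <- function(stage, name, df) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    tmp <- paste0(path, ".partial")
    readr::write_tsv(df, tmp)
    file.rename(tmp, path)
    stages[[stage]] <<- c(stages[[stage]],
                          setNames(list(list(path = path, rows = nrow(df))),
                                   name))
    invisible(path)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genes <- read_gff3_genes(file.path(cfg$input_dir, "genes.gff3"))
  genome <- readr::read_tsv(file.path(cfg$input_dir, "genome.tsv"),
                            show_col_types = FALSE)
  insertions <- read_repeatmasker_out(
    file.path(cfg$input_dir, "insertions.out"),
    family_filter = cfg$family)

  calls <- NULL
  run_stage("catalog", function() {
    calls <<- classify_insertions(insertions, genes) |>
      distance_to_downstream_exon(genes)
    out_tsv("catalog", "context_calls", calls)
    out_tsv("catalog", "context_composition", context_composition(calls))
    out_tsv("catalog", "genome_composition",
            genome_feature_composition(genes, sum(genome$length)))
    out_tsv("catalog", "intron_position",
            intron_position_distribution(calls))
    out_tsv("catalog", "expression_strata",
            expression_stratify(
              calls, read_expression_tsv(
                file.path(cfg$input_dir, "expression.tsv"))))
  })

  verdicts <- NULL
  run_stage("hybrid", function() {
    transcripts <- read_bed12_transcripts(
      file.path(cfg$input_dir, "transcripts.bed12"))
    events <- call_hybrid_events(calls, transcripts, genes,
                                 acceptor_tol = cfg$acceptor_tol)
    verdicts <<- hybrid_verdicts(calls, events,
                                 min_support = cfg$min_support)
    out_tsv("hybrid", "hybrid_events", events)
    out_tsv("hybrid", "hybrid_verdicts", verdicts)
  })

  run_stage("distance_test", function() {
    d_with <- verdicts$distance_downstream[verdicts$hybrid]
    d_without <- verdicts$distance_downstream[!verdicts$hybrid]
    d_with <- d_with[!is.na(d_with)]
    d_without <- d_without[!is.na(d_without)]
    res <- splicing_competence_test(d_with, d_without)
    out_tsv("distance_test", "splicing_competence", tidy(res))
  })

  run_stage("pirna", function() {
    sm <- read_sam(file.path(cfg$input_dir, "smrna_consensus.sam")) |>
      size_filter()
    feats <- unique(sm$chrom)
    counts <- count_by_feature_strand(sm, feats) |>
      cpm_normalize(denominator = nrow(sm))
    out_tsv("pirna", "stranded_counts", counts)
    out_tsv("pirna", "top_families", top_k_by_total(counts, 30))
  })

  run_stage("enrichment", function() {
    haps <- sort(unique(insertions$chrom))
    occ <- occupancy_by_family(insertions, sum(genome$length))
    out_tsv("enrichment", "occupancy", occ)
  })

  run_stage("context", function() {
    track <- read_bedgraph(file.path(cfg$input_dir,
                                     "accessibility.bedgraph"))
    sites <- insertions |>
      mutate(pos = if_else(.data$strand == "-", .data$end - 1L,
                           .data$start)) |>
      select("chrom", "pos", "strand")
    mp <- metaprofile(sites, track, flank = cfg$flank, bin = cfg$bin)
    lens <- setNames(genome$length, genome$chrom)
    ctrl_sites <- random_control(lens, n = cfg$n_random_controls,
                                 window_len = cfg$control_window,
                                 seed = cfg$seed)
    mp_ctrl <- metaprofile(ctrl_sites, track, flank = cfg$flank,
                           bin = cfg$bin)
    out_tsv("context", "metaprofile_sites", mp$profile)
    out_tsv("context", "metaprofile_random", mp_ctrl$profile)
  })

  run_stage("metrics", function() {
    paf <- read_paf(file.path(cfg$input_dir, "hap1_hap2.paf"))
    region <- if (!is.null(cfg$cluster_region)) {
      tibble(chrom = cfg$cluster_region[[1]],
             start = as.numeric(cfg$cluster_region[[2]]),
             end = as.numeric(cfg$cluster_region[[3]]))
    } else {
      tibble(chrom = paf$qname[1], start = 0, end = paf$qlen[1])
    }
    out_tsv("metrics", "syntenic_fraction",
            syntenic_fraction(region, paf, side = "query"))
    dna <- read_sam(file.path(cfg$input_dir, "dna_reads.sam"),
                    min_mapq = cfg$min_mapq)
    out_tsv("metrics", "presence_calls",
            junction_support(insertions, dna))
  })

  structure(list(
    version = as.character(utils::packageVersion("terewire")),
    config = cfg,
    input_checksums = checksums,
    seed = cfg$seed,
    stages = stages,
    started = t0,
    finished = Sys.time()
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("terewire run manifest (v", x$version, ")\n", sep = "")
  cat("  seed:", x$seed, "\n")
  for (stage in names(x$stages)) {
    for (nm in names(x$stages[[stage]])) {
      o <- x$stages[[stage]][[nm]]
      cat(sprintf("  %-14s %-22s %6d rows  %s\n", stage, nm, o$rows,
                  o$path))
    }
  }
  invisible(x)
}
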