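#' Run configuration for the end-to-end pipeline
#'
#' Bundles paths, analysis parameters (all defaulting to the standard
#' fragment-analysis settings: 40-220 bp size selection, >= 2 CpGs at >= 10
#' reads, Fisher/Bonferroni at alpha 0.01 with a 25% methylation-difference
#' threshold, promoter window -2 kb/+1 kb, 2 kb shores and 4 kb shelves,
#' 50 histogram bins) and the pair layout.
#'
#' @param genome FASTA path (or in-memory genome).
#' @param calls named list/vector of per-sample coverage-file paths (or call
#'   tables).
#' @param pairs data.frame with columns `tissue`, `cell` naming entries of
#'   `calls`.
#' @param gtf,cgi optional gene-model GTF and CpG-island BED paths (or
#'   in-memory equivalents).
#' @param outdir output directory.
#' @param size_min,size_max size-selection bounds (bp, inclusive).
#' @param min_reads,min_cpgs coverage-filter parameters.
#' @param alpha,min_diff DMF-calling parameters.
#' @param upstream,downstream promoter window extents (bp).
#' @param shore_width,shelf_width CGI flank widths (bp).
#' @param n_bins histogram bins.
#' @param seed seed recorded in the config echo.
#' @return validated `run_config` list.
#' @export
run_config <- function(genome, calls, pairs, gtf = NULL, cgi = NULL,
                       outdir = tempfile("rrbsdmf_run_"),
                       size_min = 40L, size_max = 220L,
                       min_reads = 10L, min_cpgs = 2L,
                       alpha = 0.01, min_diff = 0.25,
                       upstream = 2000L, downstream = 1000L,
                       shore_width = 2000L, shelf_width = 4000L,
                       n_bins = 50L, seed = 1L) {
  cfg <- list(genome = genome, calls = calls, pairs = pairs, gtf = gtf,
              cgi = cgi, outdir = outdir, size_min = size_min,
              size_max = size_max, min_reads = min_reads,
              min_cpgs = min_cpgs, alpha = alpha, min_diff = min_diff,
              upstream = upstream, downstream = downstream,
              shore_width = shore_width, shelf_width = shelf_width,
              n_bins = n_bins, seed = as.integer(seed))
  stop_if_not_scalar_number(cfg$alpha, "alpha", 0, 1)
  stop_if_not_scalar_number(cfg$min_diff, "min_diff", 0, 1)
  if (cfg$size_min > cfg$size_max) {
    stop("size_min must not exceed size_max", call. = FALSE)
  }
  if (cfg$min_reads < 1L || cfg$min_cpgs < 1L) {
    stop("min_reads and min_cpgs must be >= 1", call. = FALSE)
  }
  if (!all(c(pairs$tissue, pairs$cell) %in% names(calls))) {
    stop("pairs reference samples missing from 'calls'", call. = FALSE)
  }
  for (s in names(calls)) {
    if (is.character(calls[[s]]) && !file.exists(calls[[s]])) {
      stop("calls file not found for sample '", s, "': ", calls[[s]],
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full fragment-based differential methylation pipeline
#'
#' Digest -> size-select -> aggregate each sample -> call DMFs per pair ->
#' intersect across pairs -> annotate -> summarise. Stage outputs are
#' written as TSV under `outdir`, plus a JSON config echo and the run
#' report; the same config always produces the same report.
#'
#' @param config a [run_config()].
#' @return list with `fragments`, `frag_meth` (per sample), `dmfs` (per
#'   pair), `common`, `concordance`, `annotations`, `report`, and `paths`
#'   of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- as_genome_seqs(config$genome)

  frags_all <- digest_genome(genome)
  frags <- size_select(frags_all, config$size_min, config$size_max)
  cpg_map <- fragment_cpgs(genome, frags)
  paths <- c(fragments = file.path(config$outdir, "fragments.bed"))
  write_fragments_bed(frags, paths[["fragments"]])

  frag_meth <- lapply(config$calls, function(x) {
    calls <- read_cpg_calls(x, genome)
    aggregate_fragments(frags, cpg_map, calls,
                        min_reads = config$min_reads,
                        min_cpgs = config$min_cpgs)
  })
  for (s in names(frag_meth)) {
    p <- file.path(config$outdir, sprintf("%s.frag.tsv", s))
    write_fragment_methylation(frag_meth[[s]], p)
    paths[[paste0("frag_", s)]] <- p
  }

  pairs <- config$pairs
  dmfs <- lapply(seq_len(nrow(pairs)), function(i) {
    call_dmfs(frag_meth[[pairs$tissue[i]]], frag_meth[[pairs$cell[i]]],
              alpha = config$alpha, min_diff = config$min_diff)
  })
  names(dmfs) <- sprintf("pair%d", seq_len(nrow(pairs)))
  for (nm in names(dmfs)) {
    p <- file.path(config$outdir, sprintf("%s.dmf.tsv", nm))
    fwrite(dmfs[[nm]], p, sep = "\t")
    paths[[paste0("dmf_", nm)]] <- p
  }

  common <- NULL
  concord <- NULL
  if (length(dmfs) >= 2L) {
    common <- intersect_common(dmfs[[1L]], dmfs[[2L]])
    # with more than two pairs, the concordance label comes from the first
    # two comparisons; later pairs only restrict membership
    if (length(dmfs) > 2L) {
      for (k in 3:length(dmfs)) {
        keep <- as.data.table(dmfs[[k]])[significant == TRUE, fragment_id]
        common <- common[common$fragment_id %in% keep, ]
      }
    }
    concord <- concordance_summary(common)
    paths[["common"]] <- file.path(config$outdir, "common_dmf.tsv")
    fwrite(common, paths[["common"]], sep = "\t")
  }

  annotations <- NULL
  if (!is.null(config$gtf) && !is.null(config$cgi)) {
    gm <- if (is.character(config$gtf)) read_gene_models(config$gtf) else
      config$gtf
    islands <- if (is.character(config$cgi)) read_bed(config$cgi) else
      as.data.table(config$cgi)
    annotations <- annotate_fragments(frags, gm, islands,
                                      upstream = config$upstream,
                                      downstream = config$downstream,
                                      shore_width = config$shore_width,
                                      shelf_width = config$shelf_width)
    paths[["annotations"]] <- file.path(config$outdir, "annotations.tsv")
    fwrite(annotations, paths[["annotations"]], sep = "\t")
  }

  report <- run_report(frag_meth, dmfs = dmfs, common = common,
                       annotations = annotations, pairs = pairs,
                       path = file.path(config$outdir, "report.json"))
  paths[["report"]] <- file.path(config$outdir, "report.json")

  cfg_echo <- config
  class(cfg_echo) <- NULL
  cfg_echo$calls <- lapply(cfg_echo$calls, function(x) {
    if (is.character(x)) x else "<in-memory>"
  })
  cfg_echo$genome <- if (is.character(config$genome) &&
                           length(config$genome) == 1L) config$genome else
    "<in-memory>"
  if (!is.character(cfg_echo$gtf)) cfg_echo$gtf <- NULL
  if (!is.character(cfg_echo$cgi)) cfg_echo$cgi <- NULL
  cfg_echo$pairs <- as.data.frame(pairs)
  paths[["config"]] <- file.path(config$outdir, "config.json")
  jsonlite::write_json(cfg_echo, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")

  list(fragments = frags, frag_meth = frag_meth, dmfs = dmfs,
       common = common, concordance = concord, annotations = annotations,
       report = report, paths = paths)
}
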