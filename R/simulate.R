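#' Simulation configuration for paired tissue / cell-line RRBS counts
#'
#' Defines a toy genome whose MspI fragments, per-CpG coverage, and
#' bimodal fragment methylation mimic the structure of paired tumour-tissue
#' and derived-cell-line RRBS methylomes, with a known set of planted
#' differentially methylated fragments (DMFs) shared across pairs.
#'
#' The defaults describe the standard study conditions used throughout the
#' package's validation: two tissue/cell-line pairs, 2,000 size-selected
#' fragments (20 contigs x 100 in-window fragments), 200 planted DMFs shared
#' by both pairs with a methylation shift of 0.5, 88% of them hypermethylated
#' in the cell line, and negative-binomial per-CpG coverage with mean 30.
#'
#' @param seed integer master seed; every random draw flows from it through
#'   stage-specific substreams.
#' @param n_contigs,contig_length number and length (bp) of contigs.
#' @param fragments_per_contig MspI fragments per contig inside the
#'   size-selection window.
#' @param frac_short,frac_long additional out-of-window fragments (fractions
#'   of `fragments_per_contig`) below/above the window, exercising size
#'   selection.
#' @param cpg_range integer range of CpGs per fragment (inclusive).
#' @param beta_mixture named vector `alpha_low, beta_low, alpha_high,
#'   beta_high, weight_high`: per-fragment true methylation is drawn from the
#'   low-methylation Beta with probability `1 - weight_high`, else from the
#'   high mode; this is the bimodal shape seen in RRBS methylomes.
#' @param coverage_mean,coverage_dispersion negative-binomial per-CpG read
#'   depth (mean and `size`); the Poisson is the `size -> Inf` limit.
#' @param n_planted_dmf number of planted DMFs among size-selected fragments.
#' @param planted_delta true methylation shift in the cell-line sample at
#'   planted fragments, in \[0,1\].
#' @param planted_hyper_fraction proportion of planted DMFs shifted upward
#'   (hypermethylated) in the cell line.
#' @param n_pairs number of tissue/cell-line pairs.
#' @param shared_planted_fraction proportion of planted DMFs common to all
#'   pairs (the rest are planted per pair independently).
#' @param size_min,size_max size-selection window in bp, inclusive.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 20L,
                       contig_length = 40000L,
                       fragments_per_contig = 100L,
                       frac_short = 0.08,
                       frac_long = 0.08,
                       cpg_range = c(3L, 8L),
                       beta_mixture = c(alpha_low = 1.5, beta_low = 15,
                                        alpha_high = 15, beta_high = 1.5,
                                        weight_high = 0.45),
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       n_planted_dmf = 200L,
                       planted_delta = 0.5,
                       planted_hyper_fraction = 0.88,
                       n_pairs = 2L,
                       shared_planted_fraction = 1.0,
                       size_min = 40L,
                       size_max = 220L) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              fragments_per_contig = as.integer(fragments_per_contig),
              frac_short = frac_short, frac_long = frac_long,
              cpg_range = as.integer(cpg_range),
              beta_mixture = beta_mixture,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              n_planted_dmf = as.integer(n_planted_dmf),
              planted_delta = planted_delta,
              planted_hyper_fraction = planted_hyper_fraction,
              n_pairs = as.integer(n_pairs),
              shared_planted_fraction = shared_planted_fraction,
              size_min = as.integer(size_min), size_max = as.integer(size_max))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if_not_scalar_number(cfg$planted_delta, "planted_delta", 0, 1)
  stop_if_not_scalar_number(cfg$planted_hyper_fraction,
                            "planted_hyper_fraction", 0, 1)
  stop_if_not_scalar_number(cfg$shared_planted_fraction,
                            "shared_planted_fraction", 0, 1)
  stop_if_not_scalar_number(cfg$frac_short, "frac_short", 0, 1)
  stop_if_not_scalar_number(cfg$frac_long, "frac_long", 0, 1)
  stop_if_not_scalar_number(cfg$coverage_mean, "coverage_mean", min = 1e-9)
  stop_if_not_scalar_number(cfg$coverage_dispersion, "coverage_dispersion",
                            min = 1e-9)
  w <- cfg$beta_mixture[["weight_high"]]
  stop_if_not_scalar_number(w, "weight_high", 0, 1)
  if (cfg$n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  if (cfg$cpg_range[1L] < 2L) {
    stop("cpg_range minimum must be >= 2 (fragments need two CpG sites)",
         call. = FALSE)
  }
  n_in_window <- cfg$n_contigs * cfg$fragments_per_contig
  if (cfg$n_planted_dmf > n_in_window) {
    stop("n_planted_dmf exceeds the number of size-selected fragments",
         call. = FALSE)
  }
  invisible(cfg)
}

# deterministic substream seeds derived from the master seed
substream <- function(seed, stage, k = 0L) {
  offs <- c(genome = 104729L, truth = 224737L, pair = 350377L)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]] + as.numeric(k)) %%
               2147483647)
}

# random A/T background (no C/G, so it can never create CpGs or cut sites)
rand_at <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
}

# inner fragment sequence of length m with k planted CG dinucleotides on an
# A/T background; C appears only as the C of a planted CG, so no accidental
# CpG or CCGG can arise
inner_seq <- function(m, k) {
  if (2L * k > m) k <- m %/% 2L
  if (k == 0L) return(rand_at(m))
  slots <- m - 2L * k
  gaps <- if (slots > 0L) {
    tabulate(sample.int(k + 1L, slots, replace = TRUE), nbins = k + 1L)
  } else rep(0L, k + 1L)
  parts <- character(2L * k + 1L)
  parts[seq(1L, 2L * k + 1L, by = 2L)] <- vapply(gaps, rand_at, character(1))
  parts[seq(2L, 2L * k, by = 2L)] <- "CG"
  paste(parts, collapse = "")
}

#' Generate a toy genome with controlled MspI fragment structure
#'
#' Builds contigs as `pad CCGG inner1 CCGG inner2 ... CCGG pad`, so in-silico
#' digestion recovers exactly the planned internal fragments. Fragment
#' lengths are drawn uniformly inside the size-selection window, plus
#' `frac_short`/`frac_long` out-of-window fragments. Each fragment carries a
#' CpG at its start (the `CGG` overhang) plus planted CG dinucleotides on an
#' A/T background, so the CpG count per fragment is exact. Also emits simple
#' gene models (alternating strands, three exons each) and a disjoint CpG
#' island track.
#'
#' @param config a [sim_config()].
#' @return list with `seqs` (named character), `fragments` (planned in-window
#'   catalogue, as returned by digestion), `genes` (data.table: gene_id,
#'   contig, start, end, strand, exon intervals), `cgi` (data.table BED),
#'   `planted` (data.table of planted fragments with pair assignment and
#'   direction), and the echoed `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, "genome"))
  n_in <- config$fragments_per_contig
  n_sh <- as.integer(round(config$frac_short * n_in))
  n_lo <- as.integer(round(config$frac_long * n_in))
  seqs <- character(config$n_contigs)
  names(seqs) <- sprintf("ctg%02d", seq_len(config$n_contigs))
  for (ci in seq_len(config$n_contigs)) {
    lens <- c(sample_from(config$size_min:config$size_max, n_in),
              if (n_sh > 0L) sample_from(10:(config$size_min - 1L), n_sh),
              if (n_lo > 0L)
                sample_from((config$size_max + 1L):(config$size_max + 100L),
                            n_lo))
    lens <- lens[sample.int(length(lens))]  # shuffle along the contig
    n_frag <- length(lens)
    ks <- sample_from(config$cpg_range[1L]:config$cpg_range[2L],
                      n_frag) - 1L  # start CpG is free
    inners <- mapply(inner_seq, lens - 4L, ks)
    body_len <- (n_frag + 1L) * 4L + sum(lens - 4L)
    rem <- config$contig_length - body_len
    if (rem < 2L) {
      stop(sprintf(paste0("contig_length %d too small to host %d fragments ",
                          "(need >= %d bp)"), config$contig_length, n_frag,
                   body_len + 2L), call. = FALSE)
    }
    pad_l <- rem %/% 2L
    seqs[ci] <- paste0(rand_at(pad_l), "CCGG",
                       paste(inners, collapse = "CCGG"), "CCGG",
                       rand_at(rem - pad_l))
  }
  frags <- digest_genome(seqs)
  in_window <- size_select(frags, config$size_min, config$size_max)

  genes <- make_gene_models(names(seqs), config$contig_length)
  cgi <- make_cgi_track(names(seqs), config$contig_length)
  planted <- choose_planted(in_window, config)
  list(seqs = seqs, fragments = frags, in_window = in_window,
       cpg_map = fragment_cpgs(seqs, in_window), genes = genes,
       cgi = cgi, planted = planted, config = config)
}

# three genes per contig on alternating strands, three exons each
make_gene_models <- function(contigs, contig_length) {
  span <- max(3000L, contig_length %/% 8L)
  starts <- as.integer(seq(contig_length * 0.05, contig_length * 0.7,
                           length.out = 3L))
  out <- lapply(seq_along(contigs), function(ci) {
    data.table(gene_id = sprintf("%s_g%d", contigs[ci], 1:3),
               contig = contigs[ci],
               start = starts, end = pmin(starts + span, contig_length),
               strand = if (ci %% 2L == 1L) c("+", "-", "+") else c("-", "+", "-"))
  })
  genes <- data.table::rbindlist(out)
  exon_frac <- rbind(c(0, 0.15), c(0.4, 0.55), c(0.85, 1))
  exons <- genes[rep(seq_len(.N), each = 3L)]
  ef <- exon_frac[rep(1:3, times = nrow(genes)), ]
  exons[, `:=`(exon_start = as.integer(start + ef[, 1] * (end - start)),
               exon_end = as.integer(start + ef[, 2] * (end - start)))]
  list(genes = genes, exons = exons[, .(gene_id, contig, strand,
                                        start = exon_start, end = exon_end)])
}

# disjoint 1 kb islands, >= 8 kb apart so shore/shelf bands do not collide
make_cgi_track <- function(contigs, contig_length) {
  starts <- seq(3000L, contig_length - 5000L, by = 12000L)
  data.table::rbindlist(lapply(contigs, function(ctg) {
    data.table(contig = ctg, start = as.integer(starts),
               end = as.integer(starts + 1000L))
  }))
}

# choose planted fragments and their per-pair assignment/directions
choose_planted <- function(in_window, config) {
  set.seed(substream(config$seed, "truth"))
  eligible <- in_window[in_window$n_cpgs >= 2L, ]
  if (config$n_planted_dmf > nrow(eligible)) {
    stop("n_planted_dmf exceeds eligible (>=2 CpG) size-selected fragments",
         call. = FALSE)
  }
  n_shared <- as.integer(round(config$shared_planted_fraction *
                                 config$n_planted_dmf))
  picks <- sample(eligible$fragment_id, config$n_planted_dmf)
  shared <- picks[seq_len(n_shared)]
  shared_dir <- ifelse(runif(n_shared) < config$planted_hyper_fraction,
                       "hyper", "hypo")
  out <- list()
  for (p in seq_len(config$n_pairs)) {
    extra <- setdiff(picks, shared)
    if (length(extra) > 0L) {
      # pair-private planted fragments: re-drawn direction per pair
      dir_extra <- ifelse(runif(length(extra)) < config$planted_hyper_fraction,
                          "hyper", "hypo")
    } else dir_extra <- character(0)
    out[[p]] <- data.table(fragment_id = c(shared, extra),
                           pair_id = p,
                           shared = c(rep(TRUE, n_shared),
                                      rep(FALSE, length(extra))),
                           direction = c(shared_dir, dir_extra))
  }
  planted <- data.table::rbindlist(out)
  planted[in_window, `:=`(contig = i.contig, start = i.start, end = i.end),
          on = "fragment_id"]
  planted[]
}

#' Simulate one tissue / cell-line pair of per-CpG count files
#'
#' True fragment methylation in the tissue sample is drawn from the bimodal
#' Beta mixture; the cell-line sample equals the tissue sample except at
#' planted fragments, which are shifted by `planted_delta` in the planted
#' direction. For a hypermethylated planted fragment the tissue level is
#' drawn from the low mode (truncated at `1 - planted_delta`) so the true
#' difference is exactly `planted_delta`; mirrored for hypomethylated ones.
#' If truncation cannot keep the shifted level in \[0,1\] it is clipped and
#' the clipped value recorded. Per-CpG depth is negative binomial; methylated
#' counts are binomial at the fragment's true level (CpGs within a fragment
#' share one level, since the fragment is the unit of analysis). Zero-depth
#' CpGs are omitted, as in real coverage files.
#'
#' @param art genome artifacts from [generate_genome()].
#' @param pair_id pair number (1-based).
#' @param seed simulation seed for this pair's counts; defaults to the
#'   config seed. Varying it (with a fixed genome) yields replicate count
#'   data over the same catalogue and truth directions.
#' @return list with `tissue` and `cell` per-CpG call tables
#'   (`contig, pos, count_M, count_U`, 0-based positions) and `truth`
#'   (per planted fragment: coordinates, pair, true levels, direction,
#'   clipped flag).
#' @export
simulate_pair <- function(art, pair_id, seed = art$config$seed) {
  cfg <- art$config
  set.seed(substream(seed, "pair", pair_id))
  frag <- as.data.table(art$in_window)
  bm <- cfg$beta_mixture
  n <- nrow(frag)
  hi <- runif(n) < bm[["weight_high"]]
  level_t <- ifelse(hi, rbeta(n, bm[["alpha_high"]], bm[["beta_high"]]),
                    rbeta(n, bm[["alpha_low"]], bm[["beta_low"]]))
  level_c <- level_t

  sel <- art$planted$pair_id == pair_id
  pl <- art$planted[which(sel), ]
  clipped <- logical(nrow(pl))
  if (nrow(pl) > 0L) {
    idx <- match(pl$fragment_id, frag$fragment_id)
    d <- cfg$planted_delta
    for (j in seq_len(nrow(pl))) {
      i <- idx[j]
      if (pl$direction[j] == "hyper") {
        t0 <- min(rbeta(1, bm[["alpha_low"]], bm[["beta_low"]]), 1 - d)
        c0 <- t0 + d
      } else {
        t0 <- max(rbeta(1, bm[["alpha_high"]], bm[["beta_high"]]), d)
        c0 <- t0 - d
      }
      if (c0 < 0 || c0 > 1) {  # only reachable when truncation is impossible
        c0 <- min(max(c0, 0), 1)
        clipped[j] <- TRUE
      }
      level_t[i] <- t0
      level_c[i] <- c0
    }
  }

  cpgs <- art$cpg_map %||% fragment_cpgs(art$seqs, frag)
  fi <- match(cpgs$fragment_id, frag$fragment_id)
  draw_sample <- function(levels) {
    cov <- rnbinom(nrow(cpgs), mu = cfg$coverage_mean,
                   size = cfg$coverage_dispersion)
    m <- rbinom(nrow(cpgs), cov, levels[fi])
    dt <- data.table(contig = cpgs$contig, pos = cpgs$pos,
                     count_M = m, count_U = cov - m)
    dt[cov > 0L]
  }
  tissue <- draw_sample(level_t)
  cell <- draw_sample(level_c)

  truth <- data.table(fragment_id = pl$fragment_id, contig = pl$contig,
                      start = pl$start, end = pl$end, pair_id = pair_id,
                      shared = pl$shared,
                      true_tissue = if (nrow(pl)) level_t[match(pl$fragment_id, frag$fragment_id)] else numeric(0),
                      true_cell = if (nrow(pl)) level_c[match(pl$fragment_id, frag$fragment_id)] else numeric(0),
                      direction = pl$direction, clipped = clipped)
  list(tissue = tissue, cell = cell, truth = truth)
}

#' Write simulation artifacts to disk
#'
#' Writes `genome.fa`, `genes.gtf` (gene + exon features), `cgi.bed`
#' (0-based half-open), per-sample Bismark-coverage-style call files
#' (`<sample>.cov`: chrom, pos, pos, methylation %, count methylated,
#' count unmethylated; 1-based inclusive), `truth.tsv`, and `config.json`.
#'
#' @param art genome artifacts from [generate_genome()].
#' @param pairs list of pair simulations from [simulate_pair()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(art, pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gtf"),
             cgi = file.path(dir, "cgi.bed"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  dna <- Biostrings::DNAStringSet(art$seqs)
  Biostrings::writeXStringSet(dna, paths[["genome"]])
  write_gtf(art$genes, paths[["genes"]])
  fwrite(art$cgi, paths[["cgi"]], sep = "\t", col.names = FALSE)
  truth <- data.table::rbindlist(lapply(pairs, `[[`, "truth"))
  fwrite(truth, paths[["truth"]], sep = "\t")
  cfg <- art$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  for (p in seq_along(pairs)) {
    for (s in c("tissue", "cell")) {
      f <- file.path(dir, sprintf("pair%d_%s.cov", p, s))
      write_cov(pairs[[p]][[s]], f)
      paths[[sprintf("pair%d_%s", p, s)]] <- f
    }
  }
  invisible(paths)
}

# Bismark-coverage dialect: 1-based inclusive, 6 columns
write_cov <- function(calls, path) {
  total <- calls$count_M + calls$count_U
  out <- data.table(calls$contig, calls$pos + 1L, calls$pos + 1L,
                    ifelse(total > 0, 100 * calls$count_M / total, 0),
                    calls$count_M, calls$count_U)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# minimal GTF writer: gene + exon features, gene_id/gene_name attributes
write_gtf <- function(genes, path) {
  g <- genes$genes
  e <- genes$exons
  attr_g <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_id)
  attr_e <- sprintf('gene_id "%s"; gene_name "%s";', e$gene_id, e$gene_id)
  lines <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$contig, g$start + 1L, g$end, g$strand, attr_g),
    sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
            e$contig, e$start + 1L, e$end, e$strand, attr_e))
  writeLines(lines, path)
  invisible(path)
}
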