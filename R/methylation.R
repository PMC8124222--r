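#' Read per-CpG methylation calls (Bismark-coverage dialect)
#'
#' Expects 6 tab-separated columns: chrom, start, end (1-based inclusive),
#' methylation percentage, methylated count, unmethylated count. Positions
#' are converted to 0-based. When a genome is supplied, calls are validated
#' against CpG sites: a call at the reverse-strand C of a CpG (position `p`
#' where the genome has `CG` starting at `p - 1`) is merged into the
#' forward-strand site `p - 1` by summing counts — CpG methylation is
#' palindromic, so the two strand reads measure one site. Calls at non-CpG
#' positions are dropped with a warning and counted in the QC tally.
#' Duplicate records for one site are summed.
#'
#' @param x path to a coverage file, or a data.frame of calls with columns
#'   `contig, pos, count_M, count_U` (0-based) to be strand-merged.
#' @param genome optional genome (FASTA path, `DNAStringSet`, or named
#'   character vector) for strand merging and validation.
#' @return `data.table(contig, pos, count_M, count_U)`, 0-based forward-strand
#'   positions, at most one row per site, sorted. Attribute `qc_dropped`
#'   holds the count of dropped non-CpG calls.
#' @export
read_cpg_calls <- function(x, genome = NULL) {
  if (is.character(x)) {
    calls <- parse_cov_file(x)
  } else {
    calls <- as.data.table(x)[, .(contig, pos, count_M, count_U)]
  }
  merge_strands(calls, genome)
}

parse_cov_file <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      count_M = integer(), count_U = integer()))
  }
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
               colClasses = list(character = 1))
  if (nrow(raw) == 0L) {
    return(data.table(contig = character(), pos = integer(),
                      count_M = integer(), count_U = integer()))
  }
  if (ncol(raw) < 6L) {
    stop(sprintf("%s: expected 6 tab-separated columns, found %d",
                 path, ncol(raw)), call. = FALSE)
  }
  bad <- which(is.na(suppressWarnings(as.integer(raw[[2L]]))) |
                 is.na(suppressWarnings(as.numeric(raw[[5L]]))) |
                 is.na(suppressWarnings(as.numeric(raw[[6L]]))))
  if (length(bad) > 0L) {
    stop(sprintf("%s: malformed line %d: '%s'", path, bad[1L],
                 paste(unlist(raw[bad[1L]]), collapse = "\t")), call. = FALSE)
  }
  data.table(contig = raw[[1L]], pos = as.integer(raw[[2L]]) - 1L,
             count_M = as.integer(raw[[5L]]), count_U = as.integer(raw[[6L]]))
}

#' Merge strand-resolved CpG calls onto forward-strand sites
#'
#' @param calls `data.table(contig, pos, count_M, count_U)`, 0-based.
#' @param genome optional genome for reverse-strand detection; without it,
#'   positions are assumed to already be forward-strand C coordinates and
#'   only duplicates are summed (idempotent).
#' @return merged call table as in [read_cpg_calls()].
#' @export
merge_strands <- function(calls, genome = NULL) {
  calls <- data.table::copy(as.data.table(calls))
  n_drop <- 0L
  if (!is.null(genome) && nrow(calls) > 0L) {
    seqs <- as_genome_seqs(genome)
    cgdt <- data.table::rbindlist(lapply(names(seqs), function(ctg) {
      data.table(contig = ctg, pos = cg_positions(seqs[[ctg]]))
    }))
    is_fwd <- !is.na(cgdt[calls, on = c("contig", "pos"), which = TRUE])
    shifted <- data.table(contig = calls$contig, pos = calls$pos - 1L)
    is_rev <- !is_fwd &
      !is.na(cgdt[shifted, on = c("contig", "pos"), which = TRUE])
    calls[is_rev, pos := pos - 1L]
    merged <- calls[is_fwd | is_rev]
    n_drop <- nrow(calls) - nrow(merged)
    if (n_drop > 0L) {
      warning(sprintf("dropped %d call(s) at non-CpG positions", n_drop),
              call. = FALSE)
    }
    calls <- merged
  }
  out <- calls[, .(count_M = sum(count_M), count_U = sum(count_U)),
               by = .(contig, pos)]
  setorder(out, contig, pos)
  data.table::setattr(out, "qc_dropped", n_drop)
  out[]
}

#' Fragment methylation level from pooled counts
#'
#' @param pooled_M,pooled_U summed methylated / unmethylated read counts.
#' @return `pooled_M / (pooled_M + pooled_U)` in \[0,1\].
#' @export
methylation_level <- function(pooled_M, pooled_U) {
  tot <- pooled_M + pooled_U
  if (any(tot <= 0)) {
    stop("methylation level undefined for zero total reads", call. = FALSE)
  }
  pooled_M / tot
}

#' Aggregate per-CpG calls to fragment methylation
#'
#' Each fragment receives the strand-merged calls at its CpG positions.
#' Counts are pooled over all covered CpGs of the fragment, and the fragment
#' level is the pooled proportion (not a mean of per-CpG proportions): the
#' pooled 2x2 table is the input of the per-fragment Fisher test downstream.
#' A fragment passes the coverage filter when at least `min_cpgs` distinct
#' CpG sites each have total depth >= `min_reads` (defaults 2 sites at 10
#' reads, the standard fragment-quality rule). Fragments with no covered
#' CpG are omitted.
#'
#' @param fragments fragment catalogue (after size selection).
#' @param cpg_map `data.table(fragment_id, contig, pos)` from
#'   [fragment_cpgs()].
#' @param calls strand-merged calls from [read_cpg_calls()].
#' @param min_reads minimum total depth for a CpG to qualify.
#' @param min_cpgs minimum number of qualifying CpGs for the fragment to
#'   pass.
#' @return `data.table(fragment_id, contig, start, end, n_cpgs_covered,
#'   n_qualifying, pooled_M, pooled_U, level, passes_filter)`, sorted by
#'   coordinates.
#' @export
aggregate_fragments <- function(fragments, cpg_map, calls,
                                min_reads = 10L, min_cpgs = 2L) {
  fr <- as.data.table(fragments)
  cp <- as.data.table(cpg_map)
  cl <- as.data.table(calls)
  j <- cl[cp, on = c("contig", "pos"), nomatch = NULL]
  j <- j[count_M + count_U > 0L]
  agg <- j[, .(n_cpgs_covered = .N,
               n_qualifying = sum(count_M + count_U >= min_reads),
               pooled_M = sum(count_M), pooled_U = sum(count_U)),
           by = fragment_id]
  agg[, `:=`(level = pooled_M / (pooled_M + pooled_U),
             passes_filter = n_qualifying >= min_cpgs)]
  out <- agg[fr, on = "fragment_id", nomatch = NULL]
  out <- out[, .(fragment_id, contig, start, end, n_cpgs_covered,
                 n_qualifying, pooled_M, pooled_U, level, passes_filter)]
  setorder(out, contig, start)
  out[]
}

#' Write / read per-sample fragment methylation tables
#' @param frag_meth table from [aggregate_fragments()].
#' @param path TSV path.
#' @export
write_fragment_methylation <- function(frag_meth, path) {
  fwrite(frag_meth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_fragment_methylation
#' @export
read_fragment_methylation <- function(path) {
  fread(path, sep = "\t")
}
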