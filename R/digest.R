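#' In-silico MspI digestion of a genome
#'
#' MspI cleaves C^CGG. Every occurrence of the motif CCGG (forward strand,
#' case-insensitive, `N` never matches) defines a cut one base into the motif,
#' so an internal fragment begins with `CGG` and ends with `C`. Terminal
#' pieces (contig start to first cut, last cut to contig end) are excluded:
#' real RRBS fragments carry MspI ends on both sides. Coordinates are 0-based
#' half-open throughout.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   contig sequences.
#' @return `data.table` with columns `contig`, `start`, `end`, `fragment_id`
#'   (`contig:start-end`), `length`, `n_cpgs` (forward-strand CpGs fully
#'   inside the fragment), sorted by contig then start.
#' @export
digest_genome <- function(genome) {
  seqs <- as_genome_seqs(genome)
  out <- lapply(names(seqs), function(ctg) {
    s <- seqs[[ctg]]
    if (nchar(s) < 4L) return(NULL)
    hits <- Biostrings::matchPattern("CCGG", Biostrings::DNAString(s),
                                     fixed = TRUE)
    # 0-based cut position = (occurrence index 0-based) + 1 = 1-based start
    cuts <- BiocGenerics::start(hits)
    if (length(cuts) < 2L) return(NULL)
    st <- cuts[-length(cuts)]
    en <- cuts[-1L]
    data.table(contig = ctg, start = st, end = en)
  })
  frags <- data.table::rbindlist(out)
  if (nrow(frags) == 0L) {
    return(data.table(contig = character(), start = integer(), end = integer(),
                      fragment_id = character(), length = integer(),
                      n_cpgs = integer()))
  }
  frags[, `:=`(fragment_id = sprintf("%s:%d-%d", contig, start, end),
               length = end - start)]
  cpg <- fragment_cpgs(seqs, frags)
  ncp <- cpg[, .N, by = fragment_id]
  frags[, n_cpgs := 0L]
  frags[ncp, n_cpgs := i.N, on = "fragment_id"]
  setorder(frags, contig, start)
  frags[]
}

#' Size-select fragments
#'
#' Keeps fragments with `min_len <= length <= max_len` (inclusive bounds),
#' the in-silico counterpart of RRBS library size selection (default
#' 40-220 bp).
#'
#' @param fragments fragment table from [digest_genome()].
#' @param min_len,max_len inclusive length bounds in bp.
#' @export
size_select <- function(fragments, min_len = 40L, max_len = 220L) {
  stop_if_not_scalar_number(min_len, "min_len", min = 0)
  if (!identical(max_len, Inf)) stop_if_not_scalar_number(max_len, "max_len", min = 0)
  if (min_len > max_len) stop("min_len must not exceed max_len", call. = FALSE)
  fragments[fragments$length >= min_len & fragments$length <= max_len, ]
}

#' Enumerate CpG positions within a fragment
#'
#' Returns 0-based forward-strand positions `p` of the C of each CpG with
#' `start <= p` and `p + 2 <= end`: a CG straddling the fragment end is
#' excluded. Methylation at a CpG is palindromic, so only the forward-strand
#' coordinate is kept; reverse-strand calls are merged onto it at ingestion.
#'
#' @param genome genome as for [digest_genome()].
#' @param contig contig name.
#' @param start,end 0-based half-open fragment interval.
#' @return integer vector of 0-based CpG positions.
#' @export
enumerate_cpgs <- function(genome, contig, start, end) {
  seqs <- as_genome_seqs(genome)
  if (!contig %in% names(seqs)) stop("unknown contig: ", contig, call. = FALSE)
  s <- seqs[[contig]]
  if (start < 0L || end > nchar(s) || start >= end) {
    stop(sprintf("fragment [%d,%d) outside contig '%s' (length %d)",
                 start, end, contig, nchar(s)), call. = FALSE)
  }
  pos <- cg_positions(s)
  pos[pos >= start & pos + 2L <= end]
}

# all 0-based forward-strand CG start positions in one sequence
cg_positions <- function(s) {
  hits <- Biostrings::matchPattern("CG", Biostrings::DNAString(s), fixed = TRUE)
  BiocGenerics::start(hits) - 1L
}

#' CpG positions for every fragment
#'
#' @param genome genome as for [digest_genome()].
#' @param fragments fragment table.
#' @return `data.table(fragment_id, contig, pos)` with one row per CpG,
#'   0-based C positions.
#' @export
fragment_cpgs <- function(genome, fragments) {
  seqs <- as_genome_seqs(genome)
  fr <- as.data.table(fragments)
  out <- lapply(split(fr, fr$contig), function(fc) {
    s <- seqs[[fc$contig[1L]]]
    pos <- cg_positions(s)
    if (length(pos) == 0L) return(NULL)
    # fragments are sorted, non-overlapping: assign each CpG by interval search
    idx <- findInterval(pos, fc$start)
    ok <- idx >= 1L & idx <= nrow(fc)
    idx2 <- idx[ok]; p2 <- pos[ok]
    keep <- p2 + 2L <= fc$end[idx2]
    data.table(fragment_id = fc$fragment_id[idx2][keep],
               contig = fc$contig[1L], pos = p2[keep])
  })
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(fragment_id = character(), contig = character(),
                      pos = integer()))
  }
  setorder(res, contig, pos)
  res[]
}

#' Write / read a fragment catalogue as BED6+
#'
#' Columns: contig, start, end, fragment_id, length, ".", n_cpgs
#' (0-based half-open, the BED convention).
#' @param fragments fragment table.
#' @param path output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.table(fragments$contig, fragments$start, fragments$end,
                    fragments$fragment_id, fragments$length, ".",
                    fragments$n_cpgs)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  fr <- fread(path, header = FALSE,
              col.names = c("contig", "start", "end", "fragment_id",
                            "length", "strand", "n_cpgs"))
  fr[, strand := NULL]
  setorder(fr, contig, start)
  fr[]
}
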