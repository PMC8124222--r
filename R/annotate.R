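#' Read gene models from GTF
#'
#' Imports `gene` and `exon` features; the gene name is taken from the
#' `gene_name` attribute, falling back to `gene_id`. Returns 0-based
#' half-open intervals with the TSS at the span start on `+` and span
#' end - 1 on `-`.
#'
#' @param path GTF path.
#' @return list of `genes` (`data.table(gene, contig, start, end, strand,
#'   tss)`) and `exons` (`data.table(gene, contig, start, end)`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.table(S4Vectors::mcols(gr))
  nm <- if ("gene_name" %in% names(meta) && !all(is.na(meta$gene_name))) {
    ifelse(is.na(meta$gene_name), meta$gene_id, meta$gene_name)
  } else meta$gene_id
  dt <- data.table(gene = nm,
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,  # to 0-based
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(meta$type))
  genes <- dt[type == "gene",
              .(gene, contig, start, end, strand)]
  if (nrow(genes) == 0L) {  # derive spans from exons when no gene features
    genes <- dt[type == "exon",
                .(start = min(start), end = max(end), strand = strand[1L]),
                by = .(gene, contig)]
  }
  genes[, tss := ifelse(strand == "+", start, end - 1L)]
  exons <- dt[type == "exon", .(gene, contig, start, end)]
  list(genes = genes[], exons = exons[])
}

#' Read a BED interval file
#'
#' @param path BED path (0-based half-open); first three columns used.
#' @return `data.table(contig, start, end)` sorted.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.table(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr))
  setorder(out, contig, start)
  out[]
}

# GRanges from a 0-based half-open table
as_granges0 <- function(dt) {
  GenomicRanges::GRanges(dt$contig,
                         IRanges::IRanges(start = dt$start + 1L,
                                          end = dt$end))
}

#' Promoter interval of a gene
#'
#' The promoter window spans 2 kb upstream to 1 kb downstream of the TSS,
#' strand-aware: on `+`, `[tss - 2000, tss + 1000)`; on `-`, the mirrored
#' window `[tss - 999, tss + 2001)`. Clipped at the contig origin (and at
#' `contig_length` when given).
#'
#' @param tss 0-based TSS position(s).
#' @param strand `"+"` or `"-"` (vectorised).
#' @param upstream,downstream window extents in bp.
#' @param contig_length optional clip bound.
#' @return `data.table(start, end)` of 0-based half-open intervals.
#' @export
promoter_interval <- function(tss, strand, upstream = 2000L,
                              downstream = 1000L, contig_length = NULL) {
  start <- ifelse(strand == "+", tss - upstream, tss - downstream + 1L)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream + 1L)
  start <- pmax(start, 0L)
  if (!is.null(contig_length)) end <- pmin(end, contig_length)
  data.table(start = as.integer(start), end = as.integer(end))
}

#' Classify fragments by gene context
#'
#' Assigns exactly one of `promoter`, `junction`, `exon`, `intron`,
#' `intergenic` per fragment (any-overlap rule, >= 1 bp), with precedence
#' promoter > junction > exon > intron > intergenic. `junction` means the
#' fragment overlaps both exonic and intronic sequence of one gene, i.e. it
#' spans an exon-intron boundary. The assigned gene is the one providing the
#' winning context; ties are broken by smallest TSS distance, then
#' lexicographic gene name. Intergenic fragments overlap neither a promoter
#' window nor any gene span.
#'
#' @param fragments fragment table (0-based half-open).
#' @param gene_models list from [read_gene_models()] (or the `genes` element
#'   of a simulated genome).
#' @param upstream,downstream promoter window extents.
#' @return `data.table(fragment_id, gene_context, gene)`.
#' @export
classify_gene_context <- function(fragments, gene_models,
                                  upstream = 2000L, downstream = 1000L) {
  fr <- as.data.table(fragments)
  genes <- data.table::copy(as.data.table(gene_models$genes))
  exons <- data.table::copy(as.data.table(gene_models$exons))
  # accept simulated gene models, which carry gene_id instead of gene
  if (!"gene" %in% names(genes)) genes[, gene := gene_id]
  if (!"gene" %in% names(exons)) exons[, gene := gene_id]
  if (!"tss" %in% names(genes)) {
    genes[, tss := ifelse(strand == "+", start, end - 1L)]
  }
  frg <- as_granges0(fr)
  res <- data.table(fragment_id = fr$fragment_id,
                    gene_context = "intergenic", gene = NA_character_,
                    prio = 5L, tssdist = Inf)

  mid <- (fr$start + fr$end) / 2

  assign_hits <- function(hit_dt, new_context, new_prio) {
    # hit_dt: data.table(frag_idx, gene); keep best per fragment
    if (nrow(hit_dt) == 0L) return(invisible())
    hit_dt[, tssdist := abs(mid[frag_idx] -
                              genes$tss[match(gene, genes$gene)])]
    setorder(hit_dt, frag_idx, tssdist, gene)
    best <- hit_dt[!duplicated(frag_idx)]
    upd <- best[res$prio[best$frag_idx] > new_prio]
    if (nrow(upd) > 0L) {
      new_gene <- upd$gene
      new_tssd <- upd$tssdist
      res[upd$frag_idx, `:=`(gene_context = new_context, gene = new_gene,
                             prio = new_prio, tssdist = new_tssd)]
    }
    invisible()
  }

  # promoters
  pw <- promoter_interval(genes$tss, genes$strand, upstream, downstream)
  prom <- data.table(contig = genes$contig, start = pw$start, end = pw$end,
                     gene = genes$gene)
  ov <- GenomicRanges::findOverlaps(frg, as_granges0(prom))
  assign_hits(data.table(frag_idx = S4Vectors::queryHits(ov),
                         gene = prom$gene[S4Vectors::subjectHits(ov)]),
              "promoter", 1L)

  # exon / intron overlap per gene
  exm <- merge_intervals(exons)  # merged exons per gene
  introns <- gene_introns(genes, exm)
  ove <- GenomicRanges::findOverlaps(frg, as_granges0(exm))
  ex_hits <- data.table(frag_idx = S4Vectors::queryHits(ove),
                        gene = exm$gene[S4Vectors::subjectHits(ove)])
  ovi <- GenomicRanges::findOverlaps(frg, as_granges0(introns))
  in_hits <- data.table(frag_idx = S4Vectors::queryHits(ovi),
                        gene = introns$gene[S4Vectors::subjectHits(ovi)])
  # junction: same gene contributes exon and intron overlap
  jn <- unique(ex_hits)[unique(in_hits), on = c("frag_idx", "gene"),
                        nomatch = NULL]
  assign_hits(jn, "junction", 2L)
  assign_hits(unique(ex_hits), "exon", 3L)
  assign_hits(unique(in_hits), "intron", 4L)

  res[, `:=`(prio = NULL, tssdist = NULL)]
  res[]
}

# merge overlapping intervals within gene
merge_intervals <- function(iv) {
  iv <- as.data.table(iv)
  setorder(iv, gene, contig, start)
  iv[, grp := cumsum(start > data.table::shift(cummax(end), fill = -1L)),
     by = .(gene, contig)]
  out <- iv[, .(start = min(start), end = max(end)),
            by = .(gene, contig, grp)]
  out[, grp := NULL]
  out[]
}

# intron intervals: the gene span minus its merged exons (so any part of a
# gene span that is not exonic counts as intronic sequence)
gene_introns <- function(genes, merged_exons) {
  ex <- as.data.table(merged_exons)
  setorder(ex, gene, contig, start)
  parts <- lapply(split(ex, ex$gene), function(eg) {
    g <- genes[genes$gene == eg$gene[1L], ]
    if (nrow(g) == 0L) return(NULL)
    bounds_s <- c(g$start[1L], eg$end)
    bounds_e <- c(eg$start, g$end[1L])
    keep <- bounds_e > bounds_s
    if (!any(keep)) return(NULL)
    data.table(gene = eg$gene[1L], contig = eg$contig[1L],
               start = bounds_s[keep], end = bounds_e[keep])
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0L) {
    return(data.table(gene = character(), contig = character(),
                      start = integer(), end = integer()))
  }
  out[]
}

#' Classify fragments by CpG-island context
#'
#' `core` if the fragment overlaps a (merged) CpG island, `shore` if it
#' overlaps the `shore_width` (default 2 kb) flanks but no island, `shelf`
#' if it overlaps the next `shelf_width - shore_width` band (2-4 kb) but no
#' island or shore band, else `open_sea`. Categories partition.
#'
#' @param fragments fragment table.
#' @param islands island intervals (`data.table(contig, start, end)`).
#' @param shore_width,shelf_width flank widths in bp.
#' @return `data.table(fragment_id, cgi_context)`.
#' @export
classify_cgi_context <- function(fragments, islands,
                                 shore_width = 2000L, shelf_width = 4000L) {
  fr <- as.data.table(fragments)
  isl <- as.data.table(islands)[, .(gene = "cgi", contig, start, end)]
  isl <- merge_intervals(isl)[, .(contig, start, end)]
  frg <- as_granges0(fr)
  ov_any <- function(iv) {
    if (nrow(iv) == 0L) return(logical(nrow(fr)))
    iv <- iv[end > start]
    hits <- GenomicRanges::findOverlaps(frg, as_granges0(iv))
    seq_len(nrow(fr)) %in% S4Vectors::queryHits(hits)
  }
  core <- ov_any(isl)
  shore_band <- isl[, .(contig, start = pmax(start - shore_width, 0L),
                        end = end + shore_width)]
  shelf_band <- isl[, .(contig, start = pmax(start - shelf_width, 0L),
                        end = end + shelf_width)]
  in_shore <- ov_any(shore_band)
  in_shelf <- ov_any(shelf_band)
  ctx <- data.table::fcase(core, "core",
                           in_shore, "shore",
                           in_shelf, "shelf",
                           default = "open_sea")
  data.table(fragment_id = fr$fragment_id, cgi_context = ctx)
}

#' Overlap fragments with a feature track
#'
#' @param fragments fragment table.
#' @param features feature intervals (`data.table(contig, start, end)` or a
#'   BED path), 0-based half-open; sorted internally.
#' @return list with `overlaps` (logical per fragment, any shared bp) and
#'   `fraction` (proportion of fragments overlapping).
#' @export
overlap_features <- function(fragments, features) {
  fr <- as.data.table(fragments)
  fe <- if (is.character(features)) read_bed(features) else
    as.data.table(features)
  if (nrow(fe) == 0L || nrow(fr) == 0L) {
    return(list(overlaps = logical(nrow(fr)), fraction = 0))
  }
  setorder(fe, contig, start)
  hits <- GenomicRanges::findOverlaps(as_granges0(fr), as_granges0(fe))
  ovl <- seq_len(nrow(fr)) %in% S4Vectors::queryHits(hits)
  list(overlaps = ovl, fraction = mean(ovl))
}

#' Annotate fragments with gene and CGI context
#'
#' @inheritParams classify_gene_context
#' @inheritParams classify_cgi_context
#' @return `data.table(fragment_id, gene_context, gene, cgi_context)`.
#' @export
annotate_fragments <- function(fragments, gene_models, islands,
                               upstream = 2000L, downstream = 1000L,
                               shore_width = 2000L, shelf_width = 4000L) {
  gc <- classify_gene_context(fragments, gene_models, upstream, downstream)
  cgi <- classify_cgi_context(fragments, islands, shore_width, shelf_width)
  gc[cgi, on = "fragment_id", cgi_context := i.cgi_context]
  gc[]
}

#' Gene sets of common DMFs by context
#'
#' @param common common-DMF table from [intersect_common()].
#' @param annotations annotation table from [annotate_fragments()].
#' @return list of `promoter` (distinct assigned genes of promoter-context
#'   DMFs), `body` (genes of exon/intron/junction-context DMFs), and `both`
#'   (their intersection).
#' @export
genes_for_common_dmfs <- function(common, annotations) {
  ann <- as.data.table(annotations)
  cm <- as.data.table(common)
  a <- ann[cm, on = "fragment_id", nomatch = NULL]
  prom <- sort(unique(a[gene_context == "promoter" & !is.na(gene), gene]))
  body <- sort(unique(a[gene_context %in% c("exon", "intron", "junction") &
                          !is.na(gene), gene]))
  list(promoter = prom, body = body, both = intersect(prom, body))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail `P(X >= overlap)` per gene set, with the
#' population equal to the background (e.g. all genes overlapping commonly
#' analysed RRBS fragments), successes the set intersected with the
#' background, and draws the query size. P-values are Benjamini-Hochberg
#' adjusted across sets.
#'
#' @param query character vector of query genes (subset of background).
#' @param background character vector of background genes.
#' @param gene_sets named list of character vectors, or a GMT path.
#' @return `data.table(set, n_set, n_overlap, p_value, p_adj,
#'   overlap_genes)` sorted by p-value.
#' @export
enrich_gene_set <- function(query, background, gene_sets) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% background)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- fgsea::gmtPathways(gene_sets)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), background)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.table(set = s, n_set = K, n_overlap = k, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","))
  })
  out <- data.table::rbindlist(rows)
  out[, p_adj := p.adjust(p_value, method = "BH")]
  setorder(out, p_value)
  out[, .(set, n_set, n_overlap, p_value, p_adj, overlap_genes)]
}
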