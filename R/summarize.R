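#' Histogram of fragment methylation levels
#'
#' Bins partition \[0,1\] into `n_bins` equal intervals, left-closed with a
#' right-closed last bin, so counts always sum to the number of fragments.
#'
#' @param levels numeric vector of methylation levels in \[0,1\].
#' @param n_bins number of bins (default 50).
#' @return `data.table(bin_start, bin_end, count)`.
#' @export
methylation_histogram <- function(levels, n_bins = 50L) {
  if (!is.numeric(n_bins) || n_bins < 1L) {
    stop("n_bins must be >= 1", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(levels, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  data.table(bin_start = breaks[-(n_bins + 1L)], bin_end = breaks[-1L],
             count = counts)
}

#' Pearson correlation of two samples' fragment methylation
#'
#' Computed over fragments passing the coverage filter in both samples.
#'
#' @param fragA,fragB fragment methylation tables from
#'   [aggregate_fragments()].
#' @return Pearson r.
#' @export
pairwise_correlation <- function(fragA, fragB) {
  a <- as.data.table(fragA)[passes_filter == TRUE]
  b <- as.data.table(fragB)[passes_filter == TRUE]
  j <- a[b, on = "fragment_id", nomatch = NULL,
         .(la = x.level, lb = i.level)]
  if (nrow(j) < 3L) stop("need at least 3 shared fragments", call. = FALSE)
  if (stats::sd(j$la) == 0 || stats::sd(j$lb) == 0) {
    stop("zero variance in at least one sample", call. = FALSE)
  }
  cor(j$la, j$lb)
}

#' Build the fragment x sample methylation matrix
#'
#' Rows are fragments passing the coverage filter in every included sample,
#' sorted by coordinates; cells are methylation levels.
#'
#' @param frag_list named list of fragment methylation tables.
#' @return numeric matrix, rownames = fragment ids, colnames = sample names.
#' @export
methylome_matrix <- function(frag_list) {
  stopifnot(length(frag_list) >= 1L, !is.null(names(frag_list)))
  pass <- lapply(frag_list, function(f) {
    as.data.table(f)[passes_filter == TRUE,
                     .(fragment_id, contig, start, level)]
  })
  ids <- Reduce(intersect, lapply(pass, `[[`, "fragment_id"))
  coords <- pass[[1L]][fragment_id %in% ids]
  setorder(coords, contig, start)
  mat <- vapply(pass, function(f) {
    f$level[match(coords$fragment_id, f$fragment_id)]
  }, numeric(nrow(coords)))
  rownames(mat) <- coords$fragment_id
  mat
}

#' Hierarchical clustering of samples by methylation profile
#'
#' Agglomerative clustering with distance `1 - Pearson r` between sample
#' columns and average linkage; deterministic given the matrix (columns are
#' taken in sample-name order, which fixes tie-breaking).
#'
#' @param mat fragment x sample matrix from [methylome_matrix()].
#' @return an `hclust` object, or for a single sample a one-leaf list with
#'   element `labels`.
#' @export
cluster_samples <- function(mat) {
  if (ncol(mat) == 1L) {
    return(structure(list(labels = colnames(mat)), class = "single_leaf"))
  }
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- as.dist(1 - cor(mat))
  hclust(d, method = "average")
}

#' Newick export of a sample dendrogram
#' @param hc `hclust` object from [cluster_samples()].
#' @return Newick-style nested string with merge heights as branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  if (inherits(hc, "single_leaf")) return(paste0(hc$labels, ";"))
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g", build(hc$merge[i, 1L], h),
              build(hc$merge[i, 2L], h), parent_h - h)
    }
  }
  n <- length(hc$height)
  h <- hc$height[n]
  paste0(sprintf("(%s,%s)", build(hc$merge[n, 1L], h),
                 build(hc$merge[n, 2L], h)), ";")
}

#' Methylation distributions by genomic element class
#'
#' Per element class and sample, the median fragment level; per element
#' class and tissue/cell-line pair, a two-sided Wilcoxon rank-sum p-value on
#' the two samples' level vectors (exact for small untied samples, else the
#' tie-corrected normal approximation with continuity correction).
#'
#' @param frag_list named list of fragment methylation tables.
#' @param annotations annotation table from [annotate_fragments()].
#' @param pairs data.frame with columns `tissue`, `cell` naming samples in
#'   `frag_list`.
#' @param classes element classes to summarise (values of `gene_context`).
#' @return list of `medians` (`data.table(class, sample, median, n)`) and
#'   `tests` (`data.table(class, tissue, cell, p_value)`).
#' @export
element_distributions <- function(frag_list, annotations, pairs,
                                  classes = c("promoter", "exon", "intron",
                                              "junction", "intergenic")) {
  ann <- as.data.table(annotations)
  levels_by <- function(sample, cls) {
    f <- as.data.table(frag_list[[sample]])[passes_filter == TRUE]
    ids <- ann[gene_context == cls, fragment_id]
    f[fragment_id %in% ids, level]
  }
  med <- data.table::rbindlist(lapply(classes, function(cl) {
    data.table::rbindlist(lapply(names(frag_list), function(s) {
      v <- levels_by(s, cl)
      data.table(class = cl, sample = s,
                 median = if (length(v)) median(v) else NA_real_,
                 n = length(v))
    }))
  }))
  tests <- data.table::rbindlist(lapply(classes, function(cl) {
    data.table::rbindlist(lapply(seq_len(nrow(pairs)), function(i) {
      vt <- levels_by(pairs$tissue[i], cl)
      vc <- levels_by(pairs$cell[i], cl)
      p <- if (length(vt) == 0L || length(vc) == 0L) NA_real_ else
        suppressWarnings(wilcox.test(vt, vc)$p.value)
      data.table(class = cl, tissue = pairs$tissue[i], cell = pairs$cell[i],
                 p_value = p)
    }))
  }))
  list(medians = med, tests = tests)
}

#' Machine-readable run report
#'
#' Collects per-sample QC, fragment and DMF counts, concordance, context
#' proportions, medians (2 decimals) and pairwise correlations into one
#' JSON-serialisable list; absent stages are noted rather than failing.
#'
#' @param frag_list named list of fragment methylation tables.
#' @param dmfs named list of DMF tables per pair (may be NULL).
#' @param common common-DMF table (may be NULL).
#' @param annotations annotation table (may be NULL).
#' @param pairs pair definition data.frame (`tissue`, `cell`).
#' @param path optional JSON output path.
#' @return the report list, invisibly when written.
#' @export
run_report <- function(frag_list, dmfs = NULL, common = NULL,
                       annotations = NULL, pairs = NULL, path = NULL) {
  rep <- list()
  rep$samples <- lapply(frag_list, function(f) {
    f <- as.data.table(f)
    pass <- f[passes_filter == TRUE]
    list(n_fragments_covered = nrow(f),
         n_fragments_pass = nrow(pass),
         median_level = round_half_up(median(pass$level), 2))
  })
  if (!is.null(pairs)) {
    rep$correlations <- lapply(seq_len(nrow(pairs)), function(i) {
      list(tissue = pairs$tissue[i], cell = pairs$cell[i],
           pearson_r = pairwise_correlation(frag_list[[pairs$tissue[i]]],
                                            frag_list[[pairs$cell[i]]]))
    })
  }
  if (!is.null(dmfs)) {
    rep$dmf <- lapply(dmfs, function(d) {
      d <- as.data.table(d)
      list(n_tested = nrow(d), n_significant = sum(d$significant),
           n_hyper = sum(d$significant & d$direction == "hyper_in_cell_line"),
           n_hypo = sum(d$significant & d$direction == "hypo_in_cell_line"))
    })
  } else rep$dmf <- "absent"
  if (!is.null(common)) {
    cs <- concordance_summary(common)
    rep$common_dmf <- list(n = sum(cs$count),
                           counts = as.list(stats::setNames(cs$count, cs$category)),
                           pct = as.list(stats::setNames(cs$pct, cs$category)))
  } else rep$common_dmf <- "absent"
  if (!is.null(annotations)) {
    ann <- as.data.table(annotations)
    rep$context <- list(
      gene = as.list(prop.table(table(ann$gene_context))),
      cgi = as.list(prop.table(table(ann$cgi_context))))
  } else rep$context <- "absent"
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
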