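#' Two-sided Fisher exact test on a 2x2 count table
#'
#' The p-value is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (the conventional two-sided definition), with a relative
#' tie tolerance of 1e-7 so floating-point ties are resolved
#' deterministically. A table with a zero margin has a single attainable
#' configuration and returns p = 1. Vectorised over its four arguments.
#'
#' @param M1,U1 methylated / unmethylated counts in sample 1.
#' @param M2,U2 methylated / unmethylated counts in sample 2.
#' @return p-value(s) in (0, 1].
#' @export
fisher_exact_two_sided <- function(M1, U1, M2, U2) {
  n <- max(length(M1), length(U1), length(M2), length(U2))
  M1 <- rep_len(as.numeric(M1), n); U1 <- rep_len(as.numeric(U1), n)
  M2 <- rep_len(as.numeric(M2), n); U2 <- rep_len(as.numeric(U2), n)
  if (any(c(M1, U1, M2, U2) < 0)) stop("counts must be >= 0", call. = FALSE)
  vapply(seq_len(n), function(i) {
    fisher_one(M1[i], U1[i], M2[i], U2[i])
  }, numeric(1))
}

fisher_one <- function(m1, u1, m2, u2, tie_tol = 1e-7) {
  K <- m1 + m2          # methylated margin
  r1 <- m1 + u1         # sample 1 margin
  N <- m1 + u1 + m2 + u2
  if (N == 0) return(1)
  lo <- max(0, K - (N - r1))
  hi <- min(K, r1)
  if (lo == hi) return(1)  # zero margin: a single attainable table
  d <- dhyper(lo:hi, K, N - K, r1)
  d0 <- d[m1 - lo + 1L]
  min(1, sum(d[d <= d0 * (1 + tie_tol)]))
}

#' Call differentially methylated fragments (DMFs) for one sample pair
#'
#' Tests every fragment passing the coverage filter in both samples on its
#' pooled-count 2x2 table with [fisher_exact_two_sided()]. The Bonferroni
#' family is the set of fragments actually tested (`n_tests`); a fragment is
#' significant when `p <= alpha / n_tests` and the absolute difference of
#' pooled methylation levels is at least `min_diff`. By convention sample B
#' is the cell line, so `diff = level_B - level_A > 0` means hypermethylated
#' in the cell line.
#'
#' @param fragA,fragB fragment methylation tables from
#'   [aggregate_fragments()] over the same catalogue (A = tissue,
#'   B = cell line).
#' @param alpha family-wise significance level (default 0.01).
#' @param min_diff minimum absolute methylation difference (default 0.25).
#' @return `data.table` with one row per tested fragment: coordinates,
#'   counts, levels, `diff`, `p_value`, `n_tests`, `significant`,
#'   `direction` (`hyper_in_cell_line` / `hypo_in_cell_line`), sorted by
#'   coordinates.
#' @export
call_dmfs <- function(fragA, fragB, alpha = 0.01, min_diff = 0.25) {
  stop_if_not_scalar_number(alpha, "alpha", 0, 1)
  stop_if_not_scalar_number(min_diff, "min_diff", 0, 1)
  a <- as.data.table(fragA)[passes_filter == TRUE]
  b <- as.data.table(fragB)[passes_filter == TRUE]
  j <- a[b, on = c("fragment_id", "contig", "start", "end"), nomatch = NULL,
         .(fragment_id, contig, start, end,
           M1 = x.pooled_M, U1 = x.pooled_U, level1 = x.level,
           M2 = i.pooled_M, U2 = i.pooled_U, level2 = i.level)]
  if (nrow(j) == 0L) {
    warning("no fragments pass the coverage filter in both samples",
            call. = FALSE)
    return(j[, `:=`(diff = numeric(0), p_value = numeric(0),
                    n_tests = integer(0), significant = logical(0),
                    direction = character(0))][])
  }
  j[, `:=`(diff = level2 - level1,
           p_value = fisher_exact_two_sided(M1, U1, M2, U2),
           n_tests = nrow(j))]
  j[, `:=`(significant = p_value <= alpha / n_tests & abs(diff) >= min_diff,
           direction = ifelse(diff > 0, "hyper_in_cell_line",
                              "hypo_in_cell_line"))]
  setorder(j, contig, start)
  j[]
}

#' Intersect DMF calls across pairs
#'
#' A common DMF is a fragment significant in every pair, matched by exact
#' fragment coordinates (all samples are aggregated on one MspI catalogue).
#' Concordance is `both_hyper` / `both_hypo` when the direction agrees
#' across pairs, else `discordant`. Symmetric in its arguments.
#'
#' @param dmfs1,dmfs2 DMF tables from [call_dmfs()] for two pairs.
#' @return `data.table(fragment_id, contig, start, end, diff1, diff2,
#'   direction1, direction2, concordance)` sorted by coordinates.
#' @export
intersect_common <- function(dmfs1, dmfs2) {
  s1 <- as.data.table(dmfs1)[significant == TRUE]
  s2 <- as.data.table(dmfs2)[significant == TRUE]
  j <- s1[s2, on = c("fragment_id", "contig", "start", "end"), nomatch = NULL,
          .(fragment_id, contig, start, end,
            diff1 = x.diff, diff2 = i.diff,
            direction1 = x.direction, direction2 = i.direction)]
  j[, concordance := data.table::fcase(
    direction1 == "hyper_in_cell_line" & direction2 == "hyper_in_cell_line",
    "both_hyper",
    direction1 == "hypo_in_cell_line" & direction2 == "hypo_in_cell_line",
    "both_hypo",
    default = "discordant")]
  setorder(j, contig, start)
  j[]
}

#' Summarise direction concordance of common DMFs
#'
#' @param common common-DMF table from [intersect_common()], or a named
#'   integer vector / list with elements `both_hyper`, `both_hypo`,
#'   `discordant` (e.g. a published partition).
#' @return `data.frame(category, count, pct)` with percentages of the total
#'   rounded half-up to one decimal; an empty input yields all zeros.
#' @export
concordance_summary <- function(common) {
  cats <- c("both_hyper", "both_hypo", "discordant")
  if (is.data.frame(common)) {
    counts <- vapply(cats, function(k) sum(common$concordance == k), integer(1))
  } else {
    counts <- vapply(cats, function(k) as.integer(common[[k]] %||% 0L),
                     integer(1))
  }
  total <- sum(counts)
  pct <- if (total == 0L) rep(0, 3L) else round_half_up(100 * counts / total, 1)
  data.frame(category = cats, count = unname(counts), pct = unname(pct))
}

#' Export DMFs as BED for genome browsers
#' @param dmfs DMF table; only significant fragments are written.
#' @param path output BED path.
#' @export
write_dmf_bed <- function(dmfs, path) {
  d <- as.data.table(dmfs)[significant == TRUE]
  bed <- data.table(d$contig, d$start, d$end, d$fragment_id,
                    as.integer(round(1000 * abs(d$diff))),
                    ifelse(d$diff > 0, "+", "-"))
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
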