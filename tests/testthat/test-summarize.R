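test_that("histogram bins partition [0,1] and conserve counts", {
  h0 <- methylation_histogram(rep(0, 5), n_bins = 10)
  expect_equal(h0$count[1], 5L)
  expect_equal(sum(h0$count), 5L)
  h2 <- methylation_histogram(c(0, 1), n_bins = 2)
  expect_equal(h2$count, c(1L, 1L))   # 1.0 lands in the right-closed last bin
  set.seed(51)
  x <- runif(5000)
  h <- methylation_histogram(x, n_bins = 10)
  expect_equal(sum(h$count), 5000L)
  expect_true(all(abs(h$count - 500) <= 4 * sqrt(5000)))
  expect_error(methylation_histogram(x, n_bins = 0), "n_bins")
})

frag_levels <- function(ids, levels) {
  n <- length(ids)
  data.table::data.table(
    fragment_id = ids, contig = "c", start = seq_len(n) * 100L,
    end = seq_len(n) * 100L + 50L, n_cpgs_covered = 2L, n_qualifying = 2L,
    pooled_M = as.integer(round(levels * 100)),
    pooled_U = as.integer(round((1 - levels) * 100)),
    level = levels, passes_filter = TRUE)
}

test_that("pairwise correlation matches the closed form", {
  ids <- c("f1", "f2", "f3")
  a <- frag_levels(ids, c(0.1, 0.5, 0.9))
  b <- frag_levels(ids, c(0.2, 0.4, 0.9))
  # hand computation: cov = 0.28, sd products sqrt(0.32 * 0.26)
  expect_equal(pairwise_correlation(a, b), 0.28 / sqrt(0.32 * 0.26),
               tolerance = 1e-12)
  expect_equal(pairwise_correlation(a, a), 1.0)
  b_anti <- frag_levels(ids, 1 - c(0.1, 0.5, 0.9))
  expect_equal(pairwise_correlation(a, b_anti), -1.0)
  expect_error(pairwise_correlation(a[1:2], b[1:2]), "3 shared")
  flat <- frag_levels(ids, rep(0.5, 3))
  expect_error(pairwise_correlation(a, flat), "variance")
})

test_that("sample clustering merges planted blocks first", {
  set.seed(52)
  base1 <- runif(60); base2 <- runif(60)
  mat <- cbind(s1 = base1, s2 = base1 + rnorm(60, sd = 0.01),
               s3 = base2, s4 = base2 + rnorm(60, sd = 0.01))
  hc <- cluster_samples(mat)
  # first two merges join within-block pairs
  first_two <- lapply(1:2, function(i) sort(hc$labels[-hc$merge[i, ]]))
  expect_setequal(vapply(first_two, paste, character(1), collapse = "+"),
                  c("s1+s2", "s3+s4"))
  expect_true(all(diff(hc$height) >= -1e-12))  # average-linkage monotone
  # identical samples merge at height 0
  mat2 <- cbind(a = base1, b = base1, c = 1 - base1 + rnorm(60, sd = 0.2))
  hc2 <- cluster_samples(mat2)
  expect_equal(sort(hc2$labels[-hc2$merge[1, ]]), c("a", "b"))
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  # degenerate inputs
  one <- matrix(base1, ncol = 1, dimnames = list(NULL, "only"))
  expect_equal(cluster_samples(one)$labels, "only")
  bad <- cbind(s1 = base1, szero = rep(0.5, 60))
  expect_error(cluster_samples(bad), "szero")
})

test_that("the dendrogram exports as a Newick string", {
  set.seed(53)
  mat <- cbind(s1 = runif(30), s2 = runif(30), s3 = runif(30))
  nw <- dendrogram_newick(cluster_samples(mat))
  expect_match(nw, "^\\(.*\\);$")
  for (s in c("s1", "s2", "s3")) expect_match(nw, s, fixed = TRUE)
})

test_that("element distributions report medians and rank-sum p-values", {
  ids <- sprintf("f%d", 1:6)
  ann <- data.table::data.table(
    fragment_id = ids,
    gene_context = c(rep("promoter", 3), rep("intron", 3)),
    gene = "g", cgi_context = "open_sea")
  a <- frag_levels(ids, c(0.1, 0.2, 0.9, 1 / 6, 2 / 6, 3 / 6))
  b <- frag_levels(ids, c(0.1, 0.2, 0.9, 4 / 6, 5 / 6, 1.0))
  pairs <- data.frame(tissue = "a", cell = "b")
  got <- element_distributions(list(a = a, b = b), ann, pairs,
                               classes = c("promoter", "intron", "exon"))
  med <- got$medians
  expect_equal(med$median[med$class == "promoter" & med$sample == "a"], 0.2)
  expect_equal(med$n[med$class == "exon" & med$sample == "a"], 0L)
  expect_true(is.na(med$median[med$class == "exon" & med$sample == "a"]))
  tst <- got$tests
  # identical vectors: p = 1 under the tie-corrected approximation
  expect_equal(tst$p_value[tst$class == "promoter"], 1)
  # fully separated {1,2,3}/{4,5,6}-type ranking: exact two-sided p = 0.1
  expect_equal(tst$p_value[tst$class == "intron"], 0.1, tolerance = 1e-12)
  expect_true(is.na(tst$p_value[tst$class == "exon"]))
})

test_that("rank-sum p agrees with exhaustive rank enumeration for small n", {
  set.seed(54)
  for (i in 1:5) {
    v <- sample(seq(0.01, 1, by = 0.01), 9)  # distinct, so no rank ties
    x <- v[1:4]; y <- v[5:9]
    got <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    # enumerate all C(9,4) assignments of ranks to the x-group
    pooled <- c(x, y)
    r <- rank(pooled)
    w_obs <- sum(r[1:4]) - 4 * 5 / 2
    combos <- utils::combn(9, 4)
    ws <- apply(combos, 2, function(ix) sum(r[ix])) - 4 * 5 / 2
    # two-sided exact p: tables as extreme as observed in either direction
    mu <- 4 * 5 / 2
    p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
    expect_equal(got, p_exact, tolerance = 1e-9)
  }
})

test_that("the methylome matrix keeps only fragments passing in all samples", {
  ids <- sprintf("f%d", 1:4)
  a <- frag_levels(ids, c(0.1, 0.2, 0.3, 0.4))
  b <- frag_levels(ids, c(0.5, 0.6, 0.7, 0.8))
  b$passes_filter[2] <- FALSE
  m <- methylome_matrix(list(a = a, b = b))
  expect_equal(rownames(m), c("f1", "f3", "f4"))
  expect_equal(m[, "b"], c(f1 = 0.5, f3 = 0.7, f4 = 0.8))
})

test_that("the run report is internally consistent and serialisable", {
  sim <- small_sim()
  fm <- aggregate_sim(sim)
  pairs <- data.frame(tissue = c("pair1_tissue", "pair2_tissue"),
                      cell = c("pair1_cell", "pair2_cell"))
  dmfs <- list(pair1 = call_dmfs(fm$pair1_tissue, fm$pair1_cell),
               pair2 = call_dmfs(fm$pair2_tissue, fm$pair2_cell))
  common <- intersect_common(dmfs$pair1, dmfs$pair2)
  ann <- annotate_fragments(sim$art$in_window, sim$art$genes, sim$art$cgi)
  path <- tempfile(fileext = ".json")
  rep <- run_report(fm, dmfs, common, ann, pairs, path = path)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path)
  expect_equal(back$common_dmf$n, nrow(common))
  expect_equal(back$dmf$pair1$n_significant, sum(dmfs$pair1$significant))
  expect_equal(length(back$samples), 4L)
  # absent stages are marked, not fatal
  rep2 <- run_report(fm["pair1_tissue"], dmfs = NULL, common = NULL)
  expect_equal(rep2$dmf, "absent")
  expect_equal(rep2$common_dmf, "absent")
})
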