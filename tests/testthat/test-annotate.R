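# small hand-built annotation landscape:
# gene A (+): span [5000, 11000), exons [5000,6000) [8000,9000) [10000,11000)
# gene B (-): span [20000, 24000), exons [20000,21000) [23000,24000)
toy_genes <- function() {
  genes <- data.table::data.table(
    gene = c("geneA", "geneB"), contig = "chr1",
    start = c(5000L, 20000L), end = c(11000L, 24000L),
    strand = c("+", "-"))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  exons <- data.table::data.table(
    gene = c("geneA", "geneA", "geneA", "geneB", "geneB"), contig = "chr1",
    start = c(5000L, 8000L, 10000L, 20000L, 23000L),
    end = c(6000L, 9000L, 11000L, 21000L, 24000L))
  list(genes = genes, exons = exons)
}

toy_frag <- function(id, start, end) {
  data.table::data.table(contig = "chr1", start = as.integer(start),
                         end = as.integer(end), fragment_id = id,
                         length = as.integer(end - start), n_cpgs = 2L)
}

test_that("promoter windows are strand-mirrored around the TSS and clipped", {
  p <- promoter_interval(5000L, "+")
  expect_equal(c(p$start, p$end), c(3000L, 6000L))
  m <- promoter_interval(5000L, "-")
  expect_equal(c(m$start, m$end), c(4001L, 7001L))
  cl <- promoter_interval(500L, "+")
  expect_equal(c(cl$start, cl$end), c(0L, 1500L))
  # window lengths match on both strands (before clipping)
  expect_equal(p$end - p$start, m$end - m$start)
})

test_that("gene context follows the promoter > junction > exon > intron precedence", {
  gm <- toy_genes()
  frags <- rbind(
    toy_frag("in_prom_and_exon1", 5100, 5200),  # promoter wins over exon
    toy_frag("upstream_prom", 3500, 3600),
    toy_frag("junction_e2", 8950, 9050),        # exon2/intron boundary
    toy_frag("pure_exon", 8200, 8300),
    toy_frag("pure_intron", 7000, 7100),
    toy_frag("intergenic_far", 15000, 15100),   # >2 kb from any TSS
    toy_frag("minus_prom", 23500, 23600))       # inside geneB promoter
  got <- classify_gene_context(frags, gm)
  ctx <- stats::setNames(got$gene_context, got$fragment_id)
  expect_equal(ctx[["in_prom_and_exon1"]], "promoter")
  expect_equal(ctx[["upstream_prom"]], "promoter")
  expect_equal(ctx[["junction_e2"]], "junction")
  expect_equal(ctx[["pure_exon"]], "exon")
  expect_equal(ctx[["pure_intron"]], "intron")
  expect_equal(ctx[["intergenic_far"]], "intergenic")
  expect_equal(ctx[["minus_prom"]], "promoter")
  expect_equal(got$gene[got$fragment_id == "pure_exon"], "geneA")
  expect_true(is.na(got$gene[got$fragment_id == "intergenic_far"]))
})

test_that("CGI context bands partition and respect the adopted widths", {
  islands <- data.table::data.table(contig = "chr1", start = 10000L,
                                    end = 11000L)
  frags <- rbind(
    toy_frag("core", 10500, 10600),
    toy_frag("shore", 11500, 11600),     # within 2 kb downstream flank
    toy_frag("shore_up", 8200, 8300),    # within 2 kb upstream flank
    toy_frag("shelf", 13500, 13600),     # within 2-4 kb band
    toy_frag("open", 16000, 16100),
    toy_frag("core_edge", 10900, 11100)) # overlaps island and flank: core
  got <- classify_cgi_context(frags, islands)
  ctx <- stats::setNames(got$cgi_context, got$fragment_id)
  expect_equal(unname(ctx[c("core", "shore", "shore_up", "shelf", "open",
                            "core_edge")]),
               c("core", "shore", "shore", "shelf", "open_sea", "core"))
})

test_that("context categories always partition any fragment set", {
  sim <- small_sim()
  ann <- annotate_fragments(sim$art$in_window, sim$art$genes, sim$art$cgi)
  expect_equal(nrow(ann), nrow(sim$art$in_window))
  expect_true(all(ann$gene_context %in% c("promoter", "junction", "exon",
                                          "intron", "intergenic")))
  expect_true(all(ann$cgi_context %in% c("core", "shore", "shelf",
                                         "open_sea")))
  expect_equal(sum(prop.table(table(ann$gene_context))), 1)
  expect_equal(sum(prop.table(table(ann$cgi_context))), 1)
})

test_that("gene context is invariant under coordinate mirroring with strand flips", {
  gm <- toy_genes()
  frags <- rbind(toy_frag("a", 5100, 5200), toy_frag("b", 8950, 9050),
                 toy_frag("c", 7000, 7100), toy_frag("d", 15000, 15100),
                 toy_frag("e", 23500, 23600))
  L <- 30000L
  mirror_iv <- function(dt) {
    out <- data.table::copy(dt)
    s <- L - out$end; e <- L - out$start
    out$start <- s; out$end <- e
    out
  }
  gm2 <- list(genes = mirror_iv(gm$genes), exons = mirror_iv(gm$exons))
  gm2$genes$strand <- ifelse(gm$genes$strand == "+", "-", "+")
  gm2$genes$tss <- ifelse(gm2$genes$strand == "+", gm2$genes$start,
                          gm2$genes$end - 1L)
  got1 <- classify_gene_context(frags, gm)
  got2 <- classify_gene_context(mirror_iv(frags), gm2)
  m <- match(got1$fragment_id, got2$fragment_id)
  expect_equal(got1$gene_context, got2$gene_context[m])
  expect_equal(got1$gene, got2$gene[m])
})

test_that("feature overlap fractions follow interval arithmetic", {
  frags <- rbind(toy_frag("a", 0, 10), toy_frag("b", 20, 30))
  expect_equal(overlap_features(frags, frags[, .(contig, start, end)])$fraction, 1)
  feat <- data.table::data.table(contig = "chr1", start = 5L, end = 6L)
  got <- overlap_features(frags, feat)
  expect_equal(got$fraction, 0.5)
  expect_equal(got$overlaps, c(TRUE, FALSE))
  none <- data.table::data.table(contig = "chr1", start = 100L, end = 200L)
  expect_equal(overlap_features(frags, none)$fraction, 0)
})

test_that("common-DMF gene sets de-duplicate and intersect by context", {
  ann <- data.table::data.table(
    fragment_id = sprintf("f%d", 1:5),
    gene_context = c("promoter", "promoter", "intron", "exon", "intergenic"),
    gene = c("A", "A", "A", "B", NA),
    cgi_context = "open_sea")
  common <- data.table::data.table(fragment_id = sprintf("f%d", 1:5))
  gs <- genes_for_common_dmfs(common, ann)
  expect_equal(gs$promoter, "A")
  expect_equal(gs$body, c("A", "B"))
  expect_equal(gs$both, "A")
  empty <- genes_for_common_dmfs(common[0], ann)
  expect_equal(lengths(empty), c(promoter = 0L, body = 0L, both = 0L))
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  bg <- sprintf("g%d", 1:50)
  q <- bg[1:5]
  sets <- list(hit = bg[1:5], none = bg[40:45], all = bg)
  got <- enrich_gene_set(q, bg, sets)
  expect_equal(got$p_value[got$set == "hit"], 1 / choose(50, 5),
               tolerance = 1e-12)
  expect_equal(got$p_value[got$set == "all"], 1)
  # overlap 0: P(X >= 0) = 1... but here overlap can't be negative;
  # the 'none' set has expected overlap 0 and P(X >= 0) = 1
  expect_equal(got$n_overlap[got$set == "none"], 0L)
  expect_equal(got$p_value[got$set == "none"], 1)
  expect_equal(got$p_adj, stats::p.adjust(got$p_value, "BH"))

  # exhaustive check against direct enumeration for a small universe
  bg2 <- sprintf("h%d", 1:12)
  q2 <- bg2[1:4]
  set2 <- bg2[3:8]
  k_obs <- length(intersect(q2, set2))
  # enumerate all C(12,4) draws of the query positions
  draws <- utils::combn(12, 4)
  tail_p <- mean(apply(draws, 2, function(d) sum(d %in% 3:8) >= k_obs))
  got2 <- enrich_gene_set(q2, bg2, list(s = set2))
  expect_equal(got2$p_value, tail_p, tolerance = 1e-12)

  expect_error(enrich_gene_set("x", character(0), list()), "background")
  expect_error(enrich_gene_set("zz", bg, sets), "subset")
})

test_that("GMT libraries are read and used", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), p)
  bg <- sprintf("g%d", 1:10)
  got <- enrich_gene_set(c("g1", "g2"), bg, p)
  expect_setequal(got$set, c("setA", "setB"))
  expect_equal(got$n_overlap[got$set == "setA"], 2L)
})

test_that("gene models round-trip through GTF", {
  sim <- small_sim()
  dir <- file.path(tempdir(), "gtfio")
  write_simulation(sim$art, sim$pairs[1], dir)
  gm <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_setequal(gm$genes$gene, sim$art$genes$genes$gene_id)
  g0 <- sim$art$genes$genes[order(gene_id)]
  g1 <- gm$genes[order(gene)]
  expect_equal(g1$start, g0$start)
  expect_equal(g1$end, g0$end)
  expect_equal(g1$strand, g0$strand)
})
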