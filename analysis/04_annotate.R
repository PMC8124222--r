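#!/usr/bin/env Rscript
# Place fragments and common DMFs in genomic context: promoter / exon /
# intron / junction / intergenic and CGI core / shore / shelf / open sea;
# derive promoter and gene-body gene sets of the common DMFs and run a
# hypergeometric enrichment against a small synthetic gene-set library.

suppressMessages(library(rrbsdmf))

outdir <- "results"
frags <- read_fragments_bed(file.path(outdir, "fragments.bed"))
gm <- read_gene_models("results/sim/genes.gtf")
cgi <- read_bed("results/sim/cgi.bed")

ann <- annotate_fragments(frags, gm, cgi)
data.table::fwrite(ann, file.path(outdir, "annotations.tsv"), sep = "\t")

pct <- function(x) round(100 * prop.table(table(x)), 1)
cat("gene context, all analysed fragments (%):\n"); print(pct(ann$gene_context))
cat("CGI context, all analysed fragments (%):\n"); print(pct(ann$cgi_context))

common <- data.table::fread(file.path(outdir, "common_dmf.tsv"))
ann_c <- ann[ann$fragment_id %in% common$fragment_id, ]
cat("gene context, common DMFs (%):\n"); print(pct(ann_c$gene_context))
cat("CGI context, common DMFs (%):\n"); print(pct(ann_c$cgi_context))

gs <- genes_for_common_dmfs(common, ann)
cat(sprintf("promoter genes: %d; gene-body genes: %d; both contexts: %d\n",
            length(gs$promoter), length(gs$body), length(gs$both)))

# synthetic gene-set library over the simulated gene universe: one set
# spiked with DMF-promoter genes, the rest random
background <- sort(unique(ann$gene[!is.na(ann$gene)]))
set.seed(99)
lib <- list(
  spiked_promoter_set = unique(c(gs$promoter,
                                 sample(background, 5))),
  random_set_a = sample(background, 15),
  random_set_b = sample(background, 15))
query <- unique(c(gs$promoter, gs$body))
if (length(query) > 0) {
  enr <- enrich_gene_set(query, background, lib)
  data.table::fwrite(enr, file.path(outdir, "enrichment.tsv"), sep = "\t")
  cat("gene-set enrichment (hypergeometric, BH-adjusted):\n")
  print(as.data.frame(enr[, c("set", "n_set", "n_overlap", "p_value",
                              "p_adj")]))
}
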