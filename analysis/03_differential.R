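#!/usr/bin/env Rscript
# Call differentially methylated fragments (Fisher exact, Bonferroni at
# alpha 0.01, >= 25% methylation difference) per tissue/cell-line pair,
# intersect across the two pairs, and check recovery against the planted
# truth.

suppressMessages(library(rrbsdmf))

outdir <- "results"
fm <- lapply(c(pair1_tissue = "pair1_tissue", pair1_cell = "pair1_cell",
               pair2_tissue = "pair2_tissue", pair2_cell = "pair2_cell"),
             function(s) read_fragment_methylation(
               file.path(outdir, paste0(s, ".frag.tsv"))))

dmfs <- list(
  pair1 = call_dmfs(fm$pair1_tissue, fm$pair1_cell),
  pair2 = call_dmfs(fm$pair2_tissue, fm$pair2_cell))
for (nm in names(dmfs)) {
  d <- dmfs[[nm]]
  data.table::fwrite(d, file.path(outdir, paste0(nm, ".dmf.tsv")), sep = "\t")
  write_dmf_bed(d, file.path(outdir, paste0(nm, ".dmf.bed")))
  sig <- d[d$significant, ]
  cat(sprintf("%s: %d fragments tested, %d DMFs (%.1f%% hyper in cell line)\n",
              nm, nrow(d), nrow(sig),
              100 * mean(sig$direction == "hyper_in_cell_line")))
}

common <- intersect_common(dmfs$pair1, dmfs$pair2)
data.table::fwrite(common, file.path(outdir, "common_dmf.tsv"), sep = "\t")
cs <- concordance_summary(common)
cat(sprintf("common DMFs across both pairs: %d\n", nrow(common)))
print(cs)

truth <- data.table::fread("results/sim/truth.tsv")
planted <- unique(truth$fragment_id)
cat(sprintf("planted common DMFs recovered: %d / %d (%.1f%%)\n",
            sum(planted %in% common$fragment_id), length(planted),
            100 * mean(planted %in% common$fragment_id)))
fp <- sum(!common$fragment_id %in% planted)
cat(sprintf("common DMFs outside the planted set: %d\n", fp))
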