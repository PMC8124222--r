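#!/usr/bin/env Rscript
# Define the unit of analysis (in-silico MspI fragments, 40-220 bp) and
# aggregate each sample's per-CpG counts to fragment methylation levels
# under the >= 2 CpGs at >= 10 reads coverage filter.

suppressMessages(library(rrbsdmf))

simdir <- "results/sim"
outdir <- "results"
genome <- file.path(simdir, "genome.fa")

frags_all <- digest_genome(genome)
frags <- size_select(frags_all)
cpg_map <- fragment_cpgs(genome, frags)
write_fragments_bed(frags, file.path(outdir, "fragments.bed"))
cat(sprintf("digestion: %d internal fragments, %d in the 40-220 bp window\n",
            nrow(frags_all), nrow(frags)))
cat(sprintf("CpG sites in catalogue: %d (median %d per fragment)\n",
            nrow(cpg_map), as.integer(median(frags$n_cpgs))))

samples <- c(pair1_tissue = "pair1_tissue.cov", pair1_cell = "pair1_cell.cov",
             pair2_tissue = "pair2_tissue.cov", pair2_cell = "pair2_cell.cov")
for (s in names(samples)) {
  calls <- read_cpg_calls(file.path(simdir, samples[[s]]), genome)
  fm <- aggregate_fragments(frags, cpg_map, calls)
  write_fragment_methylation(fm, file.path(outdir, paste0(s, ".frag.tsv")))
  cat(sprintf("%-13s %5d fragments covered, %5d pass filter, median level %.2f\n",
              s, nrow(fm), sum(fm$passes_filter),
              median(fm$level[fm$passes_filter])))
}
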