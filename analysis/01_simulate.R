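#!/usr/bin/env Rscript
# Generate the study dataset: a toy genome whose MspI fragments mimic RRBS
# structure, and two paired tumour-tissue / cell-line samples with 200
# planted shared DMFs (methylation shift 0.5, 88% hypermethylated in the
# cell line), written as FASTA + GTF + BED + Bismark-coverage-style files.

suppressMessages(library(rrbsdmf))

outdir <- "results/sim"
cfg <- sim_config(seed = 1L)  # the standard study conditions
art <- generate_genome(cfg)
pairs <- lapply(seq_len(cfg$n_pairs), function(p) simulate_pair(art, p))
paths <- write_simulation(art, pairs, outdir)

cat("contigs:            ", length(art$seqs), "\n")
cat("internal fragments: ", nrow(art$fragments), "\n")
cat("size-selected 40-220:", nrow(art$in_window), "\n")
cat("planted DMFs/pair:  ",
    nrow(art$planted[art$planted$pair_id == 1L, ]), "\n")
truth <- data.table::fread(file.path(outdir, "truth.tsv"))
cat("planted hyper frac: ",
    round(mean(truth$direction[truth$pair_id == 1] == "hyper"), 3), "\n")
cat("written:\n"); print(unname(paths))
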