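#!/usr/bin/env Rscript
# Stage 2 — preprocess the counts and score the EMT signatures.
#
# Top-3000-gene selection, 5% minimum-expressed-gene cell filter, log(1 + x)
# transform; then per-cell epithelial and mesenchymal recovery-curve (AUC)
# scores. Writes the log-expression matrix and the per-cell scores.

library(emplex)

counts <- read_counts("results/dataset/counts.mtx")
sig_e <- read_signature("results/dataset/signature_epithelial.txt")
sig_m <- read_signature("results/dataset/signature_mesenchymal.txt")

pp <- preprocess(counts, top_n_genes = 3000, min_gene_fraction = 0.05)
cat("Kept", nrow(pp$expr), "genes and", ncol(pp$expr), "of", ncol(counts),
    "cells after filtering\n")

scores <- score_emt(pp$expr, sig_e, sig_m)
write.table(scores, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
dir.create("results/filtered", showWarnings = FALSE, recursive = TRUE)
write_counts_mtx(pp$counts, "results/filtered/counts.mtx")

truth <- read.delim("results/dataset/truth.tsv")
truth <- truth[match(scores$cell, truth$cell), ]
cat("Mean E / M score per true state:\n")
print(cbind(E = tapply(scores$E, truth$state, mean),
            M = tapply(scores$M, truth$state, mean)))
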