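#!/usr/bin/env Rscript
# Stage 1 — simulate the reference synthetic EMT dataset.
#
# Four discrete states (E, I1, I2, M) x 100 cells, the 108-gene epithelial
# and 193-gene mesenchymal programs, 200 housekeeping genes, three toy
# ligand-receptor pathways, negative-binomial counts with dropout, and a
# four-point sampling time course. Everything downstream reads the files
# written here.

library(emplex)

out <- "results/dataset"
cfg <- sim_config(seed = 101)
ds <- generate_emt_dataset(cfg)
write_emt_dataset(ds, out)

cat("Simulated", nrow(ds$counts), "genes x", ncol(ds$counts), "cells into",
    out, "\n")
cat("State sizes:\n")
print(table(ds$counts$cell_meta$state))
cat("Time-point composition of each state:\n")
print(fraction_table(ds$true_time, ds$counts$cell_meta$state))
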