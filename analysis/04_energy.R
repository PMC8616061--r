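#!/usr/bin/env Rscript
# Stage 4 — transcriptional diversity, whole-transcriptome single-cell
# energy and the EMT circuit energy, compared across the trajectory.
#
# The energies use the correlation-thresholded gene network (tau = 0.4); the
# EMT circuit energy restricts the network to the epithelial + mesenchymal
# signature genes, so it peaks where both programs are co-expressed.

library(emplex)

counts <- read_counts("results/filtered/counts.mtx")
pp <- preprocess(counts, top_n_genes = 3000, min_gene_fraction = 0.05)
sig_e <- read_signature("results/dataset/signature_epithelial.txt")
sig_m <- read_signature("results/dataset/signature_mesenchymal.txt")
cl <- read.delim("results/clusters.tsv")
traj <- jsonlite::read_json("results/trajectory.json", simplifyVector = TRUE)

diversity <- transcriptional_diversity(pp$counts)
net <- build_gene_network(pp$expr, tau = 0.4)
energy <- single_cell_energy(pp$expr, net)
emt_energy <- emt_circuit_energy(pp$expr, sig_e, sig_m, tau = 0.4)

tab <- data.frame(cell = colnames(pp$expr), diversity = diversity,
                  energy = energy, emt_energy = emt_energy,
                  cluster = cl$cluster[match(colnames(pp$expr), cl$cell)])
write.table(tab, "results/energies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ord <- traj$order
cat("Per-cluster means along the trajectory", paste(ord, collapse = " -> "),
    ":\n")
print(do.call(rbind, lapply(ord, function(k) data.frame(
  cluster = k,
  diversity = mean(tab$diversity[tab$cluster == k]),
  energy = mean(tab$energy[tab$cluster == k]),
  emt_energy = mean(tab$emt_energy[tab$cluster == k])))), digits = 4)

tests <- compare_along_trajectory(tab$emt_energy, tab$cluster, ord)
cat("Consecutive-cluster one-tailed t-tests on EMT circuit energy:\n")
print(tests, digits = 3)
write.table(tests, "results/energy_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
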