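#!/usr/bin/env Rscript
# Stage 6 — descriptive reporting: time-course composition, marker-style
# composition of clusters, and the star-annotated cluster comparisons.

library(emplex)

counts <- read_counts("results/filtered/counts.mtx")
truth <- read.delim("results/dataset/truth.tsv")
cl <- read.delim("results/clusters.tsv")
en <- read.delim("results/energies.tsv")
traj <- jsonlite::read_json("results/trajectory.json", simplifyVector = TRUE)

truth <- truth[match(cell_names(counts), truth$cell), ]

cat("Fraction of true states at each time point:\n")
ft <- fraction_table(truth$state, truth$time_point)
print(round(ft, 3))
write.table(data.frame(time_point = rownames(ft), ft, check.names = FALSE),
            "results/timecourse_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# marker-combination composition using the toy receptor genes as markers
markers <- grep("_REC1$", gene_names(counts), value = TRUE)
if (length(markers) >= 2) {
  comp <- marker_composition(counts, cl$cluster, markers)
  cat("Cluster composition over", length(markers),
      "receptor markers (first columns):\n")
  print(round(comp[, seq_len(min(4, ncol(comp)))], 3))
  write.table(data.frame(cluster = rownames(comp), comp, check.names = FALSE),
              "results/marker_composition.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}

cat("All-pairs one-tailed t-tests on developmental energy:\n")
print(compare_along_trajectory(en$energy, en$cluster, traj$order,
                               mode = "all_pairs"), digits = 3)
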