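# emplex

Integrated single-cell analysis of epithelial–mesenchymal transition (EMT)
progression: signature scoring, consensus clustering and trajectory
inference, plasticity energies, and cluster-level ligand–receptor
communication — with a ground-truth synthetic data generator that makes
every stage testable offline.

## Who this is for

Computational biologists studying EMT (or any ordered cell-state
transition) in scRNA-seq data who want, from one raw gene × cell count
matrix:

- per-cell **epithelial and mesenchymal scores** from curated gene
  signatures (108 downregulated / 193 upregulated genes by convention);
- data-driven **cluster number and trajectory**, anchored at the most
  epithelial cluster, with transition-cell evidence and pseudotime;
- **stemness/plasticity measures**: transcriptional diversity, a
  correlation-network single-cell energy, and an **EMT circuit energy**
  restricted to the signature genes, which peaks where both programs are
  co-expressed (hybrid E/M states);
- **cell–cell communication**: Hill-transformed ligand × receptor
  cluster probabilities, permutation significance, incoming/outgoing
  strengths and sender/receiver/mediator/influencer roles, information
  flow across conditions.

## The core quantities

For a cell with expression ranks, the signature score is a normalized
recovery-curve AUC over the top-*k* ranked genes,
`AUC = Σᵢ R(i) / Σᵢ min(i, |sig|) ∈ [0, 1]` with
`R(i) = |sig ∩ top-i|`. The cluster count maximizes the eigengap
`λₖ − λₖ₊₁` of the consensus similarity spectrum (floor of 3 to allow an
intermediate state). With per-gene max-normalized expression
`z ∈ [0, 1]` and a gene network thresholded at `|cor| ≥ τ = 0.4`, the
single-cell energy is `E_c = Σᵢ −z_ic · ln(z_ic / Σ_{j∈N(i)} z_jc)`; the
EMT circuit energy is the same computation restricted to the E ∪ M
signature genes. Communication probability between sender *a* and
receiver *b* is `L_a·R_b / (K_h + L_a·R_b)` with geometric-mean subunit
aggregation and `K_h = 0.5`.

See `vignettes/emt-plasticity-methods.Rmd` for assumptions, parameter
defaults, and the design decisions behind each stage.

## Worked example

```r
library(emplex)

res <- run_emt_pipeline(sim_config(seed = 101), n_runs = 50,
                        nperm = 100, seed = 101)
res$summary
```

On the default four-state synthetic dataset (E → I1 → I2 → M, 100 cells
per state) this prints:

```
  position cluster n_cells E_mean M_mean diversity_mean energy_mean emt_energy_mean
1        0       4     100  0.849  0.310            283        2.66            2.66
2        1       3     100  0.772  0.453            347       24.25           24.23
3        2       2     100  0.673  0.603            370       51.92           51.97
4        3       1     100  0.573  0.707            373       75.88           75.70
```

Reading it: the eigengap selected four clusters; each recovered cluster
maps one-to-one onto a true state (E score falls 0.85 → 0.57 along the
trajectory while M rises 0.31 → 0.71); transcriptional diversity and both
energies increase monotonically toward the mesenchymal end — the EMT
circuit energy rises ~28-fold because late states co-express both
programs. Consecutive-cluster one-tailed Welch t-tests on the circuit
energy (`res$energy_tests`) are all `***` (p < 0.001).

The same computations are available stage by stage
(`preprocess()`, `score_emt()`, `build_consensus()` → `select_k()` →
`soft_cluster()` → `infer_trajectory()`, `emt_circuit_energy()`,
`permutation_significance()` → `interaction_strengths()`), and the
`analysis/` directory holds a numbered six-stage workflow
(`01_simulate.R` … `06_report.R`) that writes every table under
`results/`.

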