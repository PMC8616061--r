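---
title: "Quantifying EMT progression, plasticity energy and cell-cell signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMT progression, plasticity energy and cell-cell signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emplex)
```

## Scope and model

The epithelial-mesenchymal transition (EMT) is rarely a switch between two
phenotypes: single-cell RNA-seq of carcinoma and mammary models repeatedly
shows ordered intermediate states in which epithelial and mesenchymal gene
programs are co-expressed. `emplex` implements an integrated analysis of
this process from a raw gene x cell count matrix:

1. **Preprocessing** — top-expressed-gene selection, a minimum
   expressed-gene cell filter, and a `log(pseudocount + count)` transform.
2. **Signature scoring** — per-cell epithelial (E) and mesenchymal (M)
   scores from a recovery-curve AUC over the within-cell expression
   ranking.
3. **Consensus clustering and trajectory** — a k-means ensemble similarity
   matrix, eigengap selection of the cluster number (floored at 3), soft
   memberships by symmetric NMF, transition-cell flagging, and a trajectory
   anchored at the most epithelial cluster.
4. **Plasticity energies** — transcriptional diversity, a
   correlation-network single-cell energy over all genes, and the same
   energy restricted to the E + M signature genes (the *EMT circuit
   energy*).
5. **Cell-cell communication** — cluster-level ligand-receptor
   probabilities with a permutation null, incoming/outgoing strengths,
   signaling roles, and cross-condition information flow.
6. **Reporting** — one-tailed Welch t-tests with star annotation,
   time-course composition tables, marker-combination composition.

A negative-binomial simulator with full ground truth (`sim_config()`,
`generate_emt_dataset()`) generates the data on which every claim in the
test suite is validated.

## The synthetic data and what it does (not) emulate

The simulator draws discrete cell states ordered along an EMT axis
(default 4: E, I1, I2, M; 100 cells each). Each gene belongs to one program
(epithelial, mesenchymal, housekeeping, or ligand/receptor) and is sampled
from a negative binomial with a state-specific program mean, a fixed
per-gene factor in [0.7, 1.3], dispersion `size = 2`, followed by
independent dropout with probability 0.2 — the standard noise model for
droplet scRNA-seq counts at moderate depth.

The default program means encode the asymmetry that defines hybrid E/M
biology: along E to M the mesenchymal mean rises twenty-fold
(0.5 to 10) while the epithelial mean only halves (10 to 5), so terminal
states still co-express the epithelial program at 50% of its starting
level. This co-expression is what makes the EMT circuit energy rise along
the trajectory; it is a documented default of
`default_program_means()`, not a hard-wired assumption. Ligand/receptor
genes take state-specific means from the `lr_design` table — either one
designated sender/receiver state per pathway (`default_lr_design()`), or
per-state ramps tying expression to the state index
(`lr_design_gradient()`). A time-point label per cell is drawn from a
time-course mixture over states, emulating an induction experiment.

Deliberately **not** emulated: transcriptome-wide correlation structure
beyond the program blocks, batch effects, doublets, library-size gradients
confounded with state, and continuous (as opposed to discrete) state
occupancy. Passing tests on these data therefore demonstrate that each
method recovers the structure it claims to recover under its own noise
assumptions — not that it is robust to every artifact of real data.
Because states are discrete and well separated, simulated transition cells
are rare; the consequences for trajectory inference are discussed below.

## Signature scoring

For each cell, all genes are ranked by expression descending; ties are
broken by gene name ascending so results are identical across platforms
(a random tie-break would make exact regression tests impossible). With
recovery curve $R(i) = |\mathrm{sig} \cap \mathrm{top}\,i|$, the score is

$$\mathrm{AUC} = \frac{\sum_{i=1}^{k} R(i)}{\sum_{i=1}^{k} \min(i, |\mathrm{sig}|)} \in [0, 1],$$

with $k$ = `top_k`, the only free parameter (defaults to all genes; large
windows such as 5000-7000 genes are appropriate for deeply sequenced
datasets). The score depends only on within-cell ranks, so scoring the
log-transformed or the raw matrix is equivalent; we score the log matrix
for convenience. Signature genes absent from the matrix are dropped and
the normalizer uses the retained signature size, so a partially measured
signature can still reach 1. The canonical EMT signature sizes — 108
epithelial (downregulated) and 193 mesenchymal (upregulated) genes — are
the simulator's defaults.

## Preprocessing choices

The cell filter threshold is `ceiling(min_gene_fraction * panel size)`
expressed genes. Two conventions exist for the panel: the kept (top-N)
genes or the full pre-selection panel; both are implemented
(`filter_on = "kept"` is the default) because published cell counts can
depend on the choice. Ties at the top-N boundary are broken by gene name
so the kept panel is deterministic. The natural log is used throughout;
with the default pseudocount of 1 a zero count maps to exactly 0.

## Consensus clustering, model selection, soft membership

The cell-cell similarity is the co-clustering frequency over `n_runs`
(default 50) k-means runs, sweeping the number of principal components
(5, 10, 15) and the cluster count (3-6). Two implementation details make
the whole ensemble invariant to cell order, which the test suite checks
exactly: principal-component signs are canonicalized (the largest-|loading|
gene is made positive), and each run's initial centers are the cells at
quantiles of a seeded random projection of the embedding — a value-based,
not index-based, initialization.

The cluster number is the $k \in [k_{\min}, k_{\max}]$ maximizing the
eigengap $\lambda_k - \lambda_{k+1}$ of the similarity matrix (eigenvalues
descending; gaps within $10^{-9}$ are treated as tied and resolve to the
smallest k). The floor $k_{\min} = 3$ guarantees at least one candidate
intermediate state. The eigengap is computed on the similarity matrix
itself rather than a graph Laplacian; for near-block-constant consensus
matrices the two are equivalent, and the similarity spectrum has the
convenient property that a perfect k-block matrix has exactly k nonzero
eigenvalues.

Soft memberships minimize $\|S - HH^\top\|_F^2$ over $H \ge 0$ by
multiplicative updates from seeded random starts. Convergence is declared
when the relative objective change drops below $10^{-6}$ — or when the
objective falls below $10^{-6}\,\|S\|_F^2$, since the relative criterion
can never trigger when the optimum is exactly zero (perfect blocks). Five
restarts are run and the best objective kept, the standard guard against
the local minima of symmetric NMF; without it roughly one run in seven on
default synthetic data settles in a merged/split optimum and drops the
adjusted Rand index below 0.8. Rows of $H$ are normalized to sum to one;
a cell is a *transition cell* when its top-two membership gap is below
`delta` (default 0.1, configurable — the choice only affects which cells
weight the trajectory edges). Factor components that attract no
hard-assigned cell are dropped (with `k` reduced accordingly) before
trajectory inference.

## Trajectory inference and pseudotime

The start is the cluster with the best rank-sum of (highest E score,
lowest M score); an exact tie is an error that lists the tied clusters, so
the caller can test each candidate start explicitly. Edges between
clusters count the transition cells whose two largest memberships are that
pair; the trajectory is the maximum-weight simple path from the start
(exhaustive enumeration up to k = 6, greedy beyond; alternative maximal
paths are returned in descending weight order). Clusters that
positive-weight edges cannot reach — in particular *all* non-start
clusters when the data contain no transition cells, as happens with
well-separated discrete simulated states — are appended in order of their
EMT axis position ($\bar M - \bar E$ ascending), keeping the recovered
order biologically anchored rather than arbitrary.

Pseudotime places a cell at its hard cluster's path position, shifted by
$h_b / (h_a + h_b)$ toward the adjacent cluster $b$ with which it shares
the most membership. The shift is signed — forward when $b$ lies later on
the path, backward when earlier — which keeps pseudotime inside
$[0, k - 1]$ and nondecreasing along the path; an unsigned shift would
push cells of the terminal cluster beyond the end of the trajectory.

## Plasticity energies

Transcriptional diversity is the number of genes with at least one raw
count, computed on the unnormalized matrix by definition. The gene network
connects genes with $|\mathrm{cor}| \ge \tau$ across all cells (Pearson on
log expression by default, Spearman available); $\tau = 0.4$ is the
conventional default and results depend on it only weakly. With per-gene
max-normalized expression $z \in [0,1]$, the energy of cell $c$ is

$$E_c = \sum_{i:\, z_{ic} > 0,\ N(i) \ne \emptyset} -z_{ic}
\ln\!\frac{z_{ic}}{\sum_{j \in N(i)} z_{jc}},$$

with a term set to 0 when its neighbor sum vanishes. The form is
entropy-like: zero for silent cells, driven by network neighbors, and
maximized when many connected genes are simultaneously high. It is one
concrete choice among several that share these properties (e.g. sums of
neighbor products); it is isolated behind `single_cell_energy()` so the
functional form can be swapped, and every validated property of the
energies is ordinal, not tied to particular values. The EMT circuit energy
is the same computation after restricting the matrix (and rebuilding the
network) on the union of the E and M signatures — by construction it uses
no information outside the signature genes, which a test checks
bit-exactly — and is maximal where both programs are co-expressed, i.e. in
high-plasticity hybrid states.

## Cell-cell communication

Counts are library-size normalized per cell to the median library size and
log1p-transformed. For a ligand-receptor pair, the cluster-level ligand
level $L_a$ is the geometric mean over ligand subunits of the cluster-mean
expression (one absent subunit nullifies the complex), $R_b$ likewise, and

$$P_{ab} = \frac{L_a R_b}{K_h + L_a R_b}, \qquad K_h = 0.5$$

on the normalized-log scale — a saturating Hill response, monotone in both
factors and bounded by 1. The arithmetic cluster mean replaces more ornate
summaries (trimeans, cofactor corrections) because every downstream claim
validated here is ordinal. Significance comes from `nperm` (default 100)
global label permutations with the add-one estimate
$p = (1 + \#\{P^{\mathrm{perm}} \ge P\}) / (1 + n_{\mathrm{perm}})$, which
is exactly calibrated under exchangeability. Strengths sum significant
probabilities ($p < \alpha$, default 0.05) over receivers (outgoing) or
senders (incoming); per pathway, clusters are scored as sender (row sums),
receiver (column sums), influencer (their total) and mediator — the flow
betweenness of the cluster in the pathway's weighted digraph, computed as
the total max-flow between other cluster pairs lost when the cluster is
removed. Information flow per pathway is the sum of significant
probabilities, compared across conditions in absolute and relative terms
with condition-exclusive pathways flagged.

One consequence of significance filtering matters for interpretation:
strengths are censored at zero, so along a trajectory whose early states
signal weakly, the first positions can tie at exactly 0. "Strength
increases along the trajectory" is therefore validated as *nondecreasing
with a strict overall gain*, which is the claim actually supported by
censored quantities.

## Statistics

Group comparisons use the Welch (unequal-variance) t-test, one-tailed,
with the star convention `***` p < 0.001, `**` p < 0.01, `*` p < 0.1,
`ns` otherwise; boundary p-values take the weaker annotation. Both
consecutive-pair (along a trajectory; the alternative defaults to "later
cluster greater") and all-pairs modes are provided, since both appear in
practice. No multiple-testing correction is applied — the stars annotate
raw p-values, matching common reporting. Marker composition binarizes each
marker at count > threshold (default 0, i.e. any detection is "high", a
dropout-tolerant cut) and reports per-cluster fractions over all
high/low combinations.

## Problem sizes and determinism

The validation suite runs the full pipeline on 4 x 100-cell datasets
(507 genes), 20 seeds per multi-seed property, 100 permutations per
communication run, and 50 null simulations for p-value calibration; these
sizes give stable rates (binomial s.e. about 7% at 20 seeds) while keeping
a complete run in minutes on one core. Every stochastic stage takes an
explicit integer seed and restores the caller's RNG state; fixed seeds
give bit-identical outputs, which the suite asserts end to end.

## Known limitations

- The energy's functional form is a reasoned choice, not a measured one;
  conclusions should rely on its ordinal behavior.
- The trajectory is a single dominant path; branching topologies are only
  visible through the returned alternative paths.
- Transition-cell edges need soft cluster overlap: on data with crisply
  separated states the EMT-axis fallback, not transition evidence, orders
  the path.
- The communication model ignores spatial proximity, cofactors and
  agonist/antagonist modulation; probabilities are comparable within a
  run, not across databases.
- The simulator's discrete states cannot probe continuous-trajectory
  artifacts (e.g. pseudotime compression) or batch structure.
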