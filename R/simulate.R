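#' Configuration for the synthetic EMT single-cell simulator
#'
#' Describes a population of discrete cell states ordered along an EMT axis.
#' Each state expresses an epithelial program, a mesenchymal program and a
#' housekeeping program with state-specific negative-binomial means; counts
#' are additionally zeroed by independent dropout. The defaults encode the
#' canonical EMT time-course geometry: the mesenchymal program rises strongly
#' along the state order while the epithelial program decays only mildly, so
#' late states co-express both programs (hybrid E/M plasticity). State-specific
#' ligand/receptor genes and a time-point mixture over states complete the
#' ground truth needed to validate trajectory, energy and communication
#' analyses.
#'
#' @param n_states Number of ordered EMT states (default 4: E, I1, I2, M).
#' @param state_labels Labels for the states, ordered epithelial to
#'   mesenchymal.
#' @param cells_per_state Integer vector (length `n_states`) of cells drawn
#'   per state.
#' @param n_epithelial_genes,n_mesenchymal_genes,n_housekeeping_genes Sizes
#'   of the three gene programs. Defaults follow the 108-gene epithelial /
#'   193-gene mesenchymal EMT signature convention.
#' @param program_means `n_states x 3` matrix of negative-binomial mean
#'   expression for the (epithelial, mesenchymal, housekeeping) programs in
#'   each state. The default keeps the terminal-state epithelial mean at 50%
#'   of its E-state value (hybrid co-expression) while the mesenchymal mean
#'   rises 20-fold.
#' @param nb_dispersion Negative-binomial size (dispersion) parameter; smaller
#'   is noisier.
#' @param dropout_prob Probability that any observed count is zeroed
#'   independently (dropout).
#' @param lr_design Ligand-receptor design `data.frame` with columns
#'   `pathway`, `sender_state`, `receiver_state`, `ligand_level`,
#'   `receptor_level`. Levels may be scalars (the named sender/receiver state
#'   gets the level, all other states a baseline of `lr_baseline`) or, via
#'   list columns, length-`n_states` vectors of per-state means (see
#'   [lr_design_gradient()]).
#' @param lr_baseline Baseline ligand/receptor mean in non-designated states.
#' @param timecourse_mix Time-point x state matrix of state fractions (rows
#'   sum to 1) describing a sampling time course; cells of state s are
#'   assigned time point t with probability proportional to
#'   `timecourse_mix[t, s]`.
#' @param seed Integer seed; the simulator is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @seealso [generate_emt_dataset()], [generate_lr_database()]
#' @export
sim_config <- function(n_states = 4,
                       state_labels = c("E", "I1", "I2", "M"),
                       cells_per_state = rep(100L, n_states),
                       n_epithelial_genes = 108,
                       n_mesenchymal_genes = 193,
                       n_housekeeping_genes = 200,
                       program_means = default_program_means(n_states),
                       nb_dispersion = 2,
                       dropout_prob = 0.2,
                       lr_design = default_lr_design(state_labels),
                       lr_baseline = 0.5,
                       timecourse_mix = default_timecourse_mix(n_states),
                       seed = 1L) {
  if (length(state_labels) != n_states)
    stop("state_labels length must equal n_states")
  if (length(cells_per_state) != n_states)
    stop("cells_per_state length must equal n_states")
  if (!is.matrix(program_means) || nrow(program_means) != n_states ||
      ncol(program_means) != 3)
    stop("program_means must be an n_states x 3 matrix")
  if (any(program_means < 0)) stop("program means must be nonnegative")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must be in [0, 1]")
  if (!is.matrix(timecourse_mix) || ncol(timecourse_mix) != n_states)
    stop("timecourse_mix must have one column per state")
  if (any(abs(rowSums(timecourse_mix) - 1) > 1e-9))
    stop("rows of timecourse_mix must sum to 1")
  if (!is.null(lr_design)) {
    req <- c("pathway", "sender_state", "receiver_state",
             "ligand_level", "receptor_level")
    if (!all(req %in% names(lr_design)))
      stop("lr_design must have columns ", paste(req, collapse = ", "))
    bad <- setdiff(c(lr_design$sender_state, lr_design$receiver_state),
                   state_labels)
    if (length(bad))
      stop("lr_design references unknown states: ", paste(bad, collapse = ", "))
  }
  structure(list(
    n_states = as.integer(n_states), state_labels = state_labels,
    cells_per_state = as.integer(cells_per_state),
    n_epithelial_genes = as.integer(n_epithelial_genes),
    n_mesenchymal_genes = as.integer(n_mesenchymal_genes),
    n_housekeeping_genes = as.integer(n_housekeeping_genes),
    program_means = program_means, nb_dispersion = nb_dispersion,
    dropout_prob = dropout_prob, lr_design = lr_design,
    lr_baseline = lr_baseline, timecourse_mix = timecourse_mix,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default state-by-program mean expression
#'
#' Mesenchymal means rise strongly (0.5 to 10) while epithelial means fall
#' slowly (10 to 5, i.e. the terminal state retains 50% of the epithelial
#' program), so terminal states co-express both programs.
#'
#' @param n_states Number of states; means are interpolated for
#'   `n_states != 4`.
#' @return `n_states x 3` matrix with columns epithelial, mesenchymal,
#'   housekeeping.
#' @export
default_program_means <- function(n_states = 4) {
  s <- seq(0, 1, length.out = n_states)
  cbind(epithelial = 10 - 5 * s,
        mesenchymal = 0.5 + 9.5 * s^1.5,
        housekeeping = rep(4, n_states))
}

#' Default ligand-receptor design: three toy pathways
#'
#' `NotchToy` and `WntToy` are sent most strongly by the late-intermediate
#' state and `TgfbToy` by the terminal state, mirroring intermediate-state
#' signaling peaks.
#'
#' @param state_labels Ordered state labels.
#' @return Design `data.frame` for [sim_config()].
#' @export
default_lr_design <- function(state_labels = c("E", "I1", "I2", "M")) {
  n <- length(state_labels)
  i2 <- state_labels[max(1, n - 1)]
  m <- state_labels[n]
  e <- state_labels[1]
  data.frame(
    pathway = c("NotchToy", "WntToy", "TgfbToy"),
    sender_state = c(i2, i2, m),
    receiver_state = c(m, state_labels[min(2, n)], e),
    ligand_level = c(10, 8, 6),
    receptor_level = c(10, 8, 6),
    stringsAsFactors = FALSE)
}

#' Ligand-receptor design with levels increasing along the state order
#'
#' Ties both ligand and receptor means to the state index (geometric ramp
#' from `base` up to `base * fold`), so both outgoing and incoming
#' communication strengths should rise along the EMT trajectory.
#'
#' @param state_labels Ordered state labels.
#' @param pathways Pathway names.
#' @param base Mean in the first state.
#' @param fold Fold increase from first to last state.
#' @return Design `data.frame` with per-state level vectors (list columns).
#' @export
lr_design_gradient <- function(state_labels = c("E", "I1", "I2", "M"),
                               pathways = c("NotchToy", "WntToy", "TgfbToy"),
                               base = 1, fold = 8) {
  n <- length(state_labels)
  ramp <- base * fold^(seq(0, 1, length.out = n))
  d <- data.frame(pathway = pathways,
                  sender_state = state_labels[n],
                  receiver_state = state_labels[n],
                  stringsAsFactors = FALSE)
  d$ligand_level <- replicate(length(pathways), ramp, simplify = FALSE)
  d$receptor_level <- replicate(length(pathways), ramp, simplify = FALSE)
  d
}

#' Default time-course mixture over states
#'
#' Four sampling time points that shift mass from the epithelial end to the
#' mesenchymal end, as in an induction time course.
#'
#' @param n_states Number of states.
#' @return Time-point x state fraction matrix, rows summing to 1.
#' @export
default_timecourse_mix <- function(n_states = 4) {
  if (n_states == 4) {
    m <- rbind(t0 = c(0.85, 0.10, 0.04, 0.01),
               t1 = c(0.45, 0.35, 0.15, 0.05),
               t2 = c(0.15, 0.30, 0.35, 0.20),
               t3 = c(0.05, 0.10, 0.25, 0.60))
  } else {
    # geometric shift of mass along the state axis
    m <- t(sapply(seq_len(4), function(t) {
      w <- stats::dnorm(seq_len(n_states), mean = 1 + (n_states - 1) * (t - 1) / 3,
                        sd = n_states / 4)
      w / sum(w)
    }))
    rownames(m) <- paste0("t", seq_len(4) - 1)
  }
  colnames(m) <- paste0("state", seq_len(n_states))
  m
}

# Per-gene x per-state NB mean matrix for the ligand/receptor genes.
lr_gene_means <- function(config) {
  d <- config$lr_design
  if (is.null(d) || nrow(d) == 0) return(NULL)
  if (anyDuplicated(d$pathway)) stop("duplicate pathway names in lr_design")
  n <- config$n_states
  level_vec <- function(level, state) {
    if (length(level[[1]]) == n) return(as.numeric(level[[1]]))
    v <- rep(config$lr_baseline, n)
    v[match(state, config$state_labels)] <- as.numeric(level[[1]])
    v
  }
  means <- list()
  for (i in seq_len(nrow(d))) {
    lig <- level_vec(d$ligand_level[i], d$sender_state[i])
    rec <- level_vec(d$receptor_level[i], d$receiver_state[i])
    means[[paste0(d$pathway[i], "_LIG1")]] <- lig
    means[[paste0(d$pathway[i], "_REC1")]] <- rec
  }
  out <- do.call(rbind, means)
  colnames(out) <- config$state_labels
  out
}

#' Generate the toy ligand-receptor database implied by a simulation design
#'
#' One ligand gene and one receptor gene per pathway, named
#' `<pathway>_LIG1` / `<pathway>_REC1`; these genes are part of the simulated
#' gene panel with the state-specific means given in `lr_design`.
#'
#' @param config A [sim_config()].
#' @return An `lr_database`: `data.frame` with columns `pathway`, `ligand`
#'   and `receptor` (comma-joined subunit gene names).
#' @export
generate_lr_database <- function(config) {
  d <- config$lr_design
  if (is.null(d) || nrow(d) == 0) stop("lr_design is empty")
  if (anyDuplicated(d$pathway)) stop("duplicate pathway names in lr_design")
  lr_database(data.frame(pathway = d$pathway,
                         ligand = paste0(d$pathway, "_LIG1"),
                         receptor = paste0(d$pathway, "_REC1"),
                         stringsAsFactors = FALSE))
}

#' Simulate an EMT single-cell dataset with full ground truth
#'
#' Draws gene-wise negative-binomial counts for every cell given its state's
#' program means (each gene carries a fixed multiplicative factor in
#' [0.7, 1.3] so genes within a program differ), then zeroes entries
#' independently with the dropout probability. Ligand/receptor genes from the
#' design are appended to the panel. Cells receive a time-point label drawn
#' from the time-course mixture conditioned on their state.
#'
#' @param config A [sim_config()].
#' @return A list of class `emt_dataset` with elements `counts`
#'   (a [count_matrix()] whose `cell_meta` carries `state`, `state_index`,
#'   `time_point`), `true_state` (integer index, 1-based), `true_time`,
#'   `signatures` (list of `epithelial` and `mesenchymal` gene vectors) and
#'   `lr_db` (the [generate_lr_database()] result, or `NULL`).
#' @examples
#' cfg <- sim_config(cells_per_state = rep(30L, 4), seed = 7)
#' ds <- generate_emt_dataset(cfg)
#' dim(ds$counts)
#' @export
generate_emt_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lab <- config$state_labels
    genes <- c(sprintf("EGENE_%d", seq_len(config$n_epithelial_genes)),
               sprintf("MGENE_%d", seq_len(config$n_mesenchymal_genes)),
               sprintf("HKGENE_%d", seq_len(config$n_housekeeping_genes)))
    program <- rep(1:3, c(config$n_epithelial_genes,
                          config$n_mesenchymal_genes,
                          config$n_housekeeping_genes))
    sig_e <- genes[program == 1]
    sig_m <- genes[program == 2]
    # genes x states designed means, with fixed per-gene variability
    gene_factor <- stats::runif(length(genes), 0.7, 1.3)
    mean_mat <- t(config$program_means)[program, , drop = FALSE] * gene_factor
    lrm <- lr_gene_means(config)
    if (!is.null(lrm)) {
      genes <- c(genes, rownames(lrm))
      mean_mat <- rbind(mean_mat, lrm)
    }
    rownames(mean_mat) <- genes

    true_state <- rep(seq_len(config$n_states), config$cells_per_state)
    n_cells <- length(true_state)
    counts <- matrix(0, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, sprintf("CELL_%d", seq_len(n_cells))))
    for (s in seq_len(config$n_states)) {
      idx <- which(true_state == s)
      mu <- mean_mat[, s]
      counts[, idx] <- stats::rnbinom(length(genes) * length(idx),
                                      mu = mu, size = config$nb_dispersion)
    }
    if (config$dropout_prob > 0) {
      keep <- stats::runif(length(counts)) >= config$dropout_prob
      counts <- counts * keep
    }

    # time point | state: column s of the mixture, normalized over time points
    tp_names <- rownames(config$timecourse_mix) %||%
      paste0("t", seq_len(nrow(config$timecourse_mix)) - 1)
    true_time <- vapply(true_state, function(s) {
      w <- config$timecourse_mix[, s]
      sample(tp_names, 1, prob = w / sum(w))
    }, character(1))

    meta <- data.frame(state = lab[true_state],
                       state_index = true_state,
                       time_point = true_time,
                       stringsAsFactors = FALSE)
    db <- if (!is.null(config$lr_design) && nrow(config$lr_design) > 0)
      generate_lr_database(config) else NULL
    structure(list(
      counts = count_matrix(counts, cell_meta = meta),
      true_state = true_state,
      true_time = true_time,
      signatures = list(epithelial = sig_e, mesenchymal = sig_m),
      lr_db = db,
      config = config), class = "emt_dataset")
  })
}

#' @export
print.emt_dataset <- function(x, ...) {
  cat(sprintf("<emt_dataset> %d genes x %d cells, %d states (%s)\n",
              nrow(x$counts), ncol(x$counts), x$config$n_states,
              paste(x$config$state_labels, collapse = " -> ")))
  invisible(x)
}

#' Write a simulated dataset to disk in exchange formats
#'
#' Counts as MatrixMarket triplet MTX with `genes.tsv` / `barcodes.tsv`
#' sidecars, signatures as one-gene-per-line text files, the
#' ligand-receptor table as TSV, and the ground truth (state, time point)
#' as `truth.tsv`.
#'
#' @param dataset An `emt_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_emt_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(dataset$counts, file.path(dir, "counts.mtx"))
  write_signature(dataset$signatures$epithelial,
                  file.path(dir, "signature_epithelial.txt"))
  write_signature(dataset$signatures$mesenchymal,
                  file.path(dir, "signature_mesenchymal.txt"))
  if (!is.null(dataset$lr_db))
    write_lr_database(dataset$lr_db, file.path(dir, "lr_database.tsv"))
  truth <- data.frame(cell = cell_names(dataset$counts),
                      state = dataset$counts$cell_meta$state,
                      state_index = dataset$true_state,
                      time_point = dataset$true_time)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
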