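#' One-tailed Welch t-test with star annotation
#'
#' Welch (unequal-variance) two-sample t-test with a one-sided alternative,
#' annotated with the conventional stars: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.1, `ns` otherwise (strict inequalities, so a p
#' exactly at a threshold gets the weaker annotation).
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param alternative `"b_greater"` (default) tests whether `b` has the
#'   larger mean; `"a_greater"` the reverse.
#' @return A list of class `group_comparison`: `statistic` (Welch t),
#'   `pvalue`, `direction`, `stars`.
#' @examples
#' one_tailed_ttest(rnorm(20), rnorm(20, 2))
#' @export
one_tailed_ttest <- function(a, b, alternative = c("b_greater", "a_greater")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    stop("both samples must have at least 2 observations")
  ht <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = if (alternative == "b_greater") "less"
                      else "greater")
  structure(list(statistic = unname(ht$statistic),
                 pvalue = ht$p.value,
                 direction = alternative,
                 stars = p_stars(ht$p.value)),
            class = "group_comparison")
}

#' Map a p-value to its star annotation
#'
#' @param p P-value in [0, 1].
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.1) or
#'   `"ns"`.
#' @export
p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.1) "*" else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch one-tailed t-test (%s): t = %.3f, p = %.3g  %s\n",
              x$direction, x$statistic, x$pvalue, x$stars))
  invisible(x)
}

#' Fraction of each category within each group
#'
#' E.g. the fraction of E/I1/I2/M cells at each sampling time point. Rows
#' (groups) sum to 1; empty groups are dropped with a warning.
#'
#' @param labels Per-cell category labels.
#' @param grouping Per-cell group labels (same length).
#' @return Matrix of fractions, groups x categories.
#' @export
fraction_table <- function(labels, grouping) {
  if (length(labels) != length(grouping))
    stop("labels and grouping must be aligned")
  tab <- table(grouping, labels)
  n <- rowSums(tab)
  if (any(n == 0)) {
    warning("empty group(s) dropped: ",
            paste(rownames(tab)[n == 0], collapse = ", "))
    tab <- tab[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  frac <- sweep(unclass(tab), 1, n, "/")
  frac
}

#' Cluster composition by high/low marker combinations
#'
#' Classifies each cell as high or low for every marker gene (raw count
#' strictly above the marker's threshold; default 0, i.e. any detection
#' counts as high) and bins cells by the resulting combination. `TN` (triple
#' negative: all markers low) and `TP` (all high) conventions arise as the
#' all-low and all-high bins. Fractions are reported per cluster.
#'
#' @param raw A [count_matrix()] or named matrix of raw counts.
#' @param labels Per-cell cluster labels.
#' @param markers Marker gene names; all must be present in the matrix.
#' @param thresholds Per-marker high/low count threshold (recycled; default
#'   0).
#' @return Matrix of fractions, clusters x marker combinations. Combination
#'   names join `<marker>+` / `<marker>-`; the all-low bin is additionally
#'   usable as triple-negative.
#' @export
marker_composition <- function(raw, labels, markers, thresholds = 0) {
  m <- as_count_values(raw)
  missing <- setdiff(markers, rownames(m))
  if (length(missing))
    stop("marker gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(labels) != ncol(m)) stop("labels must cover all cells")
  thresholds <- rep_len(thresholds, length(markers))
  high <- m[markers, , drop = FALSE] > thresholds
  combo <- apply(high, 2, function(h)
    paste0(markers, ifelse(h, "+", "-"), collapse = ""))
  grid <- expand.grid(rep(list(c("-", "+")), length(markers)),
                      stringsAsFactors = FALSE)
  levels_all <- apply(grid, 1, function(s) paste0(markers, s, collapse = ""))
  levels_all <- sort(unique(c(levels_all, combo)))
  fraction_table(factor(combo, levels = levels_all), labels)
}

#' Consecutive or all-pairs cluster comparisons along a trajectory
#'
#' Runs [one_tailed_ttest()] on a per-cell quantity between clusters, either
#' for consecutive clusters along a trajectory order (default; alternative =
#' later cluster greater, matching increases along EMT progression) or for
#' all cluster pairs.
#'
#' @param values Per-cell numeric vector (e.g. EMT circuit energy).
#' @param labels Per-cell cluster labels.
#' @param order Cluster order defining "later" (e.g.
#'   `trajectory$cluster_order`).
#' @param mode `"consecutive"` (default) or `"all_pairs"`.
#' @return `data.frame` with columns `from`, `to`, `statistic`, `pvalue`,
#'   `stars` (testing whether `to` exceeds `from`).
#' @export
compare_along_trajectory <- function(values, labels, order,
                                     mode = c("consecutive", "all_pairs")) {
  mode <- match.arg(mode)
  pairs <- if (mode == "consecutive") {
    cbind(order[-length(order)], order[-1])
  } else {
    t(utils::combn(order, 2))
  }
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- values[labels == pairs[i, 1]]
    b <- values[labels == pairs[i, 2]]
    ht <- one_tailed_ttest(a, b, "b_greater")
    data.frame(from = pairs[i, 1], to = pairs[i, 2],
               statistic = ht$statistic, pvalue = ht$pvalue,
               stars = ht$stars, stringsAsFactors = FALSE)
  }))
}
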