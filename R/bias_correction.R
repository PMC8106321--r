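# Bias-corrected semisupervised regression.
#
# The reliable label set L0 (villages with an unambiguous one-to-one
# cluster match) seeds a harmonic solve; the correction step then
# assigns each fuzzy cluster's indicator value to the candidate village
# whose current prediction is closest, the reliable labels are reverted
# to their originals, and the solve is repeated.  Iterating correction
# and solve T times gives the final predictions.  The module is fully
# deterministic.

#' One correction step: assign fuzzy cluster labels to villages
#'
#' For each fuzzy cluster `c`, selects among its candidate villages
#' `V_c` the one whose current prediction is closest (smallest absolute
#' gap) to the cluster's indicator value and assigns the cluster's value
#' to it.  Ties on the gap go to the smallest village index; when two
#' clusters select the same village the smaller gap wins, then the
#' smaller cluster index.  Reliable villages are always reverted to
#' their original labels.
#'
#' @param y Current prediction vector (length n, all villages).
#' @param cluster_values Numeric vector of fuzzy-cluster indicator
#'   values, one per cluster in `candidates`.
#' @param candidates List of integer vectors: candidate village indices
#'   per fuzzy cluster.
#' @param reliable_idx Integer indices of the reliable villages (L0).
#' @param reliable_values Their original labels.
#' @return List: `y` (vector with assignments applied and L0 reverted),
#'   `labeled_idx`, `labeled_values` (the new labeled set
#'   `L0 + selected villages`), `selected` (chosen village per cluster,
#'   NA when skipped), `gaps` (winning absolute gaps).
#' @export
correction_assign <- function(y, cluster_values, candidates,
                              reliable_idx, reliable_values) {
  stopifnot(length(cluster_values) == length(candidates),
            length(reliable_idx) == length(reliable_values))
  nc <- length(candidates)
  sel <- rep(NA_integer_, nc)
  gap <- rep(NA_real_, nc)
  for (c_ in seq_len(nc)) {
    vc <- candidates[[c_]]
    if (length(vc) == 0L) {
      warning(sprintf("cluster %d has no candidate villages; skipped", c_),
              call. = FALSE)
      next
    }
    g <- abs(y[vc] - cluster_values[c_])
    # argmin with smallest-index tie-break (candidates sorted first)
    o <- order(g, vc)
    sel[c_] <- vc[o[1L]]
    gap[c_] <- g[o[1L]]
  }
  # collisions: smaller gap wins, then smaller cluster index
  keep <- rep(TRUE, nc)
  ok <- which(!is.na(sel))
  if (length(ok)) {
    o <- ok[order(gap[ok], ok)]
    seen <- integer(0)
    for (c_ in o) {
      if (sel[c_] %in% seen) keep[c_] <- FALSE else seen <- c(seen, sel[c_])
    }
  }
  assign_c <- which(keep & !is.na(sel))
  y[sel[assign_c]] <- cluster_values[assign_c]
  y[reliable_idx] <- reliable_values
  labeled_idx <- union(reliable_idx, sel[assign_c])
  labeled_idx <- sort(labeled_idx)
  labeled_values <- y[labeled_idx]
  list(y = y, labeled_idx = labeled_idx, labeled_values = labeled_values,
       selected = sel, gaps = gap)
}

#' Initialization: harmonic solve from the reliable label set
#'
#' @param y0 Length-n vector with reliable labels filled in and zeros
#'   (or anything) elsewhere; only the entries at `reliable_idx` are
#'   used.
#' @param graph A [build_graph()] result (or a feature matrix, in which
#'   case a graph is built with defaults).
#' @param reliable_idx Indices of the reliable villages.
#' @param ... Passed to [harmonic_solve()].
#' @return Length-n prediction vector.
#' @export
ssl_initialize <- function(y0, graph, reliable_idx, ...) {
  if (!inherits(graph, "proximity_graph")) graph <- build_graph(graph)
  harmonic_solve(graph, labels = y0[reliable_idx],
                 labeled_idx = reliable_idx, ...)
}

#' Iterative bias-corrected semisupervised regression
#'
#' Runs the initialization (harmonic solve from L0) followed by `T`
#' rounds of correction-and-resolve.  One round with `T = 1` is the
#' plain correction algorithm: initialize, correct, solve.
#'
#' @param y0 Length-n vector carrying the reliable labels at
#'   `reliable_idx`.
#' @param graph A [build_graph()] result or a feature matrix (graph
#'   built once and reused across iterations).
#' @param cluster_values Fuzzy-cluster indicator values.
#' @param candidates List of candidate village index vectors per fuzzy
#'   cluster.
#' @param reliable_idx Indices of the reliable villages (L0).
#' @param iterations Number of correction rounds `T` (default 5).
#' @param lambda,tol Passed to [harmonic_solve()].
#' @return List of class `bias_corrected_fit`: `y` (final predictions),
#'   `y_init` (initialization-only predictions), `labeled_idx` (final
#'   labeled set), and `history` (per-iteration labeled-set size and
#'   mean winning gap).
#' @export
run_bias_corrected <- function(y0, graph, cluster_values, candidates,
                               reliable_idx, iterations = 5L,
                               lambda = 0, tol = 1e-8) {
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (!inherits(graph, "proximity_graph")) graph <- build_graph(graph)
  reliable_idx <- as.integer(reliable_idx)
  reliable_values <- y0[reliable_idx]
  y <- harmonic_solve(graph, reliable_values, reliable_idx,
                      lambda = lambda, tol = tol)
  y_init <- y
  history <- data.frame(iteration = integer(0), n_labeled = integer(0),
                        mean_gap = numeric(0))
  labeled_idx <- reliable_idx
  for (t in seq_len(iterations)) {
    corr <- correction_assign(y, cluster_values, candidates,
                              reliable_idx, reliable_values)
    labeled_idx <- corr$labeled_idx
    y <- harmonic_solve(graph, corr$labeled_values, labeled_idx,
                        lambda = lambda, tol = tol)
    history <- rbind(history, data.frame(
      iteration = t, n_labeled = length(labeled_idx),
      mean_gap = mean(corr$gaps, na.rm = TRUE)))
  }
  structure(list(y = y, y_init = y_init, labeled_idx = labeled_idx,
                 reliable_idx = reliable_idx,
                 reliable_values = reliable_values, history = history),
            class = "bias_corrected_fit")
}

#' @export
print.bias_corrected_fit <- function(x, ...) {
  cat(sprintf(
    "bias_corrected_fit: %d villages, %d reliable labels, %d final labels, %d iteration(s)\n",
    length(x$y), length(x$reliable_idx), length(x$labeled_idx),
    nrow(x$history)))
  invisible(x)
}
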