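# Graph-harmonic semisupervised regression.
#
# The village-feature proximity graph encodes the cluster assumption
# (feature-similar villages have similar prevalences); harmonic
# interpolation encodes the harmonic assumption (each unlabeled
# village's value is the weighted average of its neighbors').  The
# harmonic solution clamps labeled nodes and solves the graph-Laplacian
# subsystem over unlabeled nodes.

#' Build the village-feature proximity graph
#'
#' Standardizes each feature column (dropping constants), takes the
#' union-symmetrized k-nearest-neighbor graph under Euclidean distance,
#' and weights each edge `exp(-dist^2 / (2 * bandwidth^2))`.  The
#' default bandwidth is the median of the included edge distances.  If
#' all rows are identical the graph degenerates to the complete graph
#' with unit weights.
#'
#' @param X Numeric feature matrix, villages in rows.
#' @param k Number of nearest neighbors (default 10); must be `< n`.
#' @param bandwidth Gaussian kernel bandwidth, or `NULL` for the median
#'   edge distance.
#' @return Object of class `proximity_graph`: sparse symmetric weight
#'   matrix `W`, component labels, and construction metadata.
#' @export
build_graph <- function(X, k = 10L, bandwidth = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least two villages", call. = FALSE)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of villages",
                   call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  keep <- which(sd_ > 0)
  if (length(keep) == 0L) {
    # degenerate: all villages identical in features
    ii <- rep(seq_len(n), each = n)
    jj <- rep(seq_len(n), times = n)
    off <- ii != jj
    W <- Matrix::sparseMatrix(i = ii[off], j = jj[off], x = 1, dims = c(n, n))
    g <- structure(list(W = W, n = n, k = k, bandwidth = Inf,
                        center = mu, scale = sd_, kept_columns = keep,
                        components = rep(1L, n)),
                   class = "proximity_graph")
    return(g)
  }
  Xs <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sd_[keep])
  d2 <- euclidean_dist2(Xs)
  diag(d2) <- Inf
  idx <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(idx))
  # union symmetrization
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  key <- !duplicated(cbind(a, b))
  a <- a[key]; b <- b[key]
  ed <- sqrt(pmax(d2[cbind(a, b)], 0))
  if (is.null(bandwidth)) {
    bandwidth <- stats::median(ed)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  w <- exp(-ed^2 / (2 * bandwidth^2))
  W <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w),
                            dims = c(n, n))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W > 0, mode = "undirected"))$membership
  structure(list(W = W, n = n, k = k, bandwidth = bandwidth,
                 center = mu, scale = sd_, kept_columns = keep,
                 components = as.integer(comp)),
            class = "proximity_graph")
}

# squared Euclidean distance matrix without forming dist()
euclidean_dist2 <- function(X) {
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf(
    "proximity_graph: %d nodes, %d edges (k = %d, bandwidth = %.4g), %d component(s)\n",
    x$n, Matrix::nnzero(x$W) / 2, x$k, x$bandwidth,
    max(x$components)))
  invisible(x)
}

#' Harmonic interpolation of labels over the graph
#'
#' Labeled nodes are clamped to their labels; every unlabeled node gets
#' the weighted average of its neighbors by solving the Laplacian
#' subsystem `(L_uu + lambda I) y_u = W_ul y_l` with conjugate
#' gradients.  Connected components containing no labeled node (and
#' isolated unlabeled nodes) receive the mean of all labels, with a
#' message.  Solutions are clamped to `[min(labels), max(labels)]`,
#' removing solver-tolerance dust so the maximum principle holds
#' exactly.
#'
#' @param graph A [build_graph()] result.
#' @param labels Numeric values for the labeled nodes.
#' @param labeled_idx Integer indices of the labeled nodes (same order
#'   as `labels`).
#' @param lambda Optional ridge on the unlabeled diagonal (default 0).
#' @param tol Conjugate-gradient convergence tolerance (default 1e-8).
#' @return Numeric vector of length `n`: labels at labeled nodes,
#'   harmonic values elsewhere.
#' @export
harmonic_solve <- function(graph, labels, labeled_idx, lambda = 0,
                           tol = 1e-8) {
  stopifnot(inherits(graph, "proximity_graph"))
  n <- graph$n
  labeled_idx <- as.integer(labeled_idx)
  if (length(labeled_idx) == 0L) stop("labeled set is empty", call. = FALSE)
  if (length(labels) != length(labeled_idx)) {
    stop("labels and labeled_idx must align", call. = FALSE)
  }
  if (any(!is.finite(labels))) stop("labels must be finite", call. = FALSE)
  if (any(labeled_idx < 1L | labeled_idx > n)) {
    stop("labeled_idx out of range", call. = FALSE)
  }
  if (anyDuplicated(labeled_idx)) {
    keep <- !duplicated(labeled_idx)
    labels <- labels[keep]; labeled_idx <- labeled_idx[keep]
  }
  y <- numeric(n)
  y[labeled_idx] <- labels
  unlabeled <- setdiff(seq_len(n), labeled_idx)
  if (length(unlabeled) == 0L) return(y)

  lab_mean <- mean(labels)
  comp <- graph$components
  labeled_comps <- unique(comp[labeled_idx])
  orphan <- unlabeled[!(comp[unlabeled] %in% labeled_comps)]
  if (length(orphan)) {
    message(length(orphan),
            " unlabeled node(s) in components without labels; ",
            "assigned the global labeled mean")
    y[orphan] <- lab_mean
  }
  solve_idx <- setdiff(unlabeled, orphan)
  if (length(solve_idx) == 0L) return(clamp_range(y, labels, labeled_idx))

  W <- graph$W
  deg <- Matrix::rowSums(W)
  Wuu <- W[solve_idx, solve_idx, drop = FALSE]
  Wul <- W[solve_idx, labeled_idx, drop = FALSE]
  A <- Matrix::Diagonal(x = deg[solve_idx] + lambda) - Wuu
  b <- as.vector(Wul %*% labels)
  x0 <- rep(lab_mean, length(solve_idx))
  y[solve_idx] <- cg_solve(A, b, x0, tol = tol)
  clamp_range(y, labels, labeled_idx)
}

clamp_range <- function(y, labels, labeled_idx) {
  lo <- min(labels); hi <- max(labels)
  out <- pmin(pmax(y, lo), hi)
  out[labeled_idx] <- labels
  out
}

# Conjugate gradients for SPD sparse systems.
cg_solve <- function(A, b, x0, tol = 1e-8, max_iter = NULL) {
  n <- length(b)
  if (is.null(max_iter)) max_iter <- max(1000L, 20L * n)
  x <- x0
  r <- b - as.vector(A %*% x)
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  for (i in seq_len(max_iter)) {
    if (sqrt(rs) / bnorm < tol) break
    Ap <- as.vector(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}
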