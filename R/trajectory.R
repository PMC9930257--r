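#' Diffusion-map embedding of cells
#'
#' Builds a cell-to-cell Markov transition matrix from a Gaussian kernel
#' with locally adaptive bandwidth (per-cell sigma = distance to the
#' `ceiling(k_neighbors / 2)`-th nearest neighbor), optionally density
#' normalized (the kernel is divided by the product of its row sums,
#' removing sampling-density effects), row-normalized and
#' eigendecomposed. The trivial constant eigenvector (eigenvalue 1) is
#' dropped; component `i` is the `i`-th non-trivial eigenvector scaled by
#' its eigenvalue. Signs are fixed by making each component's
#' largest-magnitude entry positive, so results are fully deterministic.
#'
#' Because the bandwidths scale with the data, the transition matrix is
#' invariant to a global rescaling of the input coordinates.
#'
#' @param X cells x d numeric matrix (PC embedding or activity matrix).
#' @param n_comps number of diffusion components returned (default 10).
#' @param k_neighbors neighbor index used for the local bandwidth
#'   (default 30).
#' @param density_norm apply density normalization (default TRUE).
#' @return object of class `diffusion_result`: `components` (cells x
#'   n_comps), `eigenvalues`, `transition` (row-stochastic), and slots
#'   `pseudotime` / `root_cell` filled by [diffusion_pseudotime()].
#' @export
diffusion_map <- function(X, n_comps = 10L, k_neighbors = 30L,
                          density_norm = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_comps + 1L) stop("need more cells than components")
  D <- as.matrix(stats::dist(X))
  kk <- min(ceiling(k_neighbors / 2), n - 1L)
  sigma <- apply(D, 1L, function(d) sort(d)[kk + 1L])  # exclude self
  if (any(sigma == 0)) {
    # duplicate cells: fall back to the smallest positive distance
    eps <- min(D[D > 0])
    sigma[sigma == 0] <- eps
    warning("duplicate cells produced zero bandwidths; floored to the ",
            "smallest positive distance")
  }
  K <- exp(-D^2 / outer(sigma, sigma))
  diag(K) <- 0
  if (density_norm) {
    q <- rowSums(K)
    K <- K / outer(q, q)
  }
  d <- rowSums(K)
  P <- K / d
  # symmetric conjugate for a stable eigendecomposition
  S <- K / sqrt(outer(d, d))
  es <- eigen(S, symmetric = TRUE)
  phi <- es$vectors / sqrt(d)            # right eigenvectors of P
  lambda <- es$values
  keep <- 2:(n_comps + 1L)
  lambda_k <- lambda[keep]
  comp <- phi[, keep, drop = FALSE]
  comp <- apply(comp, 2L, function(v) v / sqrt(sum(v^2)))
  for (j in seq_len(ncol(comp)))
    if (comp[which.max(abs(comp[, j])), j] < 0) comp[, j] <- -comp[, j]
  components <- sweep(comp, 2L, lambda_k, "*")
  dimnames(components) <- list(rownames(X), paste0("DC", seq_len(n_comps)))
  structure(list(components = components, eigenvalues = lambda_k,
                 eigenvectors = comp, transition = P,
                 pseudotime = NULL, root_cell = NULL),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("diffusion_result:", nrow(x$components), "cells,",
      ncol(x$components), "components; leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 3L), 4), collapse = ", "),
      "\n")
  if (!is.null(x$root_cell)) cat("  pseudotime rooted at", x$root_cell, "\n")
  invisible(x)
}

#' Diffusion pseudotime anchored at a root cell
#'
#' Pseudotime of cell `c` is the Euclidean distance between the rows of
#' the root and `c` in the eigenspace weighted by `lambda / (1 - lambda)`
#' (the diffusion-pseudotime construction, which sums transition kernels
#' over all path lengths), rescaled to [0, 1] so the root sits at 0.
#'
#' @param res a [diffusion_map()] result.
#' @param root_cell cell id (rowname) or index of the root.
#' @return the `diffusion_result` with `pseudotime` (named numeric in
#'   [0, 1]) and `root_cell` filled in.
#' @export
diffusion_pseudotime <- function(res, root_cell) {
  stopifnot(inherits(res, "diffusion_result"))
  cells <- rownames(res$components)
  k <- if (is.character(root_cell)) match(root_cell, cells)
       else as.integer(root_cell)
  if (is.na(k) || k < 1L || k > nrow(res$components))
    stop("root cell not found")
  near_one <- res$eigenvalues >= 1 - 1e-12
  if (any(near_one))
    stop("kernel graph is disconnected: component(s) ",
         paste(which(near_one), collapse = ", "),
         " carry a unit eigenvalue; increase k_neighbors or check for ",
         "isolated cell groups")
  w <- res$eigenvalues / (1 - res$eigenvalues)
  M <- sweep(res$eigenvectors, 2L, w, "*")
  dpt <- sqrt(rowSums((M - matrix(M[k, ], nrow(M), ncol(M),
                                  byrow = TRUE))^2))
  if (max(dpt) > 0) dpt <- dpt / max(dpt)
  names(dpt) <- cells
  res$pseudotime <- dpt
  res$root_cell <- if (is.null(cells)) k else cells[k]
  res
}

#' Default root-cell choice for pseudotime
#'
#' Within the user-named early cluster, picks the cell most extreme on
#' the first diffusion component (largest distance from the component's
#' overall median) — a deterministic anchor at the tip of the early
#' state.
#'
#' @param res a [diffusion_map()] result.
#' @param labels cluster label per cell.
#' @param root_cluster label of the biologically earliest cluster.
#' @return index of the chosen root cell.
#' @export
select_root_cell <- function(res, labels, root_cluster) {
  stopifnot(inherits(res, "diffusion_result"))
  in_root <- which(as.character(labels) == as.character(root_cluster))
  if (!length(in_root)) stop("no cells in root cluster '", root_cluster, "'")
  dc1 <- res$components[, 1L]
  in_root[which.max(abs(dc1[in_root] - stats::median(dc1)))]
}

#' Mean cell-to-cell transition probabilities between clusters
#'
#' Entry (A, B) is the mean of the one-step transition probabilities from
#' cells of cluster A to cells of cluster B (including A = B). Adjacent
#' states along a lineage show larger mutual entries than distal ones.
#'
#' @param res a [diffusion_map()] result.
#' @param labels cluster label per cell.
#' @return clusters x clusters numeric matrix.
#' @export
cluster_transitions <- function(res, labels) {
  stopifnot(inherits(res, "diffusion_result"))
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop("empty cluster")
  lev <- levels(labels)
  out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in lev) for (b in lev)
    out[a, b] <- mean(res$transition[labels == a, labels == b])
  out
}
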