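#' Cell-specific network parameters
#'
#' @param box_frac marginal neighborhood size as a fraction of cells
#'   (default 0.1: each gene's box around a cell targets `0.1 n` cells).
#' @param alpha per-edge one-sided significance level against N(0, 1)
#'   (default 0.01).
#' @param gene_subset optional gene ids; only pairs within the subset are
#'   tested (boxes are still computed over all cells).
#' @return object of class `csn_params`.
#' @export
csn_params <- function(box_frac = 0.1, alpha = 0.01, gene_subset = NULL) {
  if (box_frac <= 0 || box_frac > 1) stop("box_frac must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(box_frac = box_frac, alpha = alpha,
                 gene_subset = gene_subset), class = "csn_params")
}

#' Marginal box membership around one cell
#'
#' For a single gene's expression over `n` cells, returns the
#' `m = ceiling(box_frac * n)` cells nearest to cell `k` in midrank — the
#' smallest rank-window centred on `k`'s midrank holding `m` cells, with
#' the lower side preferred when the two boundary candidates are
#' equidistant. Cells tied in value always enter or leave the window as a
#' whole block (ties share a midrank), which keeps the window well
#' defined under the heavy zero-ties of scRNA-seq, so the box can exceed
#' `m` cells only through value ties; `k` itself is always a member.
#'
#' @param values numeric vector (one gene over all cells).
#' @param k index of the focal cell.
#' @param box_frac neighborhood fraction.
#' @return integer vector of member cell indices.
#' @export
box_membership <- function(values, k, box_frac = 0.1) {
  n <- length(values)
  if (n < 2L) stop("need at least two cells")
  r <- rank(values, ties.method = "average")
  m <- ceiling(box_frac * n)
  which(box_indicator(r, m)[, k])
}

# rank-window indicator for every focal cell of one gene.
# r: midranks; m: target box size. Returns n x n logical, [i, k] = cell i
# in the box around cell k. Boxes hold the m nearest-in-midrank cells;
# whole value-tie blocks are included or excluded together (lower side
# first), so |box| >= m with equality unless a tie block straddles the
# boundary.
box_indicator <- function(r, m) {
  n <- length(r)
  D <- abs(outer(r, r, "-"))
  h <- apply(D, 2L, function(col) sort(col, partial = m)[m])
  B <- sweep(D, 2L, h, "<")
  for (k in seq_len(n)) {
    short <- m - sum(B[, k])
    if (short > 0L) {
      lower <- D[, k] == h[k] & r <= r[k]
      B[lower, k] <- TRUE
      if (sum(B[, k]) < m) B[D[, k] == h[k] & r > r[k], k] <- TRUE
    }
  }
  B
}

#' The cell-specific network edge statistic
#'
#' Standardized co-occupancy of the two marginal boxes around a cell:
#' `rho = sqrt(n - 1) * (n * n_xy - n_x * n_y) /
#' sqrt(n_x * n_y * (n - n_x) * (n - n_y))`. Under independence of the
#' two genes near the cell, `rho` is asymptotically standard normal, so a
#' large positive value marks a cell-specific association (edge).
#'
#' @param n total cells; `n_x`, `n_y` marginal box counts; `n_xy`
#'   intersection count.
#' @return the statistic; `NA` when a marginal box is degenerate
#'   (`n_x` or `n_y` in {0, n}), in which case the edge is untestable.
#' @export
csn_statistic <- function(n, n_x, n_y, n_xy) {
  den <- n_x * n_y * (n - n_x) * (n - n_y)
  out <- sqrt(n - 1) * (n * n_xy - n_x * n_y) / sqrt(den)
  out[den == 0] <- NA_real_
  out
}

#' Build cell-specific networks and the network degree matrix
#'
#' For every unordered gene pair (restricted to `gene_subset` when given)
#' and every cell, computes the two marginal boxes, the intersection
#' count, and the edge statistic; an edge is called significant in a cell
#' when the statistic exceeds the upper-tail normal quantile
#' `qnorm(1 - alpha)`. Untestable edges (degenerate boxes, e.g. a constant
#' gene) are never significant.
#'
#' The statistic is evaluated conditionally on the focal cell: the counts
#' entering the formula cover the other `n - 1` cells (the focal cell,
#' which sits in both of its own boxes by construction, is removed from
#' `n`, `n_x`, `n_y` and `n_xy`). This removes a deterministic one-cell
#' co-occupancy that would otherwise bias the independence null upward;
#' with exact-size boxes the conditional null count is hypergeometric and
#' the normal reference is well calibrated.
#'
#' A gene with zero expression in the focal cell has an empty
#' neighborhood there: its edges are untestable (never significant) in
#' that cell. Without this gate the shared zero block of dropout-heavy
#' data produces massive "co-silence" edges between genes that are merely
#' off together.
#'
#' @param norm cells x genes expression matrix.
#' @param params a [csn_params()].
#' @return object of class `csn_result`: `edges` (data.frame cell, gene_a,
#'   gene_b, rho over the significant calls, with gene_a < gene_b), `ndm`
#'   (genes x cells integer degree matrix over the tested genes), `n`
#'   cells, `params`.
#' @export
build_csn <- function(norm, params = csn_params()) {
  genes <- colnames(norm)
  if (!is.null(params$gene_subset)) {
    missing <- setdiff(params$gene_subset, genes)
    if (length(missing)) stop("subset gene(s) missing from matrix: ",
                              paste(missing, collapse = ", "))
    genes <- params$gene_subset
  }
  if (length(genes) < 2L) stop("need at least two genes")
  n <- nrow(norm)
  m <- ceiling(params$box_frac * n)
  if (n < m) stop("too few cells for box_frac")
  z_crit <- stats::qnorm(1 - params$alpha)

  # B[[g]]: n x n logical, B[i, k] = cell i inside gene g's box around k
  B <- vector("list", length(genes))
  names(B) <- genes
  nx <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
  for (g in seq_along(genes)) {
    r <- rank(norm[, genes[g]], ties.method = "average")
    Bg <- box_indicator(r, m)
    B[[g]] <- Bg
    nx[g, ] <- colSums(Bg) - 1  # focal cell conditioned out
  }

  cells <- rownames(norm)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  edge_cell <- edge_a <- edge_b <- character(0)
  edge_rho <- numeric(0)
  ndm <- matrix(0L, length(genes), n, dimnames = list(genes, cells))
  expressed <- t(norm[, genes, drop = FALSE] > 0)
  for (a in seq_len(length(genes) - 1L)) {
    Ba <- B[[a]]
    for (b in (a + 1L):length(genes)) {
      nxy <- colSums(Ba & B[[b]]) - 1
      rho <- csn_statistic(n - 1, nx[a, ], nx[b, ], nxy)
      sig <- !is.na(rho) & rho > z_crit & expressed[a, ] & expressed[b, ]
      if (any(sig)) {
        edge_cell <- c(edge_cell, cells[sig])
        edge_a <- c(edge_a, rep(genes[a], sum(sig)))
        edge_b <- c(edge_b, rep(genes[b], sum(sig)))
        edge_rho <- c(edge_rho, rho[sig])
        ndm[a, sig] <- ndm[a, sig] + 1L
        ndm[b, sig] <- ndm[b, sig] + 1L
      }
    }
  }
  structure(list(edges = data.frame(cell = edge_cell, gene_a = edge_a,
                                    gene_b = edge_b, rho = edge_rho),
                 ndm = ndm, n = n, params = params),
            class = "csn_result")
}

#' @export
print.csn_result <- function(x, ...) {
  cat("csn_result:", nrow(x$ndm), "genes x", x$n, "cells;",
      nrow(x$edges), "significant edge calls (alpha =",
      x$params$alpha, ", box_frac =", x$params$box_frac, ")\n")
  invisible(x)
}

#' Network degree matrix
#'
#' @param result a [build_csn()] result.
#' @return genes x cells integer matrix; entry = number of significant
#'   edges of the gene in that cell's network.
#' @export
ndm <- function(result) {
  stopifnot(inherits(result, "csn_result"))
  result$ndm
}

#' Differential network degree: one cluster against the rest
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the NDM values in the
#' target cluster against all other cells (exact for small tie-free
#' groups, normal approximation with midranks otherwise, as in
#' [stats::wilcox.test()]), with Benjamini-Hochberg adjustment across
#' genes.
#'
#' @param ndm genes x cells degree matrix.
#' @param labels cluster label per cell.
#' @param target_cluster label of the cluster of interest.
#' @return data.frame: gene, statistic (W), p_value, p_adjusted,
#'   mean_in, mean_out.
#' @export
differential_ndm <- function(ndm, labels, target_cluster) {
  labels <- as.character(labels)
  in_g <- labels == as.character(target_cluster)
  if (sum(in_g) < 2L || sum(!in_g) < 2L)
    stop("target cluster and complement each need >= 2 cells")
  if (is.null(rownames(ndm)))
    rownames(ndm) <- paste0("gene", seq_len(nrow(ndm)))
  res <- data.frame(gene = rownames(ndm), statistic = NA_real_,
                    p_value = NA_real_,
                    mean_in = rowMeans(ndm[, in_g, drop = FALSE]),
                    mean_out = rowMeans(ndm[, !in_g, drop = FALSE]))
  for (g in seq_len(nrow(ndm))) {
    x <- ndm[g, in_g]
    y <- ndm[g, !in_g]
    if (length(unique(c(x, y))) > 1L) {
      wt <- suppressWarnings(stats::wilcox.test(x, y,
                                                alternative = "two.sided"))
      res$statistic[g] <- unname(wt$statistic)
      res$p_value[g] <- wt$p.value
    } else {
      res$p_value[g] <- 1
    }
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Per-cluster edge frequencies
#'
#' For each cluster, the fraction of its cells in which each gene pair is
#' a significant edge — the quantity displayed by per-cluster arc
#' diagrams.
#'
#' @param result a [build_csn()] result.
#' @param labels cluster label per cell (covering all cells).
#' @return named list (one element per cluster) of data.frames gene_a,
#'   gene_b, frequency, restricted to pairs seen at least once overall.
#' @export
connectivity_by_cluster <- function(result, labels) {
  stopifnot(inherits(result, "csn_result"))
  cells <- colnames(result$ndm)
  labels <- stats::setNames(as.character(labels), cells)
  pairs <- unique(result$edges[, c("gene_a", "gene_b")])
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- cells[labels == cl]
    e <- result$edges[result$edges$cell %in% members, , drop = FALSE]
    key <- paste(e$gene_a, e$gene_b, sep = "\r")
    counts <- table(key)
    freq <- numeric(nrow(pairs))
    pk <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
    freq[match(names(counts), pk)] <- as.numeric(counts) / length(members)
    out[[cl]] <- data.frame(pairs, frequency = freq, row.names = NULL)
  }
  out
}
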