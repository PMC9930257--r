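# Shared fixtures, built in code at test time.

# a rank_matrix from explicit per-cell rank rows
rank_fixture <- function(rows, genes = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  dimnames(m) <- list(paste0("c", seq_len(nrow(m))), genes)
  storage.mode(m) <- "integer"
  structure(m, tie_seed = NA_integer_,
            class = c("rank_matrix", "matrix", "array"))
}

# brute-force recovery-curve AUC: literal hits(t) step-curve enumeration
auc_oracle <- function(rank_row, set_idx, top_frac) {
  G <- length(rank_row)
  T_top <- ceiling(top_frac * G)
  hits <- vapply(seq_len(T_top - 1L), function(t)
    sum(rank_row[set_idx] <= t), numeric(1L))
  mx <- sum(pmin(seq_len(T_top - 1L), length(set_idx)))
  sum(hits) / mx
}

# naive per-cell, per-pair CSN reference: explicit loops, no matrices.
# boxes: m nearest-in-midrank cells, whole value-tie blocks, lower side
# first; statistic evaluated on the n - 1 non-focal cells; genes
# unexpressed in the focal cell are untestable there.
csn_oracle <- function(X, box_frac = 0.1, alpha = 0.01) {
  n <- nrow(X)
  G <- ncol(X)
  m <- ceiling(box_frac * n)
  z <- qnorm(1 - alpha)
  box_of <- function(vals, k) {
    r <- rank(vals, ties.method = "average")
    d <- abs(r - r[k])
    h <- sort(d)[m]
    members <- which(d < h)
    if (length(members) < m) {
      lower <- which(d == h & r <= r[k])
      members <- c(members, lower)
      if (length(members) < m)
        members <- c(members, which(d == h & r > r[k]))
    }
    members
  }
  edges <- list()
  ndm <- matrix(0L, G, n, dimnames = list(colnames(X), rownames(X)))
  for (k in seq_len(n)) {
    for (a in seq_len(G - 1L)) {
      A <- box_of(X[, a], k)
      for (b in (a + 1L):G) {
        if (X[k, a] <= 0 || X[k, b] <= 0) next
        B <- box_of(X[, b], k)
        nx <- length(A) - 1L
        ny <- length(B) - 1L
        nxy <- length(intersect(A, B)) - 1L
        nn <- n - 1L
        den <- nx * ny * (nn - nx) * (nn - ny)
        if (den == 0) next
        rho <- sqrt(nn - 1) * (nn * nxy - nx * ny) / sqrt(den)
        if (rho > z) {
          edges[[length(edges) + 1L]] <-
            data.frame(cell = rownames(X)[k], gene_a = colnames(X)[a],
                       gene_b = colnames(X)[b], rho = rho)
          ndm[a, k] <- ndm[a, k] + 1L
          ndm[b, k] <- ndm[b, k] + 1L
        }
      }
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(cell = character(0), gene_a = character(0),
                    gene_b = character(0), rho = numeric(0)),
       ndm = ndm)
}

# default study-condition dataset used by recovery tests
default_dataset <- function(seed = 1L, ...) {
  simulate_counts(sim_config(seed = seed, ...))
}
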