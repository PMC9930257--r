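#' Quality-control parameters
#'
#' Cell-level filters for droplet scRNA-seq: detected-gene bounds (low =
#' empty droplets / degraded cells, high = doublets), a mitochondrial
#' count-fraction ceiling, a set of genes that must be detected (lineage
#' selection; by default the early osteoblast marker RUNX2) and a set of
#' genes whose detection disqualifies a cell (erythrocyte contamination via
#' hemoglobin genes).
#'
#' @param min_genes minimum detected genes per cell (default 200).
#' @param max_genes maximum detected genes per cell (default 5000).
#' @param max_mito_frac maximum mitochondrial count fraction (default 0.15).
#' @param required_positive_genes genes that must have count > 0.
#' @param excluded_if_expressed genes that must have count == 0.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200L, max_genes = 5000L,
                      max_mito_frac = 0.15,
                      required_positive_genes = "RUNX2",
                      excluded_if_expressed = c("HBM", "HBA1", "HBA2", "HBB"),
                      mito_prefix = "MT-") {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in [0, 1]")
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_frac = max_mito_frac,
                 required_positive_genes = required_positive_genes,
                 excluded_if_expressed = excluded_if_expressed,
                 mito_prefix = mito_prefix),
            class = "qc_params")
}

#' Filter low-quality cells
#'
#' Keeps cells satisfying all rules of [qc_params()]. A cell failing
#' several rules is attributed to the first failing rule, in the fixed
#' order low gene count, high gene count, mitochondrial fraction, missing
#' required gene, excluded gene expressed — so removal counts are
#' reproducible.
#'
#' @param counts cells x genes matrix of non-negative integer counts with
#'   dimnames (dense matrix or dgCMatrix).
#' @param params a [qc_params()].
#' @return list with `counts` (the surviving cells), `keep` (logical per
#'   input cell) and `report` (named removal counts per rule, plus any
#'   warnings about unresolvable gene ids).
#' @export
qc_filter <- function(counts, params = qc_params()) {
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  genes <- colnames(counts)
  warnings <- character(0)
  detected <- Matrix::rowSums(counts > 0)
  totals <- Matrix::rowSums(counts)
  mito_genes <- genes[startsWith(genes, params$mito_prefix)]
  mito_frac <- if (length(mito_genes))
    Matrix::rowSums(counts[, mito_genes, drop = FALSE]) / pmax(totals, 1)
  else rep(0, nrow(counts))

  miss_req <- setdiff(params$required_positive_genes, genes)
  if (length(miss_req))
    warnings <- c(warnings, paste("required genes absent from matrix:",
                                  paste(miss_req, collapse = ", ")))
  req <- intersect(params$required_positive_genes, genes)
  req_ok <- if (length(req))
    Matrix::rowSums(counts[, req, drop = FALSE] > 0) == length(req)
  else rep(TRUE, nrow(counts))

  miss_exc <- setdiff(params$excluded_if_expressed, genes)
  if (length(miss_exc))
    warnings <- c(warnings, paste("excluded genes absent from matrix:",
                                  paste(miss_exc, collapse = ", ")))
  exc <- intersect(params$excluded_if_expressed, genes)
  exc_ok <- if (length(exc))
    Matrix::rowSums(counts[, exc, drop = FALSE] > 0) == 0
  else rep(TRUE, nrow(counts))

  fail <- cbind(low = detected < params$min_genes,
                high = detected > params$max_genes,
                mito = mito_frac > params$max_mito_frac,
                marker = !req_ok,
                excluded = !exc_ok)
  keep <- rowSums(fail) == 0L
  first_rule <- apply(fail, 1L, function(f) which(f)[1L])
  report <- vapply(seq_len(ncol(fail)), function(j)
    sum(first_rule == j, na.rm = TRUE), integer(1L))
  names(report) <- colnames(fail)
  if (!any(keep)) stop("QC removed every cell")
  list(counts = counts[keep, , drop = FALSE], keep = keep,
       report = as.list(c(report, warnings = list(warnings))))
}

#' Library-size normalize and log-transform
#'
#' Each cell is scaled to `scale_total` total counts and log1p-transformed:
#' `value = log(1 + count / cell_total * scale_total)`, so per-cell
#' `sum(expm1(value))` reproduces `scale_total` exactly.
#'
#' @param counts cells x genes count matrix (no all-zero cell).
#' @param scale_total per-cell total after scaling (default 10000).
#' @return An object of class `norm_matrix`: a dense cells x genes numeric
#'   matrix with attributes `scale_total` and `log_applied = TRUE`.
#' @export
normalize_log <- function(counts, scale_total = 10000) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) stop("all-zero cell(s): ",
                             paste(which(totals == 0), collapse = ", "))
  x <- log1p(as.matrix(counts) / totals * scale_total)
  structure(x, scale_total = scale_total, log_applied = TRUE,
            class = c("norm_matrix", class(x)))
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion of the log-normalized values:
#' the per-gene dispersion (variance / mean) is z-scored within
#' equal-frequency bins of the gene mean, so a gene is "variable" when
#' its dispersion is unusual *for its expression level* rather than
#' merely because lowly expressed genes are noisy. The top `n_top` genes
#' are returned, with a deterministic tie-break by gene id.
#'
#' @param norm a [normalize_log()] matrix (cells x genes).
#' @param n_top number of genes to return (default 2000).
#' @param n_bins number of mean bins for the standardization (default 20).
#' @return character vector of gene ids.
#' @export
select_hvg <- function(norm, n_top = 2000L, n_bins = 20L) {
  if (n_top > ncol(norm)) stop("n_top exceeds the number of genes")
  means <- colMeans(norm)
  vars <- apply(norm, 2L, stats::var)
  if (all(vars == 0)) stop("all genes constant; no variable genes")
  disp <- ifelse(means > 0, vars / means, 0)
  n_bins <- max(1L, min(n_bins, floor(ncol(norm) / 5)))
  bin <- cut(rank(means, ties.method = "first"), n_bins, labels = FALSE)
  zdisp <- disp
  for (b in unique(bin)) {
    idx <- bin == b
    s <- stats::sd(disp[idx])
    zdisp[idx] <- if (is.na(s) || s == 0) 0
                  else (disp[idx] - mean(disp[idx])) / s
  }
  zdisp[vars == 0] <- -Inf   # a constant gene is never variable
  ord <- order(-zdisp, colnames(norm))
  colnames(norm)[ord][seq_len(n_top)]
}

#' Principal component analysis with variance-explained reporting
#'
#' PCA over the given genes of the normalized matrix, with per-gene
#' centering and (optionally) unit scaling. Genes constant over cells are
#' dropped with a warning before scaling. Per-PC standard deviations are
#' the singular values divided by sqrt(cells - 1); all of them are kept so
#' the variance percentages sum to 100 over the computed spectrum.
#'
#' @param norm a [normalize_log()] matrix.
#' @param genes gene ids to use (default: all).
#' @param n_pcs number of components kept in the embedding (default 18).
#' @param center,unit_scale per-gene centering / scaling flags.
#' @return list of class `pc_result`: `embedding` (cells x n_pcs),
#'   `stdevs` (all PCs), `variance_pct` (all PCs, sums to 100),
#'   `loadings` (genes x n_pcs).
#' @export
run_pca <- function(norm, genes = colnames(norm), n_pcs = 18L,
                    center = TRUE, unit_scale = TRUE) {
  x <- norm[, genes, drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s) before PCA")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds min(cells, genes)")
  x <- scale(x, center = center, scale = unit_scale)
  sv <- svd(x)
  stdevs <- sv$d / sqrt(nrow(x) - 1)
  emb <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(n_pcs)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      sv$v[, j] <- -v
      emb[, j] <- -emb[, j]
    }
  }
  dimnames(emb) <- list(rownames(norm), paste0("PC", seq_len(n_pcs)))
  structure(list(embedding = emb, stdevs = stdevs,
                 variance_pct = variance_explained(stdevs),
                 loadings = sv$v[, seq_len(n_pcs), drop = FALSE]),
            class = "pc_result")
}

#' Percentage of variance explained per principal component
#'
#' `stdev^2 / sum(stdev^2) * 100`, elementwise.
#'
#' @param stdevs per-PC standard deviations (non-negative, not all zero).
#' @return numeric vector summing to 100.
#' @export
variance_explained <- function(stdevs) {
  if (any(stdevs < 0)) stop("standard deviations must be non-negative")
  tot <- sum(stdevs^2)
  if (tot == 0) stop("all-zero standard deviations")
  stdevs^2 / tot * 100
}

#' Baseline k-means cell clustering
#'
#' A deterministic (seeded, multi-restart) k-means over an embedding.
#' External labels (e.g., graph-based community detection run elsewhere)
#' can be supplied to downstream functions instead.
#'
#' @param embedding cells x d numeric matrix.
#' @param k number of clusters (2 <= k <= cells).
#' @param seed integer seed.
#' @param n_init number of random restarts.
#' @return integer vector of cluster labels (1..k), named by cell.
#' @export
cluster_cells <- function(embedding, k, seed = 1L, n_init = 10L) {
  if (k > nrow(embedding)) stop("k exceeds the number of cells")
  set.seed(seed)
  if (k == nrow(embedding)) return(stats::setNames(seq_len(k),
                                                   rownames(embedding)))
  km <- stats::kmeans(embedding, centers = k, nstart = n_init,
                      iter.max = 100L)
  stats::setNames(km$cluster, rownames(embedding))
}

#' Read a 10x-style Matrix Market triple
#'
#' Expects `matrix.mtx` (genes x cells), `features.tsv` (or `genes.tsv`)
#' and `barcodes.tsv` in `dir`; returns a cells x genes integer matrix.
#'
#' @param dir directory containing the triple.
#' @return dense cells x genes integer matrix with dimnames.
#' @export
read_tenx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  if (!file.exists(feats)) feats <- file.path(dir, "genes.tsv")
  m <- as.matrix(Matrix::t(Matrix::readMM(mtx)))
  storage.mode(m) <- "integer"
  f <- utils::read.table(feats, sep = "\t", header = FALSE,
                         colClasses = "character")
  dimnames(m) <- list(readLines(file.path(dir, "barcodes.tsv")), f[[1L]])
  m
}

#' Read a dense count table
#'
#' @param path CSV or TSV file with row and column names.
#' @param cells_in `"rows"` or `"cols"`: orientation of the table.
#' @param sep field separator (default inferred from the extension).
#' @return cells x genes integer matrix.
#' @export
read_dense_counts <- function(path, cells_in = c("rows", "cols"),
                              sep = NULL) {
  cells_in <- match.arg(cells_in)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- as.matrix(utils::read.table(path, sep = sep, header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  if (cells_in == "cols") m <- t(m)
  storage.mode(m) <- "integer"
  m
}
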