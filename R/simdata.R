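#' Planted regulon description
#'
#' A regulon is a transcription factor together with the target genes it
#' co-regulates. A *planted* regulon additionally names the clusters in
#' which the whole program is switched on, which gives downstream scoring
#' and network stages an exact ground truth.
#'
#' @param name TF gene id (must not appear among its own targets).
#' @param targets character vector of target gene ids.
#' @param active_clusters integer vector of 1-based cluster indices in
#'   which the regulon (TF and targets) is elevated.
#' @return An object of class `planted_regulon`.
#' @export
planted_regulon <- function(name, targets, active_clusters) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(targets), length(targets) >= 1L)
  if (name %in% targets)
    stop("regulon '", name, "' lists its own TF among its targets")
  if (length(active_clusters) == 0L)
    stop("regulon '", name, "' has no active clusters")
  structure(list(name = name, targets = unique(targets),
                 active_clusters = as.integer(sort(unique(active_clusters)))),
            class = "planted_regulon")
}

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic single-cell experiment:
#' `n_clusters` cell states ordered along a latent pseudotime in [0, 1],
#' negative-binomial counts with logistic dropout, planted regulons
#' elevated by `active_fold_change` in their active clusters, marker genes
#' with monotone pseudotime trends, and (optionally) decoy genes plus
#' deliberately low-quality cells for exercising QC.
#'
#' Counts are NB(mean, size = `dispersion`). The dropout probability of a
#' count with underlying mean `mu` is `plogis(-dropout_slope * (log(mu) -
#' dropout_midpoint))`, applied as independent post-hoc zeroing. Marker-up
#' genes have mean `mu0 * (1 + marker_coef * t)` at pseudotime `t`, and
#' marker-down genes `mu0 * (1 + marker_coef * (1 - t))`.
#'
#' @param n_clusters number of clusters (equal-width pseudotime bins).
#' @param cells_per_cluster cells per cluster.
#' @param n_genes number of background genes `G0001..`; regulon TFs and
#'   targets must be drawn from this universe.
#' @param regulons list of [planted_regulon()] objects (may be empty).
#' @param baseline_mean NB mean of an unregulated gene (mu0).
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param active_fold_change fold change applied to the TF and targets of
#'   a regulon in cells of its active clusters; must exceed 1 when any
#'   regulon is planted.
#' @param dropout_midpoint log-mean at which the dropout probability is 0.5.
#' @param dropout_slope slope of the logistic dropout curve; 0 disables
#'   dropout entirely.
#' @param n_marker_up,n_marker_down numbers of monotone marker genes.
#' @param marker_coef trend strength `c` of the marker means.
#' @param n_qc_bad_cells cells appended that each violate exactly one QC
#'   rule (cycled: too few genes, too many genes, high mitochondrial
#'   fraction, missing RUNX2).
#' @param include_decoy_genes add MT-1..MT-10, HBM/HBA1/HBA2/HBB and RUNX2
#'   rows so that QC rules have something to act on.
#' @param branch if `TRUE`, cells in the upper half of pseudotime are
#'   split across two branch flags (a simple bifurcation).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 3L, cells_per_cluster = 200L,
                       n_genes = 200L, regulons = default_regulons(),
                       baseline_mean = 2, dispersion = 2,
                       active_fold_change = 8,
                       dropout_midpoint = 0, dropout_slope = 1,
                       n_marker_up = 10L, n_marker_down = 10L,
                       marker_coef = 3,
                       n_qc_bad_cells = 0L, include_decoy_genes = FALSE,
                       branch = FALSE, seed = 1L) {
  if (n_clusters < 1L || cells_per_cluster < 1L || n_genes < 1L)
    stop("n_clusters, cells_per_cluster and n_genes must be positive")
  if (baseline_mean <= 0 || dispersion <= 0)
    stop("baseline_mean and dispersion must be positive")
  if (length(regulons) > 0L && active_fold_change <= 1)
    stop("active_fold_change must exceed 1 when regulons are planted")
  universe <- sprintf("G%04d", seq_len(n_genes))
  for (r in regulons) {
    stopifnot(inherits(r, "planted_regulon"))
    unknown <- setdiff(c(r$name, r$targets), universe)
    if (length(unknown))
      stop("regulon '", r$name, "' references genes outside the simulated ",
           "universe: ", paste(unknown, collapse = ", "))
    if (any(r$active_clusters > n_clusters))
      stop("regulon '", r$name, "' active in a cluster index > n_clusters")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 n_genes = as.integer(n_genes), regulons = regulons,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 active_fold_change = active_fold_change,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 n_marker_up = as.integer(n_marker_up),
                 n_marker_down = as.integer(n_marker_down),
                 marker_coef = marker_coef,
                 n_qc_bad_cells = as.integer(n_qc_bad_cells),
                 include_decoy_genes = isTRUE(include_decoy_genes),
                 branch = isTRUE(branch), seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted regulons
#'
#' Two non-overlapping ten-target regulons: one active in the first
#' (earliest) cluster, one in the last (most mature) — the synthetic
#' analogue of an early-stage and a late-stage transcriptional program.
#'
#' @param n_clusters number of clusters the programs are placed into.
#' @return list of two [planted_regulon()] objects.
#' @export
default_regulons <- function(n_clusters = 3L) {
  list(planted_regulon("G0001", sprintf("G%04d", 2:11), 1L),
       planted_regulon("G0012", sprintf("G%04d", 13:22), n_clusters))
}

decoy_gene_ids <- function() {
  c(sprintf("MT-%d", 1:10), "HBM", "HBA1", "HBA2", "HBB", "RUNX2")
}

#' Simulate a single-cell counts dataset with planted structure
#'
#' @param config a [sim_config()].
#' @return An object of class `synthetic_dataset` with elements
#'   `counts` (cells x genes integer matrix with dimnames),
#'   `true_labels` (integer cluster per cell), `true_pseudotime` (in
#'   [0, 1]), `branch` (integer branch flag, all 1 unless branching),
#'   `regulon_truth` (list: `regulons` as a named list of target vectors,
#'   `activity_design` regulon x cluster binary matrix), `qc_truth`
#'   (logical, `TRUE` = should survive QC), `qc_rule` (the rule each bad
#'   cell violates) and `qc_params` ([qc_params()] scaled to this gene
#'   universe).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_clusters
  n_good <- K * config$cells_per_cluster
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  if (config$include_decoy_genes) genes <- c(genes, decoy_gene_ids())
  G <- length(genes)

  # stratified pseudotime: cluster j covers [ (j-1)/K, j/K )
  t_good <- (rep(seq_len(K), each = config$cells_per_cluster) - 1 +
             stats::runif(n_good)) / K
  labels <- pmin(floor(t_good * K) + 1L, K)
  branch <- rep(1L, n_good)
  if (config$branch) {
    upper <- t_good > 0.5
    branch[upper] <- 1L + stats::rbinom(sum(upper), 1L, 0.5)
  }

  # per-gene x per-cell mean matrix (cells x genes)
  mu <- matrix(config$baseline_mean, nrow = n_good, ncol = G,
               dimnames = list(NULL, genes))
  design <- matrix(0L, nrow = length(config$regulons), ncol = K,
                   dimnames = list(vapply(config$regulons, `[[`, "", "name"),
                                   paste0("cluster", seq_len(K))))
  for (i in seq_along(config$regulons)) {
    r <- config$regulons[[i]]
    design[i, r$active_clusters] <- 1L
    active_cells <- labels %in% r$active_clusters
    mu[active_cells, c(r$name, r$targets)] <-
      mu[active_cells, c(r$name, r$targets)] * config$active_fold_change
  }
  marker_up <- marker_down <- character(0)
  if (config$n_marker_up + config$n_marker_down > 0L) {
    pool <- setdiff(genes, c(unlist(lapply(config$regulons, function(r)
      c(r$name, r$targets))), decoy_gene_ids()))
    marker_up <- utils::tail(pool, config$n_marker_up + config$n_marker_down)
    marker_down <- utils::head(marker_up, config$n_marker_down)
    marker_up <- setdiff(marker_up, marker_down)
    mu[, marker_up] <- mu[, marker_up] *
      (1 + config$marker_coef * t_good)
    mu[, marker_down] <- mu[, marker_down] *
      (1 + config$marker_coef * (1 - t_good))
  }
  if (config$include_decoy_genes) {
    # hemoglobin decoys silent in good cells; RUNX2 modestly expressed
    mu[, c("HBM", "HBA1", "HBA2", "HBB")] <- 0
    mu[, "RUNX2"] <- config$baseline_mean * 2
  }

  counts <- matrix(0L, nrow = n_good, ncol = G)
  nz <- mu > 0
  counts[nz] <- stats::rnbinom(sum(nz), mu = mu[nz],
                               size = config$dispersion)
  if (config$dropout_slope != 0) {
    p_drop <- matrix(0, n_good, G)
    p_drop[nz] <- stats::plogis(-config$dropout_slope *
                                (log(mu[nz]) - config$dropout_midpoint))
    drop <- matrix(stats::runif(n_good * G), n_good, G) < p_drop
    counts[drop] <- 0L
  }
  dimnames(counts) <- list(sprintf("C%04d", seq_len(n_good)), genes)
  if (config$include_decoy_genes) {
    counts[, "RUNX2"] <- pmax(counts[, "RUNX2"], 1L)  # guaranteed marker
    # keep good cells safely under the mito ceiling (<= 12% of counts),
    # so the QC truth flag is exact rather than probabilistic
    mt <- sprintf("MT-%d", 1:10)
    mt_tot <- rowSums(counts[, mt, drop = FALSE])
    allowed <- floor(0.12 * rowSums(counts))
    over <- which(mt_tot > allowed)
    for (i in over)
      counts[i, mt] <- as.integer(floor(counts[i, mt] *
                                        allowed[i] / mt_tot[i]))
  }

  qc_truth <- rep(TRUE, n_good)
  qc_rule <- rep(NA_character_, n_good)
  qc <- NULL
  if (config$include_decoy_genes) {
    qc <- qc_params(min_genes = max(2L, round(0.10 * G)),
                    max_genes = round(0.95 * G))
    if (config$n_qc_bad_cells > 0L) {
      types <- rep(c("low", "high", "mito", "marker"),
                   length.out = config$n_qc_bad_cells)
      bad <- matrix(0L, nrow = config$n_qc_bad_cells, ncol = G,
                    dimnames = list(sprintf("C%04d", n_good +
                                            seq_len(config$n_qc_bad_cells)),
                                    genes))
      template <- counts[sample.int(n_good, config$n_qc_bad_cells,
                                    replace = TRUE), , drop = FALSE]
      for (i in seq_len(config$n_qc_bad_cells)) {
        row <- template[i, ]
        row["RUNX2"] <- max(row["RUNX2"], 1L)
        row[c("HBM", "HBA1", "HBA2", "HBB")] <- 0L
        switch(types[i],
          low = {  # keep only a handful of non-decoy genes (plus RUNX2)
            keep <- c(utils::head(setdiff(genes[row > 0], decoy_gene_ids()),
                                  max(1L, qc$min_genes - 3L) - 1L), "RUNX2")
            row[setdiff(genes, keep)] <- 0L
          },
          high = {                                # every non-excluded gene on
            row[row == 0L] <- 1L
            row[c("HBM", "HBA1", "HBA2", "HBB")] <- 0L
          },
          mito = row[sprintf("MT-%d", 1:10)] <-   # ~50% mito mass
            as.integer(ceiling(sum(row) / 10)),
          marker = row["RUNX2"] <- 0L)
        bad[i, ] <- row
      }
      counts <- rbind(counts, bad)
      labels <- c(labels, rep(NA_integer_, config$n_qc_bad_cells))
      t_good <- c(t_good, rep(NA_real_, config$n_qc_bad_cells))
      branch <- c(branch, rep(NA_integer_, config$n_qc_bad_cells))
      qc_truth <- c(qc_truth, rep(FALSE, config$n_qc_bad_cells))
      qc_rule <- c(qc_rule, types)
    }
  }
  storage.mode(counts) <- "integer"

  regs <- lapply(config$regulons, `[[`, "targets")
  names(regs) <- vapply(config$regulons, `[[`, "", "name")
  structure(list(counts = counts, true_labels = labels,
                 true_pseudotime = t_good, branch = branch,
                 regulon_truth = list(regulons = regs,
                                      activity_design = design),
                 marker_genes = list(up = marker_up, down = marker_down),
                 qc_truth = qc_truth, qc_rule = qc_rule, qc_params = qc,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$counts), "cells x", ncol(x$counts),
      "genes;", x$config$n_clusters, "clusters;",
      length(x$regulon_truth$regulons), "planted regulons;",
      sum(!x$qc_truth), "planted low-quality cells\n")
  invisible(x)
}

#' Simulate a weighted interaction graph with planted cliques
#'
#' Erdos-Renyi background over `n_background` nodes (edge probability
#' `p_background`, weights uniform in [0.4, 1]) plus fully connected
#' planted cliques on extra nodes with weights >= 0.9.
#'
#' @param n_background number of background nodes.
#' @param planted_cliques integer vector of clique sizes (each >= 3).
#' @param p_background background edge probability in [0, 1).
#' @param seed integer seed.
#' @return list with `edges` (data.frame: node_a, node_b, combined_score)
#'   and `truth` (list of clique member-id vectors).
#' @export
simulate_ppi_graph <- function(n_background, planted_cliques = integer(0),
                               p_background = 0.02, seed = 1L) {
  if (length(planted_cliques) && any(planted_cliques < 3L))
    stop("planted clique sizes must be >= 3")
  if (p_background < 0 || p_background >= 1)
    stop("p_background must be in [0, 1)")
  set.seed(seed)
  bg <- sprintf("B%03d", seq_len(n_background))
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      combined_score = numeric(0))
  if (n_background >= 2L && p_background > 0) {
    pairs <- utils::combn(bg, 2L)
    keep <- stats::runif(ncol(pairs)) < p_background
    if (any(keep))
      edges <- data.frame(node_a = pairs[1L, keep], node_b = pairs[2L, keep],
                          combined_score = stats::runif(sum(keep), 0.4, 1.0))
  }
  truth <- list()
  next_id <- 1L
  for (s in planted_cliques) {
    members <- sprintf("M%03d", next_id:(next_id + s - 1L))
    next_id <- next_id + s
    pairs <- utils::combn(members, 2L)
    edges <- rbind(edges,
                   data.frame(node_a = pairs[1L, ], node_b = pairs[2L, ],
                              combined_score = stats::runif(ncol(pairs),
                                                            0.9, 1.0)))
    truth[[length(truth) + 1L]] <- members
  }
  rownames(edges) <- NULL
  list(edges = edges, truth = truth)
}

#' Write a synthetic dataset as a 10x-style Matrix Market triple
#'
#' Emits `matrix.mtx` (genes x cells, as in the 10x dialect),
#' `features.tsv`, `barcodes.tsv`, truth tables (`truth_labels.tsv`,
#' `truth_pseudotime.tsv`, `truth_qc.tsv`), the regulons as
#' `regulons.gmt` and a JSON echo of the configuration.
#'
#' @param ds a `synthetic_dataset`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$counts), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(out_dir, "matrix.mtx"))
  utils::write.table(data.frame(id = colnames(ds$counts),
                                symbol = colnames(ds$counts)),
                     file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(ds$counts), file.path(out_dir, "barcodes.tsv"))
  utils::write.table(data.frame(barcode = rownames(ds$counts),
                                cluster = ds$true_labels),
                     file.path(out_dir, "truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = rownames(ds$counts),
                                pseudotime = ds$true_pseudotime,
                                branch = ds$branch),
                     file.path(out_dir, "truth_pseudotime.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(barcode = rownames(ds$counts),
                                qc_pass = ds$qc_truth, rule = ds$qc_rule),
                     file.path(out_dir, "truth_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(ds$regulon_truth$regulons, file.path(out_dir, "regulons.gmt"))
  cfg <- ds$config
  cfg$regulons <- lapply(cfg$regulons, unclass)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(out_dir,
                      c("matrix.mtx", "features.tsv", "barcodes.tsv",
                        "truth_labels.tsv", "truth_pseudotime.tsv",
                        "truth_qc.tsv", "regulons.gmt", "config.json")))
}
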