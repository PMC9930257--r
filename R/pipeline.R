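stage_seed <- function(global_seed, stage) {
  # deterministic per-stage child seed, kept inside 32-bit integer range
  (as.integer(global_seed) %% 100000L) * 10000L +
    sum(utf8ToInt(stage)) %% 10000L
}

write_tsv_commented <- function(x, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s=%s", k, header[[k]]), con)
  df <- as.data.frame(x)
  if (!identical(rownames(df), as.character(seq_len(nrow(df)))))
    df <- cbind(id = rownames(df), df)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

pipeline_defaults <- function() {
  list(simulate = NULL, input_dir = NULL, regulons_gmt = NULL,
       labels_tsv = NULL,
       qc = list(min_genes = 200L, max_genes = 5000L, max_mito_frac = 0.15),
       normalize = list(scale_total = 10000),
       hvg = list(n_top = 2000L),
       pca = list(n_pcs = 18L),
       cluster = list(k = 3L, source = "expression"),
       score = list(top_frac = 0.05, tie_seed = NULL),
       csn = list(enabled = TRUE, box_frac = 0.1, alpha = 0.01,
                  gene_subset = NULL),
       trajectory = list(enabled = TRUE, input = "expression",
                         n_comps = 10L, k_neighbors = 30L,
                         root_cluster = NULL),
       gsea = list(enabled = FALSE, gmt = NULL, cluster = NULL,
                   n_perm = 1000L),
       out_dir = "pipeline_out", seed = 1L)
}

merge_strict <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key: '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        is.list(user[[key]]) && !is.null(names(defaults[[key]])))
      defaults[[key]] <- merge_strict(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or already-parsed list) configuration, fills defaults,
#' rejects unknown keys by name and range-checks the numeric knobs. A
#' configuration either has a `simulate` block (a [sim_config()] argument
#' list) or an `input_dir` pointing at a Matrix Market triple.
#'
#' @param path YAML file path, or a named list.
#' @return validated config of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- merge_strict(pipeline_defaults(), user)
  if (is.null(cfg$simulate) && is.null(cfg$input_dir))
    stop("config needs either a 'simulate' block or 'input_dir'")
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir))
    stop("input_dir does not exist: ", cfg$input_dir)
  for (f in c("regulons_gmt", "labels_tsv"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(f, " does not exist: ", cfg[[f]])
  if (cfg$csn$box_frac <= 0 || cfg$csn$box_frac > 1)
    stop("csn.box_frac must be in (0, 1]")
  if (cfg$csn$alpha <= 0 || cfg$csn$alpha >= 1)
    stop("csn.alpha must be in (0, 1)")
  if (cfg$score$top_frac <= 0 || cfg$score$top_frac > 1)
    stop("score.top_frac must be in (0, 1]")
  if (cfg$qc$min_genes >= cfg$qc$max_genes)
    stop("qc.min_genes must be < qc.max_genes")
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end regulon-activity analysis
#'
#' Stages, in order: simulate (or ingest) counts, QC, normalization, HVG
#' selection, PCA, clustering (k-means on the chosen space, or external
#' labels), regulon AUC scoring, cell-specific networks with NDM and the
#' per-cluster differential NDM test, diffusion-map pseudotime with
#' cluster transition summaries, and (optionally) cluster-vs-rest GSEA.
#' Every stochastic stage consumes a child seed derived from the global
#' seed and the stage name, so a rerun of the same configuration
#' reproduces every output byte for byte. Tabular outputs are TSV with
#' `# key=value` comment headers; the run report is JSON.
#'
#' @param config a [validate_config()] result (or something coercible).
#' @return the run report (invisibly a list; written to
#'   `<out_dir>/run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- ingest ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- stage_seed(config$seed, "simulate")
    if (!is.null(sim_args$regulons) && is.character(sim_args$regulons[[1]]))
      stop("simulate.regulons must be built in R; use the default")
    ds <- run_stage("simulate", simulate_counts(do.call(sim_config, sim_args)))
    counts <- ds$counts
    truth <- ds
    regulons <- ds$regulon_truth$regulons
    qc <- if (!is.null(ds$qc_params)) ds$qc_params else qc_params()
    note("simulate", cells = nrow(counts), genes = ncol(counts),
         regulons = length(regulons))
  } else {
    counts <- run_stage("ingest", read_tenx(config$input_dir))
    regulons <- NULL
    qc <- qc_params(min_genes = config$qc$min_genes,
                    max_genes = config$qc$max_genes,
                    max_mito_frac = config$qc$max_mito_frac)
    note("ingest", cells = nrow(counts), genes = ncol(counts))
  }
  if (!is.null(config$regulons_gmt))
    regulons <- read_gmt(config$regulons_gmt)
  if (is.null(regulons)) stop("no regulons: supply regulons_gmt or simulate")

  # --- qc + normalize -------------------------------------------------
  qcres <- run_stage("qc", qc_filter(counts, qc))
  counts <- qcres$counts
  note("qc", survivors = nrow(counts),
       removed = qcres$report[setdiff(names(qcres$report), "warnings")])
  norm <- run_stage("normalize",
                    normalize_log(counts, config$normalize$scale_total))

  # --- hvg + pca ------------------------------------------------------
  hvg <- run_stage("hvg",
                   select_hvg(norm, min(config$hvg$n_top, ncol(norm))))
  pca <- run_stage("pca",
                   run_pca(norm, hvg,
                           n_pcs = min(config$pca$n_pcs, length(hvg),
                                       nrow(norm) - 1L)))
  note("pca", n_pcs = ncol(pca$embedding),
       variance_pct_kept = sum(pca$variance_pct[seq_len(
         ncol(pca$embedding))]))

  # --- regulon scoring ------------------------------------------------
  tie_seed <- if (is.null(config$score$tie_seed))
    stage_seed(config$seed, "rank") else config$score$tie_seed
  ranks <- run_stage("rank", rank_genes_per_cell(norm, tie_seed))
  activity <- run_stage("score",
                        score_all(ranks, regulons, config$score$top_frac))
  note("score", regulons_scored = ncol(activity))

  # --- clustering -----------------------------------------------------
  labels <- if (!is.null(config$labels_tsv)) {
    lab <- utils::read.table(config$labels_tsv, sep = "\t", header = TRUE,
                             comment.char = "#")
    stats::setNames(lab[[2L]], lab[[1L]])[rownames(counts)]
  } else {
    space <- if (config$cluster$source == "activity") activity
             else pca$embedding
    run_stage("cluster",
              cluster_cells(space, config$cluster$k,
                            seed = stage_seed(config$seed, "cluster")))
  }
  note("cluster", k = length(unique(labels)))

  diff_act <- run_stage("diff_activity",
                        differential_activity(activity, labels))

  # --- csn ------------------------------------------------------------
  csn_res <- NULL
  if (isTRUE(config$csn$enabled)) {
    subset <- config$csn$gene_subset
    if (is.null(subset))
      subset <- intersect(unique(c(names(regulons), unlist(regulons))),
                          colnames(norm))
    csn_res <- run_stage("csn",
      build_csn(norm, csn_params(config$csn$box_frac, config$csn$alpha,
                                 subset)))
    note("csn", genes = nrow(csn_res$ndm), edge_calls = nrow(csn_res$edges))
  }

  # --- trajectory -----------------------------------------------------
  traj <- NULL
  if (isTRUE(config$trajectory$enabled)) {
    X <- if (config$trajectory$input == "activity") activity
         else pca$embedding
    dm <- run_stage("trajectory",
                    diffusion_map(X, n_comps = min(config$trajectory$n_comps,
                                                   nrow(X) - 2L),
                                  k_neighbors = config$trajectory$k_neighbors))
    root_cluster <- config$trajectory$root_cluster
    if (is.null(root_cluster)) root_cluster <- sort(unique(labels))[1L]
    root <- select_root_cell(dm, labels, root_cluster)
    dm <- diffusion_pseudotime(dm, root)
    traj <- list(map = dm,
                 transitions = cluster_transitions(dm, labels))
    note("trajectory", root_cell = dm$root_cell,
         components = ncol(dm$components))
  }

  # --- gsea -----------------------------------------------------------
  gsea_res <- NULL
  if (isTRUE(config$gsea$enabled)) {
    gsets <- read_gmt(config$gsea$gmt)
    gcl <- config$gsea$cluster
    if (is.null(gcl)) gcl <- sort(unique(labels))[1L]
    ranked <- rank_cluster_vs_rest(norm, labels, gcl)
    gsea_res <- run_stage("gsea",
      preranked_gsea(ranked, gsets, n_perm = config$gsea$n_perm,
                     seed = stage_seed(config$seed, "gsea")))
    note("gsea", sets_tested = nrow(gsea_res),
         significant = sum(gsea_res$significant))
  }

  # --- outputs --------------------------------------------------------
  hdr <- list(seed = config$seed)
  out <- function(f) file.path(config$out_dir, f)
  write_tsv_commented(as.data.frame(as.matrix(activity)),
                      out("activity.tsv"), hdr)
  write_tsv_commented(data.frame(cell = rownames(counts), label = labels),
                      out("labels.tsv"), hdr)
  write_tsv_commented(diff_act, out("differential_activity.tsv"), hdr)
  if (!is.null(csn_res)) {
    write_tsv_commented(as.data.frame(csn_res$ndm), out("ndm.tsv"), hdr)
    write_tsv_commented(csn_res$edges, out("csn_edges.tsv"), hdr)
  }
  if (!is.null(traj)) {
    write_tsv_commented(data.frame(cell = rownames(counts),
                                   pseudotime = traj$map$pseudotime),
                        out("pseudotime.tsv"), hdr)
    write_tsv_commented(as.data.frame(traj$transitions),
                        out("cluster_transitions.tsv"), hdr)
  }
  if (!is.null(gsea_res))
    write_tsv_commented(gsea_res, out("gsea.tsv"), hdr)
  report$outputs <- list.files(config$out_dir)
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(report = report, counts = counts, norm = norm,
                 activity = activity, labels = labels,
                 differential_activity = diff_act, csn = csn_res,
                 trajectory = traj, gsea = gsea_res, pca = pca,
                 truth = truth))
}
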