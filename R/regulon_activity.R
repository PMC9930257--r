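#' Read gene sets in GMT format
#'
#' One set per line: name, description, then the member genes, all
#' tab-separated. For regulons the convention is name = TF, description =
#' motif annotation, members = target genes.
#'
#' @param path GMT file.
#' @return named list of character vectors; per-set descriptions are kept
#'   in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (default `"."`).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep(".", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L)), path)
  invisible(path)
}

#' Rank genes within each cell
#'
#' Per cell, genes are ordered by decreasing expression (rank 1 = highest).
#' Ties — in scRNA-seq dominated by the zero block — are broken by a
#' seeded random shuffle so the ranking is a proper permutation and the
#' downstream recovery-curve AUC is well defined; the same seed always
#' yields the same permutation.
#'
#' @param norm cells x genes expression matrix.
#' @param tie_seed integer seed for the tie-breaking shuffle.
#' @return object of class `rank_matrix`: cells x genes integer matrix,
#'   each row a permutation of `1..G`, with attribute `tie_seed`.
#' @export
rank_genes_per_cell <- function(norm, tie_seed = 1L) {
  if (nrow(norm) == 0L || ncol(norm) == 0L) stop("empty matrix")
  set.seed(tie_seed)
  G <- ncol(norm)
  ranks <- t(apply(norm, 1L, function(x)
    rank(-x, ties.method = "random")))
  dimnames(ranks) <- dimnames(norm)
  storage.mode(ranks) <- "integer"
  structure(ranks, tie_seed = tie_seed, class = c("rank_matrix", "matrix",
                                                  "array"))
}

#' Recovery-curve AUC of a gene set in each cell
#'
#' With `G` genes and `T = ceiling(top_frac * G)`, the recovery curve of a
#' set `S` counts `hits(t) = #{g in S : rank_g <= t}` over the top block.
#' The score is the left-rectangle area `sum_{t=1}^{T-1} hits(t)`
#' normalized by its maximum `sum_{t=1}^{T-1} min(t, |S|)`, so it lies in
#' [0, 1] and equals 1 exactly when the set packs the top ranks.
#'
#' @param ranks a [rank_genes_per_cell()] matrix.
#' @param gene_set character vector of gene ids; genes absent from the
#'   matrix are dropped with a warning.
#' @param top_frac fraction of top-ranked genes integrated over
#'   (default 0.05).
#' @return numeric vector: per-cell AUC in [0, 1].
#' @export
aucell_score <- function(ranks, gene_set, top_frac = 0.05) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  G <- ncol(ranks)
  T_top <- ceiling(top_frac * G)
  if (T_top < 2L) stop("top block too small (T = ", T_top,
                       "); increase top_frac")
  usable <- intersect(gene_set, colnames(ranks))
  if (length(usable) < length(gene_set))
    warning(length(gene_set) - length(usable),
            " gene(s) of the set absent from the rank matrix")
  if (length(usable) == 0L) stop("no usable genes in the set")
  r <- ranks[, usable, drop = FALSE]
  # raw = sum over set genes of (T - 1 - rank + 1) for rank <= T-1
  inside <- r <= (T_top - 1L)
  raw <- rowSums(ifelse(inside, T_top - r, 0))
  s <- length(usable)
  mx <- sum(pmin(seq_len(T_top - 1L), s))
  as.numeric(raw / mx)
}

#' Score a whole regulon collection
#'
#' Applies [aucell_score()] to every entry of a regulon set; columns keep
#' the input order. Regulons with no usable genes yield an `NA` column
#' with a warning.
#'
#' @param ranks a [rank_genes_per_cell()] matrix.
#' @param regulons named list of target-gene vectors (e.g. [read_gmt()]).
#' @param top_frac as in [aucell_score()].
#' @return object of class `activity_matrix`: cells x regulons numeric
#'   matrix in [0, 1] with attribute `top_frac`.
#' @export
score_all <- function(ranks, regulons, top_frac = 0.05) {
  stopifnot(length(regulons) > 0L, !is.null(names(regulons)))
  auc <- matrix(NA_real_, nrow = nrow(ranks), ncol = length(regulons),
                dimnames = list(rownames(ranks), names(regulons)))
  for (j in seq_along(regulons)) {
    col <- tryCatch(aucell_score(ranks, regulons[[j]], top_frac),
                    error = function(e) {
                      warning("regulon '", names(regulons)[j],
                              "' not scorable: ", conditionMessage(e))
                      rep(NA_real_, nrow(ranks))
                    })
    auc[, j] <- col
  }
  structure(auc, top_frac = top_frac,
            class = c("activity_matrix", "matrix", "array"))
}

#' Kruskal-Wallis differential test across groups
#'
#' Per feature (column), a Kruskal-Wallis rank-sum test of the values
#' across the label groups, with tie correction and the chi-squared
#' approximation, followed by Benjamini-Hochberg adjustment across
#' features. Features constant over all cells are reported untestable
#' (`NA` statistic and p) and excluded from the adjustment.
#'
#' @param values cells x features numeric matrix.
#' @param labels group label per cell (>= 2 groups, each >= 2 cells).
#' @return data.frame: feature, statistic, p_value, p_adjusted, and the
#'   per-group medians.
#' @export
differential_activity <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two groups")
  if (any(table(labels) < 2L)) stop("every group needs >= 2 cells")
  if (ncol(values) == 0L) stop("no features to test")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  res <- data.frame(feature = colnames(values),
                    statistic = NA_real_, p_value = NA_real_)
  meds <- matrix(NA_real_, ncol(values), nlevels(labels),
                 dimnames = list(colnames(values),
                                 paste0("median_", levels(labels))))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    meds[j, ] <- tapply(x, labels, stats::median)
    if (length(unique(x)) > 1L) {
      kw <- stats::kruskal.test(x, labels)
      res$statistic[j] <- unname(kw$statistic)
      res$p_value[j] <- kw$p.value
    }
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  cbind(res, as.data.frame(meds))
}

#' Summarize features by cluster
#'
#' Per-cluster mean (or median) of each feature, optionally z-scaled
#' across clusters for display (a constant feature z-scales to 0).
#'
#' @param values cells x features matrix.
#' @param labels cluster label per cell.
#' @param stat `"mean"` or `"median"`.
#' @param row_scale `"z"` or `"none"`.
#' @return clusters x features numeric matrix.
#' @export
summarize_by_cluster <- function(values, labels, stat = c("mean", "median"),
                                 row_scale = c("none", "z")) {
  stat <- match.arg(stat)
  row_scale <- match.arg(row_scale)
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop("empty cluster")
  f <- if (stat == "mean") mean else stats::median
  out <- t(vapply(levels(labels), function(l)
    apply(values[labels == l, , drop = FALSE], 2L, f),
    numeric(ncol(values))))
  rownames(out) <- levels(labels)
  if (row_scale == "z") {
    out <- apply(out, 2L, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
    rownames(out) <- levels(labels)
  }
  out
}
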