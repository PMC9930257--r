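# toy 5-cell matrix where cells 1-4 each violate exactly one QC rule
toy_qc_matrix <- function() {
  genes <- c(paste0("g", 1:7000), "MT-1", "RUNX2", "HBB")
  m <- matrix(0L, 5, length(genes), dimnames = list(paste0("c", 1:5), genes))
  m[1, c(paste0("g", 1:119), "RUNX2")] <- 1L            # 120 detected: low
  m[2, c(paste0("g", 1:6000), "RUNX2")] <- 1L           # 6001 detected: high
  m[3, paste0("g", 1:800)] <- 1L                        # 20% mito
  m[3, "MT-1"] <- 200L
  m[3, "RUNX2"] <- 1L
  m[4, paste0("g", 1:800)] <- 1L                        # RUNX2 absent
  m[5, paste0("g", 1:800)] <- 1L                        # passes
  m[5, "RUNX2"] <- 1L
  m
}

test_that("qc_filter enumerates the four violation rules on a toy matrix", {
  res <- qc_filter(toy_qc_matrix(), qc_params())
  expect_equal(rownames(res$counts), "c5")
  expect_equal(res$report[c("low", "high", "mito", "marker", "excluded")],
               list(low = 1L, high = 1L, mito = 1L, marker = 1L,
                    excluded = 0L))
})

test_that("a vacuous filter keeps every cell and filtering is idempotent", {
  m <- toy_qc_matrix()
  loose <- qc_params(min_genes = 0, max_genes = .Machine$integer.max,
                     max_mito_frac = 1, required_positive_genes = character(0),
                     excluded_if_expressed = character(0))
  expect_equal(nrow(qc_filter(m, loose)$counts), 5)
  # idempotence under the strict defaults
  once <- qc_filter(m, qc_params())$counts
  twice <- qc_filter(once, qc_params())
  expect_identical(twice$counts, once)
  expect_true(all(unlist(twice$report[1:5]) == 0))
})

test_that("qc defaults match the standard droplet thresholds", {
  p <- qc_params()
  expect_equal(p$min_genes, 200L)
  expect_equal(p$max_genes, 5000L)
  expect_equal(p$max_mito_frac, 0.15)
  expect_equal(p$required_positive_genes, "RUNX2")
  expect_setequal(p$excluded_if_expressed, c("HBM", "HBA1", "HBA2", "HBB"))
})

test_that("qc_filter removes exactly the planted low-quality cells", {
  ds <- simulate_counts(sim_config(cells_per_cluster = 40, n_genes = 100,
                                   n_qc_bad_cells = 8,
                                   include_decoy_genes = TRUE, seed = 6))
  res <- qc_filter(ds$counts, ds$qc_params)
  expect_identical(unname(res$keep), ds$qc_truth)
})

test_that("normalization scales cells to the target total before log1p", {
  m <- matrix(c(1, 1, 2), 1, 3, dimnames = list("c1", paste0("g", 1:3)))
  norm <- normalize_log(m)
  expect_equal(expm1(as.numeric(norm)), c(2500, 2500, 5000))
  expect_equal(sum(expm1(norm[1, ])), 10000)
  expect_equal(normalize_log(matrix(c(0, 5), 1, 2))[1, 1], 0)
  expect_error(normalize_log(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("normalization is invariant to per-cell scaling of counts", {
  set.seed(1)
  m <- matrix(rpois(60, 4) + 1, 4, 15)
  m2 <- m
  m2[2, ] <- m2[2, ] * 7L
  expect_equal(unclass(normalize_log(m)), unclass(normalize_log(m2)))
  # expm1 row sums reproduce the scale for every cell
  n <- normalize_log(m, scale_total = 10000)
  expect_equal(unname(rowSums(expm1(n))), rep(10000, 4))
})

test_that("hvg selection finds the variable genes", {
  set.seed(3)
  m <- matrix(1, 30, 20, dimnames = list(NULL, sprintf("g%02d", 1:20)))
  m[, 1:10] <- m[, 1:10] + matrix(rpois(300, 6), 30, 10)
  norm <- structure(m, class = c("norm_matrix", "matrix", "array"))
  expect_setequal(select_hvg(norm, 10), sprintf("g%02d", 1:10))
  expect_equal(length(select_hvg(norm, 20)), 20)
  expect_error(select_hvg(norm, 21), "exceeds")
})

test_that("pca reports a full variance spectrum with ordered stdevs", {
  set.seed(8)
  base <- rnorm(40)
  x <- outer(base, seq(1, 3, length.out = 12))        # exactly rank 1
  x <- x + matrix(rnorm(480, sd = 1e-8), 40, 12)
  colnames(x) <- paste0("g", 1:12)
  res <- run_pca(x, n_pcs = 3, unit_scale = FALSE)
  expect_gt(res$variance_pct[1], 99.99)
  expect_true(all(diff(res$stdevs) <= 1e-8))
  expect_equal(sum(res$variance_pct), 100)
  expect_equal(dim(res$embedding), c(40, 3))
})

test_that("variance_explained is the squared-stdev share", {
  expect_equal(variance_explained(c(3, 1)), c(90, 10))
  expect_equal(variance_explained(5), 100)
  expect_equal(variance_explained(c(1, 1, 1, 1)), rep(25, 4))
  expect_equal(sum(variance_explained(runif(7))), 100, tolerance = 1e-9)
  expect_error(variance_explained(c(0, 0)), "all-zero")
})

test_that("k-means recovers separated blobs deterministically", {
  set.seed(11)
  emb <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
               matrix(rnorm(40, 5, 0.2), 20, 2))
  truth <- rep(1:2, each = 20)
  lab <- cluster_cells(emb, 2, seed = 5)
  expect_equal(length(unique(paste(lab, truth))), 2)   # exact up to relabel
  expect_identical(lab, cluster_cells(emb, 2, seed = 5))
  expect_equal(unname(cluster_cells(emb[1:4, ], 4, seed = 1)), 1:4)
  expect_error(cluster_cells(emb, 41), "exceeds")
})
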