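test_that("per-cell gene ranking is deterministic and rank-invariant", {
  m <- matrix(c(5, 4, 3, 2, 1), 1, 5,
              dimnames = list("c1", paste0("g", 1:5)))
  expect_equal(as.numeric(rank_genes_per_cell(m, 1)), 1:5)
  # monotone transform preserves ranks
  expect_equal(rank_genes_per_cell(m^2, 3), rank_genes_per_cell(m, 3))
  # all-zero cell: a seeded permutation, reproducible
  z <- matrix(0, 1, 6, dimnames = list("c1", paste0("g", 1:6)))
  r1 <- rank_genes_per_cell(z, 42)
  expect_setequal(as.numeric(r1), 1:6)
  expect_equal(rank_genes_per_cell(z, 42), r1)
})

test_that("recovery-curve AUC matches hand-enumerated step curves", {
  r <- rank_fixture(list(1:10))
  expect_equal(aucell_score(r, c("g1", "g2"), 0.5), 1.0)
  expect_equal(aucell_score(r, c("g9", "g10"), 0.5), 0.0)
  expect_equal(aucell_score(r, c("g1", "g3"), 0.5), 6 / 7)
  expect_error(aucell_score(r, c("g1"), 0.05), "top block")
  expect_error(suppressWarnings(aucell_score(r, c("absent"), 0.5)),
               "no usable")
  expect_warning(aucell_score(r, c("g1", "nope"), 0.5), "absent")
})

test_that("AUC agrees with the brute-force step-curve oracle", {
  set.seed(17)
  for (rep in 1:20) {
    G <- sample(10:20, 1)
    perm <- sample(G)
    r <- rank_fixture(list(perm))
    s <- sample(G, sample(2:5, 1))
    frac <- runif(1, 0.2, 1)
    if (ceiling(frac * G) < 2) next
    expect_equal(aucell_score(r, paste0("g", s), frac),
                 auc_oracle(perm, s, frac))
  }
})

test_that("AUC is bounded and invariant to monotone expression changes", {
  set.seed(23)
  m <- matrix(rexp(200), 10, 20, dimnames = list(paste0("c", 1:10),
                                                 paste0("g", 1:20)))
  r1 <- rank_genes_per_cell(m, 5)
  r2 <- rank_genes_per_cell(log1p(m) * 3, 5)
  sets <- replicate(5, paste0("g", sample(20, 4)), simplify = FALSE)
  for (s in sets) {
    a <- aucell_score(r1, s, 0.5)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(a, aucell_score(r2, s, 0.5))
  }
})

test_that("mean AUC of random sets on shuffled ranks matches the null", {
  set.seed(31)
  G <- 20
  n <- 400
  ranks <- rank_fixture(lapply(seq_len(n), function(i) sample(G)))
  # oracle: mean over explicit step-curve enumeration per cell
  s <- sample(G, 4)
  mine <- mean(aucell_score(ranks, paste0("g", s), 0.5))
  oracle <- mean(vapply(seq_len(n), function(i)
    auc_oracle(ranks[i, ], s, 0.5), numeric(1L)))
  expect_equal(mine, oracle)
  # analytic null: E hits(t) = |S| t / G under uniform ranks
  T_top <- 10
  expected <- sum(4 * seq_len(T_top - 1) / G) /
    sum(pmin(seq_len(T_top - 1), 4))
  expect_lt(abs(mine - expected), 0.02)
})

test_that("score_all mirrors aucell_score column by column", {
  set.seed(7)
  m <- matrix(rexp(300), 15, 20, dimnames = list(paste0("c", 1:15),
                                                 paste0("g", 1:20)))
  r <- rank_genes_per_cell(m, 2)
  regs <- list(A = paste0("g", 1:4), B = paste0("g", 10:14),
               A2 = paste0("g", 1:4))
  act <- score_all(r, regs, top_frac = 0.5)
  expect_equal(as.numeric(act[, "A"]),
               aucell_score(r, regs$A, 0.5))
  expect_identical(act[, "A"], act[, "A2"])  # duplicated set, same column
  expect_equal(colnames(act), c("A", "B", "A2"))
})

test_that("Kruskal-Wallis statistic matches the hand-computed rank formula", {
  v <- matrix(1:9, ncol = 1)
  res <- differential_activity(v, rep(1:3, each = 3))
  expect_equal(res$statistic, 7.2)
  # identical distributions: no signal after adjustment
  set.seed(12)
  base <- rep(c(1.1, 2.2, 3.3, 4.4, 5.5), 3)
  null <- matrix(base + seq_along(base) * 1e-9, ncol = 1)
  res0 <- differential_activity(null, rep(1:3, each = 5))
  expect_gt(res0$p_adjusted, 0.05)
  # constant feature reported untestable
  resc <- differential_activity(cbind(a = rep(1, 9), b = 1:9),
                                rep(1:3, each = 3))
  expect_true(is.na(resc$p_value[resc$feature == "a"]))
  expect_error(differential_activity(v, rep(1, 9)), "two groups")
})

test_that("cluster summaries behave at the degenerate edges", {
  v <- cbind(f1 = c(1, 1, 1, 1), f2 = c(1, 2, 3, 4))
  lab <- c("a", "a", "b", "b")
  z <- summarize_by_cluster(v, lab, row_scale = "z")
  expect_equal(unname(z[, "f1"]), c(0, 0))     # constant feature
  one <- summarize_by_cluster(v[1:2, ], c("a", "b"))
  expect_equal(unname(one), unname(v[1:2, ]))  # one cell per cluster
})

test_that("planted regulons dominate their active cluster's activity", {
  ds <- default_dataset(seed = 3)
  norm <- normalize_log(ds$counts)
  act <- score_all(rank_genes_per_cell(norm, 11),
                   ds$regulon_truth$regulons)
  sm <- summarize_by_cluster(act, ds$true_labels)
  design <- ds$regulon_truth$activity_design
  for (tf in rownames(design))
    expect_equal(unname(which.max(sm[, tf])),
                 unname(which(design[tf, ] == 1)))
  # KW flags every planted regulon
  res <- differential_activity(act, ds$true_labels)
  expect_true(all(res$p_adjusted < 0.05))
})

test_that("decoy gene-set activity shows no differential signal excess", {
  # a gene universe large enough that rank competition from the 22
  # planted genes is negligible, as in the ~20k-gene data it emulates
  ds <- default_dataset(seed = 19, n_genes = 2000)
  norm <- normalize_log(ds$counts)
  r <- rank_genes_per_cell(norm, 4)
  planted <- unique(c(names(ds$regulon_truth$regulons),
                      unlist(ds$regulon_truth$regulons)))
  pool <- setdiff(colnames(norm)[!startsWith(colnames(norm), "MT-")],
                  c(planted, unlist(ds$marker_genes)))
  set.seed(40)
  decoys <- stats::setNames(
    replicate(40, sample(pool, 10), simplify = FALSE),
    paste0("decoy", 1:40))
  act <- score_all(r, decoys)
  res <- differential_activity(act, ds$true_labels)
  expect_lte(mean(res$p_adjusted < 0.05, na.rm = TRUE), 0.05)
})

test_that("gmt files round-trip and agree with the fgsea reader", {
  sets <- list(TF1 = c("a", "b", "c"), TF2 = c("d", "e"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("motif1", "motif2"))
  back <- read_gmt(path)
  expect_equal(back[], sets, ignore_attr = TRUE)
  expect_equal(unname(attr(back, "description")), c("motif1", "motif2"))
  skip_if_not_installed("fgsea")
  expect_equal(fgsea::gmtPathways(path), sets)
})
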