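test_that("box membership follows the rank-window rules", {
  expect_equal(box_membership(1:10, 5, 0.3), 4:6)
  expect_equal(box_membership(1:10, 5, 1.0), 1:10)
  expect_equal(box_membership(rep(1, 10), 3, 0.1), 1:10)  # all tied
  # focal cell always inside its own box
  set.seed(2)
  for (rep in 1:10) {
    v <- sample(c(rep(0, 6), rexp(6)))
    k <- sample(12, 1)
    expect_true(k %in% box_membership(v, k, 0.25))
  }
  # value-tie blocks enter whole: zeros dominate
  v <- c(rep(0, 7), 1, 2, 3)
  expect_setequal(box_membership(v, 1, 0.2), 1:7)
  expect_error(box_membership(numeric(1), 1), "two cells")
})

test_that("the edge statistic reproduces hand-computed values", {
  expect_equal(csn_statistic(100, 10, 10, 1), 0)
  expect_equal(csn_statistic(100, 10, 10, 10), sqrt(99))
  expect_equal(csn_statistic(100, 10, 10, 0), sqrt(99) * (-100) / 900)
  expect_true(is.na(csn_statistic(100, 0, 10, 0)))     # degenerate box
  expect_true(is.na(csn_statistic(100, 100, 10, 10)))
  # symmetry in x and y
  set.seed(3)
  for (rep in 1:20) {
    nx <- sample(5:50, 1); ny <- sample(5:50, 1)
    nxy <- sample(0:min(nx, ny), 1)
    expect_equal(csn_statistic(100, nx, ny, nxy),
                 csn_statistic(100, ny, nx, nxy))
  }
})

test_that("vectorized CSN equals the naive triple-loop reference", {
  set.seed(5)
  for (rep in 1:3) {
    n <- sample(20:30, 1)
    G <- sample(4:8, 1)
    X <- matrix(rexp(n * G), n, G,
                dimnames = list(paste0("c", seq_len(n)),
                                paste0("g", seq_len(G))))
    X[sample(length(X), length(X) %/% 3)] <- 0   # scRNA-seq-like zeros
    mine <- build_csn(X, csn_params(box_frac = 0.2, alpha = 0.05))
    ref <- csn_oracle(X, box_frac = 0.2, alpha = 0.05)
    expect_identical(mine$ndm, ref$ndm)
    o1 <- mine$edges[order(mine$edges$cell, mine$edges$gene_a,
                           mine$edges$gene_b), ]
    o2 <- ref$edges[order(ref$edges$cell, ref$edges$gene_a,
                          ref$edges$gene_b), ]
    expect_equal(o1$rho, o2$rho, tolerance = 1e-12)
    expect_equal(o1[, 1:3], o2[, 1:3], ignore_attr = TRUE)
  }
})

test_that("independent genes trigger edges at the exact conditional rate", {
  # with exact-size boxes on tie-free data the conditional null count is
  # hypergeometric, so the upper-tail call rate has a closed form
  n <- 500
  m <- ceiling(0.1 * n)
  exact <- phyper(ceiling((m - 1)^2 / (n - 1) +
                          qnorm(0.99) * (m - 1) * (n - m) /
                            ((n - 1) * sqrt(n - 2))) - 1,
                  m - 1, n - m, m - 1, lower.tail = FALSE)
  rates <- vapply(1:4, function(s) {
    set.seed(300 + s)
    X <- matrix(runif(n * 8), n, 8,
                dimnames = list(NULL, paste0("g", 1:8)))
    nrow(build_csn(X, csn_params(alpha = 0.01))$edges) / (n * 28)
  }, numeric(1L))
  expect_lt(abs(mean(rates) - exact), 0.004)
})

test_that("a perfectly co-expressed pair is significant almost everywhere", {
  set.seed(2)
  x <- runif(300)
  cr <- build_csn(cbind(g1 = x, g2 = x), csn_params(alpha = 0.01))
  expect_gte(nrow(cr$edges) / 300, 0.95)
})

test_that("the degree matrix satisfies degree counting and the handshake", {
  edges <- data.frame(cell = "c1", gene_a = c("a", "a"),
                      gene_b = c("b", "c"), rho = c(3, 4))
  # via the public builder on constructed data: use the naive check instead
  set.seed(9)
  X <- matrix(rexp(25 * 5), 25, 5,
              dimnames = list(paste0("c", 1:25), paste0("g", 1:5)))
  cr <- build_csn(X, csn_params(box_frac = 0.2, alpha = 0.1))
  nd <- ndm(cr)
  for (cell in colnames(nd)) {
    e <- cr$edges[cr$edges$cell == cell, ]
    expect_equal(sum(nd[, cell]), 2 * nrow(e))
    for (g in rownames(nd))
      expect_equal(nd[g, cell], sum(e$gene_a == g | e$gene_b == g))
  }
})

test_that("differential NDM reproduces the exact rank-sum p-value", {
  nd <- matrix(c(1, 2, 3, 4, 5, 6), 1,
               dimnames = list("g1", paste0("c", 1:6)))
  res <- differential_ndm(nd, c(1, 1, 1, 2, 2, 2), 1)
  expect_equal(res$p_value, 0.1)   # 2 * 1/20, exhaustive C(6,3)
  # identical columns: null
  nd2 <- matrix(rep(c(2, 2, 2, 2), 2), 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  res2 <- differential_ndm(nd2, c(1, 1, 2, 2), 1)
  expect_true(all(res2$p_adjusted == 1))
  expect_error(differential_ndm(nd, rep(1, 6), 1), ">= 2 cells")
})

test_that("per-cluster edge frequencies hit the extremes and bounds", {
  # constructed result: the (a, b) edge fires in every cluster-A cell and
  # in no cluster-B cell; (a, c) fires in one A cell
  cells <- paste0("c", 1:10)
  labels <- rep(c("A", "B"), each = 5)
  edges <- rbind(data.frame(cell = cells[1:5], gene_a = "a", gene_b = "b",
                            rho = 3),
                 data.frame(cell = cells[2], gene_a = "a", gene_b = "c",
                            rho = 4))
  nd <- matrix(0L, 3, 10, dimnames = list(c("a", "b", "c"), cells))
  cr <- structure(list(edges = edges, ndm = nd, n = 10,
                       params = csn_params()), class = "csn_result")
  freq <- connectivity_by_cluster(cr, labels)
  ab_A <- freq$A$frequency[freq$A$gene_b == "b"]
  expect_equal(ab_A, 1.0)
  expect_equal(freq$B$frequency[freq$B$gene_b == "b"], 0.0)
  expect_equal(freq$A$frequency[freq$A$gene_b == "c"], 0.2)
  expect_true(all(unlist(lapply(freq, `[[`, "frequency")) >= 0))
  expect_true(all(unlist(lapply(freq, `[[`, "frequency")) <= 1))
})

test_that("the planted TF is most connected in its active cluster", {
  ds <- default_dataset(seed = 1)
  norm <- normalize_log(ds$counts)
  subset <- unique(c(names(ds$regulon_truth$regulons),
                     unlist(ds$regulon_truth$regulons)))
  nd <- ndm(build_csn(norm, csn_params(gene_subset = subset)))
  design <- ds$regulon_truth$activity_design
  for (tf in rownames(design)) {
    active <- unname(which(design[tf, ] == 1))
    means <- tapply(nd[tf, ], ds$true_labels, mean)
    expect_equal(unname(which.max(means)), active)
    dn <- differential_ndm(nd, ds$true_labels, active)
    expect_lt(dn$p_adjusted[dn$gene == tf], 0.05)
  }
})
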