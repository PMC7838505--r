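test_that("binarization keeps exactly the strongest edges", {
  set.seed(51)
  # hemisphere-scale edge counts
  m <- matrix(rnorm(123^2), 123)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  expect_equal(sum(binarize_at_sparsity(m, 0.10)) / 2, 750)
  expect_equal(sum(binarize_at_sparsity(m, 0.34)) / 2, 2551)

  # the three largest of six weights on four nodes
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.5; w[1, 4] <- 0.1
  w[2, 3] <- 0.7; w[2, 4] <- -0.2; w[3, 4] <- 0.3
  w <- w + t(w)
  a <- binarize_at_sparsity(w, 0.5)
  expect_equal(sum(a) / 2, 3)
  expect_true(all(a[cbind(c(1, 2, 1), c(2, 3, 3))] == 1))
  expect_true(a[2, 4] == 0)

  # deterministic lexicographic tie-break
  tie <- matrix(1, 5, 5)
  diag(tie) <- 0
  a1 <- binarize_at_sparsity(tie, 0.3)
  expect_identical(a1, binarize_at_sparsity(tie, 0.3))
  expect_equal(a1[1, 2] + a1[1, 3] + a1[1, 4], 3)  # first pairs in (i,j) order

  expect_error(binarize_at_sparsity(w, 0.01), "zero edges")
})

test_that("graph metrics match brute-force oracles on random graphs", {
  for (s in 1:30) {
    n <- sample(5:15, 1)
    adj <- random_adjacency(n, runif(1, 0.15, 0.6), seed = 1000 + s)
    gm <- global_metrics(adj)
    nm <- nodal_metrics(adj)
    or <- oracle_global_metrics(adj)
    expect_equal(gm$Cp, or$Cp, tolerance = 1e-12)
    expect_equal(gm$Lp, or$Lp, tolerance = 1e-12)
    expect_equal(gm$Eg, or$Eg, tolerance = 1e-12)
    expect_equal(gm$Eloc, or$Eloc, tolerance = 1e-12)
    expect_equal(unname(nm$Dc), or$Dc, tolerance = 1e-12)
    expect_equal(unname(nm$NEg), or$NEg, tolerance = 1e-12)
    expect_equal(unname(nm$NEloc), or$NEloc, tolerance = 1e-12)
    expect_equal(unname(nm$Bc), oracle_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("global and nodal efficiencies are mutually consistent", {
  adj <- random_adjacency(20, 0.3, seed = 77)
  gm <- global_metrics(adj)
  nm <- nodal_metrics(adj)
  expect_equal(gm$Eg, mean(nm$NEg), tolerance = 1e-12)
  expect_equal(gm$Eloc, mean(nm$NEloc), tolerance = 1e-12)
})

test_that("hand-enumerable graphs give the known metric values", {
  k5 <- global_metrics(adj_complete(5))
  expect_equal(k5$Cp, 1)
  expect_equal(k5$Lp, 1)
  expect_equal(k5$Eg, 1)
  expect_equal(k5$Eloc, 1)

  p3 <- global_metrics(adj_path(3))
  expect_equal(p3$Lp, 4 / 3)
  expect_equal(p3$Eg, (1 + 1 + 0.5) / 3)
  expect_equal(p3$Cp, 0)
  expect_equal(unname(nodal_metrics(adj_path(3))$Bc[2]), 1)

  star <- nodal_metrics(adj_star(5))
  expect_equal(unname(star$Dc[1]), 4)
  expect_equal(unname(star$Bc[1]), 6)     # C(4,2) leaf pairs through the hub
  expect_equal(unname(star$Bc[2:5]), rep(0, 4))
})

test_that("degree-preserving rewiring conserves degrees deterministically", {
  adj <- random_adjacency(25, 0.25, seed = 61)
  nul <- degree_preserving_null(adj, seed = 4)
  expect_identical(sort(rowSums(nul)), sort(rowSums(adj)))
  expect_true(all(diag(nul) == 0))
  expect_true(all(nul %in% c(0, 1)))
  expect_identical(nul, degree_preserving_null(adj, seed = 4))
  expect_identical(degree_preserving_null(adj, n_swaps = 0, seed = 1), adj)
  # a complete graph admits no legal swap
  expect_equal(degree_preserving_null(adj_complete(5), seed = 9),
               adj_complete(5), ignore_attr = TRUE)
})

test_that("small-world indices behave canonically", {
  # sigma = gamma / lambda by construction
  adj <- random_adjacency(30, 0.2, seed = 71)
  sw <- small_world_indices(adj, n_null = 5, seed = 2)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)

  # Watts-Strogatz ring lattice: high clustering relative to nulls
  for (s in 1:5) {
    ws <- withr::with_seed(200 + s, {
      g <- igraph::sample_smallworld(1, 100, 3, 0.05)
      igraph::as_adjacency_matrix(igraph::simplify(g), sparse = FALSE)
    })
    sw <- small_world_indices(ws, n_null = 5, seed = s)
    expect_gt(sw$gamma, 1.5)
    expect_lt(sw$lambda, 1.5)
  }

  # dense random graphs are left unchanged in expectation
  er <- random_adjacency(60, 0.5, seed = 81)
  sw <- small_world_indices(er, n_null = 5, seed = 3)
  expect_gt(sw$gamma, 0.8)
  expect_lt(sw$gamma, 1.2)
})

test_that("AUC over sparsity integrates exactly", {
  s <- seq(0.01, 0.34, by = 0.01)
  expect_equal(auc_over_sparsity(rep(2, 34), s), 0.33 * 2, tolerance = 1e-12)
  # trapezoid is exact for linear curves
  expect_equal(auc_over_sparsity(s, s), (0.34^2 - 0.01^2) / 2, tolerance = 1e-12)
  expect_equal(auc_over_sparsity(c(0, 2), c(0.01, 0.02)), 0.01, tolerance = 1e-12)
  v <- rep(1, 34)
  v[5] <- NaN
  expect_error(auc_over_sparsity(v, s), "0.05")
})

test_that("topology profiles have the right shape and are deterministic", {
  set.seed(91)
  ts <- matrix(rnorm(15 * 300), 15, 300)
  fc <- pearson_fc(ts)
  grid <- seq(0.05, 0.34, by = 0.01)
  pr1 <- compute_topology_profile(fc, sparsities = grid, n_null = 3, seed = 12)
  pr2 <- compute_topology_profile(fc, sparsities = grid, n_null = 3, seed = 12)
  expect_identical(pr1$global, pr2$global)
  expect_identical(pr1$nodal, pr2$nodal)
  expect_length(pr1$global, 7)
  expect_length(pr1$nodal, 4 * 15)
  expect_named(pr1$global, c("aGamma", "aLambda", "aSigma", "aCp", "aLp",
                             "aEg", "aEloc"))
  expect_true(all(is.finite(c(pr1$global, pr1$nodal))))
  expect_true(all(pr1$nodal[grep("^aDc_", names(pr1$nodal))] >= 0))
})

test_that("a dense covariance module boosts its members' local efficiency", {
  n <- 14
  cv <- diag(n)
  members <- 1:5
  cv[members, members] <- 0.6
  diag(cv) <- 1
  ts <- sample_subject_timeseries(cv, 600, seed = 17)
  fc <- pearson_fc(ts)
  pr <- compute_topology_profile(fc, sparsities = seq(0.08, 0.3, by = 0.02),
                                 n_null = 2, seed = 5)
  neloc <- pr$nodal[grep("^aNEloc_", names(pr$nodal))]
  expect_gt(median(neloc[members]), median(neloc[-members]))
})
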