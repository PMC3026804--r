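test_that("nodf handles the canonical extremes", {
  tri <- matrix(0, 4, 4)
  for (i in 1:4) tri[i, seq_len(5 - i)] <- 1   # strictly decreasing, full overlap
  expect_equal(nodf(tri), 100)
  expect_equal(nodf(diag(4)), 0)               # equal fills, no overlap
  expect_warning(z <- nodf(matrix(0, 3, 3)), "all-zero")
  expect_equal(z, 0)
  expect_error(nodf(matrix(1, 1, 5)), "2 x 2")
})

test_that("nodf equals the direct-definition oracle and is permutation invariant", {
  set.seed(123)
  for (i in 1:60) {
    m <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6, 6)
    if (all(m == 0)) next
    expect_equal(suppressWarnings(nodf(m)), nodf_oracle(m), tolerance = 1e-12)
    pm <- m[sample(6), sample(6)]
    expect_equal(suppressWarnings(nodf(pm)), suppressWarnings(nodf(m)),
                 tolerance = 1e-12)
  }
})

test_that("nodf agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rbinom(56, 1, 0.45), 8, 7)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(nodf(m),
                 as.numeric(vegan::nestednodf(m, order = TRUE)$statistic["NODF"]),
                 tolerance = 1e-9)
  }
})

test_that("relative nestedness standardizes against the null mean", {
  null <- rep(20, 150)
  expect_equal(relative_nestedness(20, null), 0)
  expect_equal(relative_nestedness(40, null), 1)
  expect_error(relative_nestedness(1, rep(0, 150)), "undefined")
  expect_error(relative_nestedness(1, rep(1, 50)), "100 null samples")
})

test_that("degree, connectance and clustering match hand values", {
  k5 <- projection_graph(matrix(1, 5, 5) - diag(5))
  ds <- degree_stats(k5)
  expect_equal(ds$normalized_mean, 1)
  expect_equal(ds$normalized_se, 0)
  expect_equal(connectance(k5), 1)
  expect_equal(clustering(k5)$average, 1)

  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  gs <- projection_graph(star)
  expect_equal(unname(degree_stats(gs)$degrees), c(4, 1, 1, 1, 1))
  expect_equal(degree_stats(gs)$mean_degree, 1.6)
  expect_equal(clustering(gs)$average, 0)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(connectance(projection_graph(path3)), 2 / 3)
  expect_equal(connectance(projection_graph(matrix(0, 4, 4))), 0)

  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering(projection_graph(tri))$average, 1)
})

test_that("metrics match enumeration oracles on random graphs", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    a <- matrix(rbinom(n * n, 1, 0.4), n, n)
    a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
    g <- projection_graph(a)
    expect_equal(unname(clustering(g)$local), clustering_oracle(a))
    expect_equal(unname(degree_stats(g)$degrees), rowSums(a))
    # algebraic identity: connectance = mean degree / (n - 1)
    expect_equal(connectance(g), degree_stats(g)$mean_degree / (n - 1),
                 tolerance = 1e-12)
  }
})

test_that("functional specialization equals BFS distances", {
  # two species in different groups joined by one edge -> FS = 1
  m2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g2 <- projection_graph(m2, groups = c(a = "beefly", b = "beetle"))
  expect_equal(functional_specialization(g2, "beefly", "beetle"), 1)
  # path A - x - B -> FS(A, B) = 2
  p <- matrix(0, 3, 3, dimnames = list(c("A", "x", "B"), c("A", "x", "B")))
  p["A", "x"] <- p["x", "A"] <- p["x", "B"] <- p["B", "x"] <- 1
  g3 <- projection_graph(p, groups = c(A = "beefly", x = "hoverfly", B = "beetle"))
  expect_equal(functional_specialization(g3, "beefly", "beetle"), 2)
  # random fixture against igraph-free BFS oracle
  set.seed(21)
  n <- 10
  a <- matrix(rbinom(n * n, 1, 0.35), n, n); a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
  dimnames(a) <- list(letters[1:n], letters[1:n])
  grp <- setNames(rep(c("g1", "g2"), each = 5), letters[1:n])
  g <- projection_graph(a, groups = grp)
  # Floyd-Warshall oracle
  d <- ifelse(a == 1, 1, Inf); diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  focal <- letters[1:5]; target <- letters[6:10]
  dd <- d[focal, target]; dd[is.infinite(dd)] <- NA
  expected <- mean(rowMeans(dd, na.rm = TRUE), na.rm = TRUE)
  expect_equal(suppressWarnings(functional_specialization(g, "g1", "g2")), expected)
  expect_error(functional_specialization(g, "nope", "g2"), "no species")
})

test_that("hub scores match a dense eigen-decomposition", {
  k3 <- projection_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(hub_scores(k3)), rep(1, 3))
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  hs <- hub_scores(projection_graph(star))
  expect_equal(unname(which.max(hs)), 1L)
  expect_equal(unname(hs[1]), 1)
  set.seed(31)
  a <- matrix(rbinom(64, 1, 0.45), 8, 8); a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
  g <- projection_graph(a)
  ev <- eigen(a, symmetric = TRUE)
  principal <- abs(ev$vectors[, which.max(ev$values)])
  expect_equal(unname(hub_scores(g)), principal / max(principal), tolerance = 1e-8)
})
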