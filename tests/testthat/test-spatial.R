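test_that("spatial weights are row-standardized and reject duplicates", {
  # a point with two equidistant neighbours splits its row 0.5 / 0.5
  coords <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  W <- spatial_weights(coords)$W
  expect_equal(W[1, 2], 0.5)
  expect_equal(W[1, 3], 0.5)
  expect_error(spatial_weights(rbind(c(0, 0), c(0, 0))), "duplicate")
  set.seed(17)
  for (scheme in c("inverse_distance", "knn", "gabriel")) {
    W8 <- spatial_weights(matrix(runif(16), 8, 2), scheme)$W
    expect_equal(unname(rowSums(W8)), rep(1, 8), tolerance = 1e-12)
    expect_equal(unname(diag(W8)), rep(0, 8))
  }
})

test_that("residualize matches the normal-equation solution", {
  set.seed(18)
  x <- rnorm(10); y <- 2 * x + rnorm(10)
  r <- residualize(y, x)
  expect_equal(r, unname(resid(lm(y ~ x))), tolerance = 1e-12)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(residualize(2 * x, x), rep(0, 10), tolerance = 1e-10)
  # orthogonal covariate: residuals are the centred metric
  z <- c(-1, 1, -1, 1)
  m <- c(1, 1, 3, 3)
  expect_equal(residualize(m, z), m - mean(m), tolerance = 1e-12)
})

test_that("SAR with fixed rho = 0 reproduces OLS exactly", {
  set.seed(19)
  x <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(50)
  W <- spatial_weights(matrix(runif(100), 50, 2))$W
  f <- fit_sar_mix(y, x, W, rho = 0, lag_predictors = FALSE)
  ols <- lm(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-6)
})

test_that("SAR profile likelihood recovers parameters and flags collinearity", {
  set.seed(20)
  d <- sar_sim(60, rho = 0.4, beta = 1, gamma = 0.5)
  f <- fit_sar_mix(d$y, d$x, d$W)
  expect_lt(abs(f$rho - 0.4), 0.35)
  expect_lt(abs(f$coefficients["x"] - 1), 0.5)
  expect_true(f$rho > f$feasible["lower"] && f$rho < f$feasible["upper"])
  # local maximum: neighbourhood evaluations do not beat the optimum
  ll <- function(r) {
    n <- length(d$y)
    Wy <- d$W %*% d$y
    Z <- cbind(1, d$x, d$W %*% d$x)
    e <- resid(lm.fit(Z, d$y - r * Wy))
    ev <- Re(eigen(d$W, only.values = TRUE)$values)
    -n / 2 * log(sum(e^2) / n) + sum(log(abs(1 - r * ev)))
  }
  expect_gte(ll(f$rho) + 1e-6, ll(f$rho + 0.01))
  expect_gte(ll(f$rho) + 1e-6, ll(f$rho - 0.01))
  # collinear predictors are named in the error
  xx <- cbind(p = d$x[, 1], q = d$x[, 1])
  expect_error(fit_sar_mix(d$y, xx, d$W, lag_predictors = FALSE), "collinear")
  expect_warning(fit_sar_mix(rnorm(8), matrix(rnorm(8)), spatial_weights(matrix(runif(16), 8, 2))$W),
                 "fragile")
})

test_that("SAR permutation p-values behave under the null", {
  set.seed(22)
  d <- sar_sim(30, rho = 0, beta = 0, gamma = 0)
  f <- fit_sar_mix(d$y, d$x, d$W, rho = 0, perms = 99, seed = 5)
  expect_true(all(f$perm_p > 0.01))
  f2 <- fit_sar_mix(d$y, d$x, d$W, rho = 0, perms = 99, seed = 5)
  expect_identical(f$perm_p, f2$perm_p)
})

test_that("partial Mantel statistic behaves at the exchangeable extremes", {
  set.seed(23)
  A <- random_symmetric(12); B <- random_symmetric(12); C <- random_symmetric(12)
  same <- partial_mantel(A, A, C, perms = 200, seed = 1)
  expect_equal(same$statistic, 1, tolerance = 1e-10)
  expect_lt(same$p_value, 0.05)
  selfc <- partial_mantel(A, B, A, perms = 200, seed = 2)
  expect_lt(abs(selfc$statistic), 0.15)
  expect_error(partial_mantel(A[1:3, 1:3], B[1:3, 1:3], C[1:3, 1:3]), "4 objects")
  expect_error(partial_mantel(matrix(1:9, 3, 3), B, C), "symmetric")
})

test_that("partial Mantel agrees with vegan's statistic", {
  skip_if_not_installed("vegan")
  set.seed(24)
  for (i in 1:5) {
    A <- random_symmetric(10); B <- random_symmetric(10); C <- random_symmetric(10)
    mine <- partial_mantel(A, B, C, perms = 99, seed = 1)
    ref <- vegan::mantel.partial(as.dist(A), as.dist(B), as.dist(C),
                                 method = "spearman", permutations = 0)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})
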