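test_that("CE cell probabilities follow the fill-averaging formula", {
  expect_equal(unclass(ce_probabilities(matrix(1, 3, 4))),
               matrix(1, 3, 4), ignore_attr = TRUE)
  expect_equal(unclass(ce_probabilities(matrix(0, 3, 4))),
               matrix(0, 3, 4), ignore_attr = TRUE)
  # 2x2 hand case: row 1 fill 1/2, col 1 fill 1/2 -> mean 0.5
  p <- ce_probabilities(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[1, 2], 0.25)
  expect_equal(p[2, 2], 0)
  # 3x3 hand case
  m <- matrix(c(1, 1, 0,
                1, 0, 0,
                0, 0, 0), 3, 3, byrow = TRUE)
  p3 <- ce_probabilities(m)
  expect_equal(p3[1, 1], (2 / 3 + 2 / 3) / 2)  # row fill 2/3, col fill 2/3
  expect_equal(p3[2, 2], (1 / 3 + 1 / 3) / 2)
  expect_equal(p3[3, 3], 0)
})

test_that("sample_ce respects probabilities and redraw rules", {
  ones <- ce_probabilities(matrix(1, 3, 3))
  expect_equal(sample_ce(ones, seed = 1), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_error(sample_ce(matrix(0, 1, 1), seed = 1), "redraws")
  # expected fill preserved within 2% over many draws (matrix large enough
  # that the empty-row/column redraw rule fires with negligible probability)
  set.seed(8)
  pr <- matrix(runif(42, 0.35, 0.8), 6, 7)
  fill <- mean(replicate(2000, mean(sample_ce(pr))))
  expect_lt(abs(fill - mean(pr)) / mean(pr), 0.02)
})

test_that("nodf_null_test detects nestedness and signs correctly", {
  tri <- matrix(0, 8, 8)
  for (i in 1:8) tri[i, seq_len(9 - i)] <- 1
  nt <- nodf_null_test(tri, reps = 200, seed = 3)
  expect_lte(nt$ensemble$p_value, 0.01)
  expect_gt(nt$relative_nestedness, 0)
  # observed far below the null mean: anti-nested checkerboard
  cb <- 1 * (outer(1:8, 1:8, "+") %% 2 == 0)
  nt2 <- nodf_null_test(cb, reps = 200, seed = 4)
  expect_gt(nt2$ensemble$p_value, 0.5)
  expect_lt(nt2$relative_nestedness, 0)
  # p-values never zero, reproducible by seed
  nt3 <- nodf_null_test(tri, reps = 200, seed = 3)
  expect_identical(nt$ensemble$null, nt3$ensemble$null)
  expect_gt(nt$ensemble$p_value, 0)
})

test_that("random-visitation ensemble handles degenerate frequencies", {
  inc <- inc_from_matrix(matrix(1, 5, 4))
  rv <- random_visitation_ensemble(inc, reps = 100, master_rows = 500, seed = 2)
  expect_true(all(rv$connectance$null == 1))   # f = 1: complete null networks
  expect_named(rv, c("mean_degree", "connectance", "clustering"))
  # all-zero frequencies rejected
  inc0 <- inc_from_matrix(matrix(0, 4, 3))
  expect_error(random_visitation_ensemble(inc0, reps = 100, master_rows = 100),
               "zero")
})

test_that("ensembles are reproducible and effort-bounded by the add-one rule", {
  set.seed(77)
  m <- matrix(rbinom(60, 1, 0.5), 10, 6)
  m[rowSums(m) == 0, 1] <- 1
  inc <- inc_from_matrix(m)
  a <- random_visitation_ensemble(inc, reps = 150, master_rows = 2000, seed = 9)
  b <- random_visitation_ensemble(inc, reps = 150, master_rows = 2000, seed = 9)
  expect_identical(a$clustering$null, b$clustering$null)
  for (e in a) {
    expect_gt(e$p_value, 0)
    expect_lte(e$p_value, 1)
    expect_gte(e$p_value, 1 / 151)
  }
  # boundary: subsample size equal to master rows is a row permutation
  inc2 <- inc_from_matrix(matrix(rbinom(20, 1, 0.6), 5, 4))
  rv2 <- random_visitation_ensemble(inc2, reps = 50, master_rows = 5, seed = 1)
  expect_equal(length(unique(rv2$connectance$null)), 1)
})
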