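test_that("simulate_pool produces valid, reproducible assemblages", {
  one <- simulate_pool(1, seed = 1)
  expect_equal(one$relative_abundance, 1)
  pool <- simulate_pool(32, seed = 2)
  expect_equal(sum(pool$relative_abundance), 1, tolerance = 1e-12)
  expect_true(all(pool$functional_group %in%
                    c("large_bee", "small_bee", "wasp", "beefly", "hoverfly",
                      "beetle", "butterfly", "other")))
  # deterministic foraging modes for the three behaviourally fixed groups
  expect_true(all(pool$foraging_mode[pool$functional_group == "beefly"] == "indiscriminate"))
  expect_true(all(pool$foraging_mode[pool$functional_group == "hoverfly"] == "distance_limited"))
  expect_true(all(pool$foraging_mode[pool$functional_group == "beetle"] == "within_plant"))
  # bit-identical regeneration under the same seed
  expect_identical(simulate_pool(30, abundance_shape = 1.5, seed = 7),
                   simulate_pool(30, abundance_shape = 1.5, seed = 7))
  expect_error(simulate_pool(5, group_weights = rep(-1, 8)), "normalizable")
})

test_that("simulate_visitation books effort and respects limits", {
  pool <- simulate_pool(6, seed = 3)
  pop <- simulate_population("t", 12, seed = 4)
  v <- simulate_visitation(pool, pop, surveys = 4, minutes_per_plant = 5, seed = 5)
  # effort bookkeeping: every plant x survey pair present exactly once
  eff <- tapply(v$minutes_observed, paste(v$plant_id, v$survey),
                function(x) x[1])
  expect_equal(sum(eff), 4 * 12 * 5)
  # zero rate -> only zero-visit placeholder rows
  v0 <- simulate_visitation(pool, pop, surveys = 2, visit_rate = 0, seed = 6)
  expect_equal(sum(v0$visits), 0)
  expect_equal(nrow(v0), 12 * 2)
  # one indiscriminate species at a high rate visits both plants
  p1 <- simulate_pool(1, seed = 8)
  p1$foraging_mode <- "indiscriminate"
  two <- simulate_population("u", 2, seed = 9)
  vh <- simulate_visitation(p1, two, surveys = 1, minutes_per_plant = 500,
                            visit_rate = 5, seed = 10)
  expect_setequal(unique(vh$plant_id[vh$visits > 0]), two$plant_ids)
})

test_that("per-plant richness under the default design is near its target", {
  r <- numeric(20)
  for (i in 1:20) {
    pool <- simulate_pool(32, seed = 100 + i)
    pop <- simulate_population("t", 60, seed = 200 + i)
    v <- simulate_visitation(pool, pop, seed = 300 + i)
    r[i] <- mean(rowSums(build_incidence(v)$presence))
  }
  expect_lt(abs(mean(r) - 4) / 4, 0.2)
})

test_that("foraging modes shape connectivity: indiscriminate beats within-plant", {
  wins <- 0
  for (s in 1:50) {
    pop <- simulate_population("f", 25, seed = 4000 + s)
    mk <- function(mode) {
      pool <- simulate_pool(6, seed = 5000 + s)
      pool$foraging_mode <- mode
      v <- simulate_visitation(pool, pop, surveys = 4, seed = 6000 + s)
      if (sum(v$visits) == 0) return(NA)
      degree_stats(project_plants(build_incidence(v)))$mean_degree
    }
    a <- mk("indiscriminate"); b <- mk("within_plant")
    if (is.na(a) || is.na(b)) next
    wins <- wins + (a > b)
  }
  expect_gt(wins / 50, 0.9)
})

test_that("the fitness chain propagates zeros and couplings correctly", {
  params0 <- fitness_chain_params(germination_prob = 0)
  perf0 <- simulate_performance(runif(50), params0, seed = 1)
  expect_true(all(perf0$juveniles == 0))
  # no coupling: juveniles independent of latent connectivity
  latent <- runif(1000)
  perf_null <- simulate_performance(latent, fitness_chain_params(architecture_effect = 0),
                                    seed = 2)
  expect_lt(abs(cor(latent, perf_null$juveniles, method = "spearman")), 0.08)
  # positive coupling recovered in >= 95% of seeds
  hits <- 0
  for (s in 1:100) {
    l <- runif(200)
    p <- simulate_performance(l, fitness_chain_params(architecture_effect = 0.5,
                                                      noise_sd = 0.1), seed = s)
    hits <- hits + (cor(l, p$juveniles, method = "spearman") > 0)
  }
  expect_gte(hits, 95)
  expect_error(simulate_performance(c(1, NaN), fitness_chain_params()), "NaN")
})

test_that("increasing architecture_effect increases mean juveniles", {
  latent <- runif(1000, 0.2, 1)
  m <- vapply(c(0, 0.5, 1, 2), function(ae) {
    mean(simulate_performance(latent, fitness_chain_params(architecture_effect = ae),
                              seed = 42)$juveniles)
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("simulate_study matches the eight-population field scale", {
  st <- simulate_study(seed = 1)
  expect_s3_class(st, "pollination_study")
  expect_equal(nrow(st$populations), 8)
  dims <- vapply(st$populations$population_id, function(pid) {
    v <- st$visits[st$visits$population_id == pid, ]
    inc <- build_incidence(suppressMessages(filter_plants(v)))
    c(length(inc$plants), length(inc$pollinators))
  }, numeric(2))
  expect_true(all(dims[1, ] >= 47 & dims[1, ] <= 90))
  expect_true(all(dims[2, ] >= 30 & dims[2, ] <= 41))
  # byte-identical under the same seed
  expect_identical(st, simulate_study(seed = 1))
  expect_warning(simulate_study(n_pops = 2, n_plants = 10,
                                species_range = c(5, 6), seed = 2),
                 "spatial models")
})
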