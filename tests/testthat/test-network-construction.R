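test_that("filter_plants applies the strict >15 min / >=1 visit rule", {
  # A fails minutes only (exactly 15), B fails visits only, C fails both,
  # D and E survive
  tab <- toy_visits(
    plants = c("A", "B", "C", "D", "E"),
    species = c("s1", NA, NA, "s1", "s2"),
    visits = c(3, 0, 0, 2, 1),
    minutes = c(15, 20, 10, 25, 16))
  out <- suppressMessages(filter_plants(tab))
  expect_setequal(unique(out$plant_id), c("D", "E"))
  expect_equal(unname(attr(out, "dropped")["kept"]), 2)
  expect_equal(unname(attr(out, "dropped")["too_few_minutes"]), 2)  # A and C
  expect_equal(unname(attr(out, "dropped")["no_visits"]), 1)        # B
})

test_that("filter_plants sums effort over surveys and is idempotent", {
  # 2 surveys x 10 min = 20 min total: survives despite 10 min per survey
  tab <- toy_visits(plants = c("A", "A"), species = c("s1", "s1"),
                    visits = c(1, 2), minutes = c(10, 10), survey = c(1, 2))
  out <- suppressMessages(filter_plants(tab))
  expect_setequal(unique(out$plant_id), "A")
  again <- suppressMessages(filter_plants(out))
  expect_equal(as.data.frame(again), as.data.frame(out))
  # and errors when nothing survives
  bad <- toy_visits("A", "s1", 1, minutes = 15)
  expect_error(suppressMessages(filter_plants(bad)), "no plants survive")
})

test_that("build_incidence aggregates counts and matches a hand-built matrix", {
  tab <- toy_visits(
    plants = c("p1", "p1", "p1", "p2", "p3", "p4", "p4"),
    species = c("sA", "sA", "sB", "sB", "sC", "sA", "sC"),
    visits = c(1, 1, 2, 1, 3, 1, 1),
    minutes = 20, survey = c(1, 2, 1, 1, 1, 1, 1))
  inc <- build_incidence(tab)
  hand_counts <- matrix(c(2, 2, 0,
                          0, 1, 0,
                          0, 0, 3,
                          1, 0, 1), 4, 3, byrow = TRUE,
                        dimnames = list(c("p1", "p2", "p3", "p4"),
                                        c("sA", "sB", "sC")))
  expect_equal(inc$counts, hand_counts, ignore_attr = "class")
  expect_equal(inc$presence, (hand_counts >= 1) + 0L, ignore_attr = "class")
  # repeated visits by the same species: count 2, presence 1
  expect_equal(inc$counts["p1", "sA"], 2)
  expect_equal(inc$presence["p1", "sA"], 1L)
})

test_that("visitation_table validates schema and values", {
  df <- data.frame(population_id = "p", survey = 1, plant_id = "a",
                   pollinator_species = "s", functional_group = "other",
                   visits = -1, minutes_observed = 5, open_flowers = 2)
  expect_error(visitation_table(df), "nonnegative")
  expect_error(visitation_table(df[, -6]), "missing columns")
  df$visits <- 1; df$minutes_observed <- 0
  expect_error(visitation_table(df), "positive")
})

test_that("plant projection matches the set-intersection oracle", {
  expect_equal(project_plants(matrix(c(1, 0, 0, 1), 2, 2))$L, 0)
  g <- project_plants(matrix(1, 2, 2))
  expect_equal(g$mult[1, 2], 2)
  expect_equal(g$L, 1)
  set.seed(42)
  for (i in 1:50) {
    m <- matrix(rbinom(48, 1, runif(1, 0.2, 0.8)), 8, 6)
    g <- project_plants(m)
    expect_equal(unname(g$mult), projection_oracle(m))
    expect_true(all(diag(g$mult) == 0))
    expect_lte(g$L, g$n * (g$n - 1) / 2)
  }
})

test_that("pollinator projection mirrors plant projection on the transpose", {
  # one plant visited by 3 species -> triangle
  tri <- project_pollinators(matrix(1, 1, 3))
  expect_equal(tri$L, 3)
  # disjoint plant sets -> isolated species
  iso <- project_pollinators(diag(3))
  expect_equal(iso$L, 0)
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rbinom(30, 1, 0.5), 5, 6)
    expect_equal(project_pollinators(m)$mult, project_plants(t(m))$mult)
  }
})

test_that("adding a presence never removes a projection edge", {
  set.seed(11)
  for (i in 1:30) {
    m <- matrix(rbinom(35, 1, 0.4), 7, 5)
    zero <- which(m == 0)
    if (!length(zero)) next
    m2 <- m
    m2[sample(zero, 1)] <- 1
    a1 <- project_plants(m)$adjacency
    a2 <- project_plants(m2)$adjacency
    expect_true(all(a2 >= a1))
  }
})
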