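# Independent oracle implementations and fixture builders. Oracles are kept
# deliberately naive (loops, set operations, dense eigendecompositions) so
# they share no code path with the package implementations they check.

# Direct-definition NODF: explicit loops over ordered pairs.
nodf_oracle <- function(m) {
  pair_sum <- function(mat) {
    n <- nrow(mat)
    tot <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        fi <- sum(mat[i, ]); fj <- sum(mat[j, ])
        if (fi == fj) next
        poor <- if (fi < fj) i else j
        rich <- if (fi < fj) j else i
        fp <- sum(mat[poor, ])
        if (fp == 0) next
        shared <- sum(mat[poor, ] == 1 & mat[rich, ] == 1)
        tot <- tot + 100 * shared / fp
      }
    }
    tot
  }
  (pair_sum(m) + pair_sum(t(m))) / (choose(nrow(m), 2) + choose(ncol(m), 2))
}

# Brute-force shared-partner multiplicities via set intersection.
projection_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      out[i, j] <- length(intersect(which(m[i, ] == 1), which(m[j, ] == 1)))
    }
  }
  out
}

# Neighbour-enumeration degree and triangle-counting clustering.
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k <= 1) { ci[i] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]] == 1) links <- links + 1
    }
    ci[i] <- links / (k * (k - 1) / 2)
  }
  ci
}

# Small visitation table from a named spec; each row one (plant, species)
# visit total observed across `minutes` of effort.
toy_visits <- function(plants, species, visits, minutes, flowers = 5,
                       pop = "popA", group = "other", survey = 1) {
  visitation_table(data.frame(
    population_id = pop, survey = survey, plant_id = plants,
    pollinator_species = species, functional_group = group,
    visits = visits, minutes_observed = minutes, open_flowers = flowers,
    stringsAsFactors = FALSE))
}

# Incidence object straight from a binary matrix (bypasses table plumbing).
inc_from_matrix <- function(m, counts = NULL) {
  rownames(m) <- rownames(m) %||% sprintf("pl%02d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("sp%02d", seq_len(ncol(m)))
  structure(list(presence = m, counts = counts %||% m,
                 plants = rownames(m), pollinators = colnames(m),
                 groups = setNames(rep("other", ncol(m)), colnames(m))),
            class = "incidence_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_symmetric <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- m + t(m); diag(m) <- 0
  m
}

# Simulate from y = rho W y + Z theta + eps for SAR recovery checks.
sar_sim <- function(n, rho, beta, gamma, sd = 0.5) {
  coords <- matrix(runif(2 * n), n, 2)
  W <- spatial_weights(coords, "gabriel")$W
  x <- rnorm(n)
  Z <- cbind(1, x, W %*% x)
  y <- solve(diag(n) - rho * W, Z %*% c(0.5, beta, gamma) + rnorm(n, 0, sd))
  list(y = as.numeric(y), x = matrix(x, dimnames = list(NULL, "x")), W = W)
}
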