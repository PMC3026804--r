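#' CE null-model cell probabilities
#'
#' Under the CE null model the probability that cell (i, k) of a binary
#' incidence matrix holds a presence is the average of its row and column
#' fill proportions: `p[i,k] = (P_i / C + P_k / R) / 2`, where `P_i` is the
#' number of presences in row i, `P_k` the number in column k, and `R`, `C`
#' the matrix dimensions.
#'
#' @param presence binary matrix.
#' @return matrix of probabilities, same shape, class `ce_probabilities`.
#' @export
ce_probabilities <- function(presence) {
  assert_binary_matrix(presence)
  r <- nrow(presence); c <- ncol(presence)
  stop_if_not(r >= 1 && c >= 1, "degenerate matrix")
  p <- outer(rowSums(presence) / c, colSums(presence) / r, function(a, b) (a + b) / 2)
  dimnames(p) <- dimnames(presence)
  class(p) <- c("ce_probabilities", class(p))
  p
}

#' Sample one matrix from CE cell probabilities
#'
#' Independent Bernoulli draw per cell. Draws containing an all-zero row or
#' column are rejected and redrawn (they would make NODF's poorer lines
#' degenerate), up to `max_redraws` attempts.
#'
#' @param probs matrix from [ce_probabilities()].
#' @param seed optional seed; NULL continues the current RNG stream.
#' @param max_redraws redraw cap (default 1000).
#' @return binary matrix of the same shape.
#' @export
sample_ce <- function(probs, seed = NULL, max_redraws = 1000) {
  stop_if_not(is.matrix(probs) && is_prob(as.numeric(probs)),
              "`probs` must be a matrix of probabilities")
  with_seed(seed, {
    for (i in seq_len(max_redraws)) {
      m <- matrix(rbinom(length(probs), 1, probs), nrow(probs), ncol(probs),
                  dimnames = dimnames(probs))
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
    }
    stop("sample_ce: exceeded ", max_redraws,
         " redraws without a matrix free of empty rows/columns; ",
         "the matrix fill is too low for the CE null", call. = FALSE)
  })
}

new_null_ensemble <- function(metric, observed, null, tail, reps, seed) {
  b <- switch(tail,
              greater = sum(null >= observed),
              less = sum(null <= observed),
              two_sided = 2 * min(sum(null >= observed), sum(null <= observed)))
  p <- min(1, (1 + b) / (reps + 1))
  structure(list(metric = metric, observed = observed, null = null,
                 p_value = p, reps = reps, seed = seed, tail = tail),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: observed %0.4f vs null %0.4f +/- %0.4f (%d reps), p (%s) = %0.4g\n",
              x$metric, x$observed, mean(x$null), sd(x$null), x$reps, x$tail, x$p_value))
  invisible(x)
}

#' NODF significance and relative nestedness under the CE null
#'
#' Compares the observed NODF of a binary incidence matrix with the
#' distribution of NODF over CE-null matrices. The empirical p-value uses the
#' add-one rule `(1 + b) / (reps + 1)` so it is never 0.
#'
#' @param presence binary matrix.
#' @param reps number of null matrices (>= 100; default 1000).
#' @param seed RNG seed.
#' @param tail `"greater"` (default; nested more than expected), `"less"`, or
#'   `"two_sided"`.
#' @param probs optional cell-probability matrix to sample from; by default
#'   the CE probabilities are estimated from `presence` itself. Supplying the
#'   generating probabilities (when they are known, as in calibration
#'   studies) makes observed and null draws exchangeable and the p-value
#'   exactly uniform under the null; estimating them from the data makes the
#'   test mildly conservative.
#' @return list with `ensemble` (a `null_ensemble`) and `relative_nestedness`.
#' @export
nodf_null_test <- function(presence, reps = 1000, seed = NULL, tail = "greater",
                           probs = NULL) {
  stop_if_not(reps >= 100, "need reps >= 100")
  obs <- nodf(presence)
  probs <- probs %||% ce_probabilities(presence)
  null <- with_seed(seed, vapply(seq_len(reps), function(i) {
    nodf(sample_ce(probs))
  }, numeric(1)))
  ens <- new_null_ensemble("nodf", obs, null, tail, reps, seed)
  list(ensemble = ens, relative_nestedness = relative_nestedness(obs, null))
}

# Metrics of the plant projection of one binary incidence draw; all plants
# (including all-zero rows) count as nodes.
projection_metric_vector <- function(m) {
  g <- project_plants(m)
  c(mean_degree = mean(rowSums(g$adjacency)),
    connectance = connectance(g),
    clustering = clustering(g)$average)
}

#' Random-visitation null ensemble for projection metrics
#'
#' The frequency-based null for "non-choosy pollinators": (1) estimate each
#' species' interaction frequency `f_k` from the empirical incidence; (2)
#' build a master matrix of `master_rows` virtual plants x species filled
#' with independent Bernoulli(`f_k`) per column; (3) draw `reps` row
#' subsamples of the empirical plant count without replacement; (4) project
#' each subsample onto plants and compute mean degree, connectance and
#' clustering; (5) report one-tailed empirical p-values for the observed
#' metrics against these distributions.
#'
#' `f_k` defaults to presence frequency (share of empirical plants visited by
#' species k), which preserves expected species prevalence in null networks;
#' `frequency = "visits"` instead uses per-plant visit rates capped at 1.
#'
#' @param inc an `incidence_matrix`.
#' @param reps number of subsampled null networks (default 1000).
#' @param master_rows rows of the master matrix (default 100000; use 10000
#'   for desk-scale runs).
#' @param seed RNG seed.
#' @param frequency `"presence"` (default) or `"visits"`.
#' @param tail p-value tail, default `"greater"`.
#' @param frequencies optional vector of per-species interaction
#'   probabilities to fill the master matrix with, overriding estimation
#'   from `inc`. As with [nodf_null_test()], supplying the generating
#'   frequencies makes the test exactly calibrated; the default (frequencies
#'   re-estimated from the data being tested) is mildly conservative.
#' @return named list of `null_ensemble` objects: `mean_degree`,
#'   `connectance`, `clustering`.
#' @export
random_visitation_ensemble <- function(inc, reps = 1000, master_rows = 100000,
                                       seed = NULL, frequency = c("presence", "visits"),
                                       tail = "greater", frequencies = NULL) {
  stop_if_not(inherits(inc, "incidence_matrix"), "`inc` must be an incidence_matrix")
  frequency <- match.arg(frequency)
  p <- nrow(inc$presence); pol <- ncol(inc$presence)
  stop_if_not(master_rows >= p, "`master_rows` must be at least the number of plants")
  f <- frequencies %||% switch(frequency,
              presence = colSums(inc$presence) / p,
              visits = pmin(1, colSums(inc$counts) / p))
  stop_if_not(length(f) == pol && is_prob(f), "invalid interaction frequencies")
  if (all(f == 0)) stop("all interaction frequencies are zero", call. = FALSE)
  observed <- projection_metric_vector(inc$presence)
  null <- with_seed(seed, {
    master <- matrix(rbinom(master_rows * pol, 1, rep(f, each = master_rows)),
                     master_rows, pol)
    vapply(seq_len(reps), function(i) {
      rows <- sample.int(master_rows, p)
      projection_metric_vector(master[rows, , drop = FALSE])
    }, numeric(3))
  })
  out <- lapply(names(observed), function(nm) {
    new_null_ensemble(nm, observed[[nm]], null[nm, ], tail, reps, seed)
  })
  names(out) <- names(observed)
  out
}
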