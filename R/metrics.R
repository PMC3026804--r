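#' NODF nestedness of a binary matrix
#'
#' Nestedness based on Overlap and Decreasing Fill. For every unordered pair
#' of rows (and of columns) with strictly different marginal totals, the
#' paired nestedness is the percentage of the poorer line's presences that
#' also occur in the richer line; pairs with equal fills (or an empty poorer
#' line) contribute 0. NODF is the mean paired value over all row pairs and
#' all column pairs, on a 0-100 scale.
#'
#' @param presence binary matrix with at least 2 rows and 2 columns.
#' @return scalar in \[0, 100\].
#' @export
nodf <- function(presence) {
  assert_binary_matrix(presence)
  stop_if_not(nrow(presence) >= 2 && ncol(presence) >= 2,
              "NODF needs at least a 2 x 2 matrix")
  if (all(presence == 0)) {
    warning("all-zero matrix: NODF defined as 0")
    return(0)
  }
  sum_pairs <- function(m) {
    fill <- rowSums(m)
    overlap <- tcrossprod(m)       # shared presences for each line pair
    lo <- outer(fill, fill, pmin)
    active <- outer(fill, fill, "!=") & lo > 0
    contrib <- ifelse(active, 100 * overlap / pmax(lo, 1), 0)
    sum(contrib[upper.tri(contrib)])
  }
  npairs <- choose(nrow(presence), 2) + choose(ncol(presence), 2)
  (sum_pairs(presence) + sum_pairs(t(presence))) / npairs
}

#' Relative nestedness
#'
#' Standardizes an observed nestedness score against a null distribution:
#' `(observed - mean(null)) / mean(null)`.
#'
#' @param observed_nodf observed NODF value.
#' @param null_nodfs numeric vector of null NODF values (>= 100 draws).
#' @return scalar relative nestedness.
#' @export
relative_nestedness <- function(observed_nodf, null_nodfs) {
  stop_if_not(length(null_nodfs) >= 100, "need at least 100 null samples")
  m <- mean(null_nodfs)
  if (m == 0) stop("null mean is 0: relative nestedness undefined", call. = FALSE)
  (observed_nodf - m) / m
}

#' Degree statistics of a projection graph
#'
#' Degrees are taken on the simple-graph reduction. The normalized degree of
#' a node is its degree divided by `n - 1`; the report gives the mean with
#' the standard error of the mean (sd / sqrt(n)), matching the
#' "mean +/- SE" presentation conventional for these networks.
#'
#' @param g a [projection_graph()] with >= 2 nodes.
#' @return list with `degrees` (named), `mean_degree`, `normalized`,
#'   `normalized_mean`, `normalized_se`.
#' @export
degree_stats <- function(g) {
  stop_if_not(inherits(g, "projection_graph"), "`g` must be a projection_graph")
  stop_if_not(g$n >= 2, "need at least 2 nodes")
  k <- rowSums(g$adjacency)
  nd <- k / (g$n - 1)
  list(degrees = k, mean_degree = mean(k), normalized = nd,
       normalized_mean = mean(nd), normalized_se = sd(nd) / sqrt(g$n))
}

#' Connectance of a projection graph
#'
#' Realized proportion of links in the simple reduction relative to the
#' maximum `n (n - 1) / 2`.
#'
#' @inheritParams degree_stats
#' @return scalar in \[0, 1\].
#' @export
connectance <- function(g) {
  stop_if_not(inherits(g, "projection_graph"), "`g` must be a projection_graph")
  stop_if_not(g$n >= 2, "need at least 2 nodes")
  g$L / (g$n * (g$n - 1) / 2)
}

#' Clustering coefficients (CC1)
#'
#' Per-node clustering is the fraction of a node's neighbour pairs that are
#' themselves linked, `C_i = e_i / (k_i (k_i - 1) / 2)`, computed on the
#' simple reduction. Nodes with degree <= 1 have no neighbour pair and are
#' assigned `C_i = 0` (the Pajek CC1 convention), which keeps the network
#' average defined for sparse graphs.
#'
#' @inheritParams degree_stats
#' @return list with `local` (per-node C_i) and `average` (C-bar).
#' @export
clustering <- function(g) {
  stop_if_not(inherits(g, "projection_graph"), "`g` must be a projection_graph")
  a <- g$adjacency
  k <- rowSums(a)
  # diag(A^3)[i] = 2 * number of edges among neighbours of i
  a3 <- a %*% a %*% a
  ci <- ifelse(k <= 1, 0, diag(a3) / (k * (k - 1)))
  names(ci) <- g$nodes
  list(local = ci, average = mean(ci))
}

#' Architecture metrics report for one network
#'
#' Bundles the Table-1-style metrics of a plant projection graph, optionally
#' adding NODF of the underlying incidence matrix.
#'
#' @param g a [projection_graph()].
#' @param inc optional `incidence_matrix` for NODF.
#' @return object of class `metrics_report` (a list): `n`, `L`, `nodf`,
#'   `mean_degree`, `normalized_degree_mean`, `normalized_degree_se`,
#'   `connectance`, `clustering`, plus per-node `degrees` and
#'   `local_clustering`.
#' @export
network_metrics <- function(g, inc = NULL) {
  ds <- degree_stats(g)
  cl <- clustering(g)
  structure(list(
    n = g$n, L = g$L,
    nodf = if (!is.null(inc)) nodf(if (inherits(inc, "incidence_matrix")) inc$presence else inc) else NA_real_,
    mean_degree = ds$mean_degree,
    normalized_degree_mean = ds$normalized_mean,
    normalized_degree_se = ds$normalized_se,
    connectance = connectance(g),
    clustering = cl$average,
    degrees = ds$degrees,
    local_clustering = cl$local
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d L=%d NODF=%s k=%0.2f ",
                     "nd=%0.3f+/-%0.3f C=%0.3f cc=%0.3f\n"),
              x$n, x$L,
              if (is.na(x$nodf)) "NA" else sprintf("%0.2f", x$nodf),
              x$mean_degree, x$normalized_degree_mean, x$normalized_degree_se,
              x$connectance, x$clustering))
  invisible(x)
}
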