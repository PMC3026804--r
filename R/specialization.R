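#' Functional specialization between pollinator types
#'
#' The FS index of a focal functional group with respect to a target group is
#' the mean, over focal-group species, of the mean unweighted shortest-path
#' distance from that species to each species of the target group in the
#' pollinator projection graph. Small values mean the focal type is directly
#' linked (shares plants) with the target type. Disconnected focal/target
#' pairs (infinite distance) are excluded from the means with a warning.
#'
#' @param pg a [projection_graph()] on pollinator species with non-NULL
#'   `groups`.
#' @param focal_group,target_group functional group labels present in
#'   `pg$groups`.
#' @return scalar FS value (NA if every pair is disconnected).
#' @export
functional_specialization <- function(pg, focal_group, target_group) {
  stop_if_not(inherits(pg, "projection_graph"), "`pg` must be a projection_graph")
  stop_if_not(!is.null(pg$groups), "pollinator graph has no functional group labels")
  focal <- pg$nodes[pg$groups == focal_group & !is.na(pg$groups)]
  target <- pg$nodes[pg$groups == target_group & !is.na(pg$groups)]
  stop_if_not(length(focal) > 0, sprintf("no species in focal group '%s'", focal_group))
  stop_if_not(length(target) > 0, sprintf("no species in target group '%s'", target_group))
  d <- igraph::distances(as_igraph(pg), v = focal, to = target)
  if (any(is.infinite(d))) {
    warning(sprintf("%d disconnected species pairs excluded from FS(%s, %s)",
                    sum(is.infinite(d)), focal_group, target_group))
    d[is.infinite(d)] <- NA
  }
  per_focal <- rowMeans(d, na.rm = TRUE)
  per_focal <- per_focal[is.finite(per_focal)]
  if (!length(per_focal)) return(NA_real_)
  mean(per_focal)
}

#' Group-level functional specialization
#'
#' For each functional group, the mean FS over all other groups present in
#' the graph (the quantity compared across pollinator types).
#'
#' @inheritParams functional_specialization
#' @return named numeric vector, one FS value per group.
#' @export
group_specialization <- function(pg) {
  groups <- sort(unique(pg$groups[!is.na(pg$groups)]))
  stop_if_not(length(groups) >= 2, "need at least 2 functional groups")
  out <- vapply(groups, function(a) {
    mean(vapply(setdiff(groups, a), function(b) {
      suppressWarnings(functional_specialization(pg, a, b))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  names(out) <- groups
  out
}

#' Hub scores of a projection graph
#'
#' Mutually reinforcing hub/authority scores computed by power iteration on
#' the simple adjacency matrix. Because the adjacency is symmetric, hubs and
#' authorities coincide with principal-eigenvector centrality; iterating on
#' A^2 (the HITS update collapsed onto itself) guarantees convergence on
#' bipartite-like components as well. Scores are normalized to a maximum of 1.
#'
#' @param pg a [projection_graph()] whose largest component has >= 2 nodes.
#' @param tol convergence tolerance on the max absolute change (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return named numeric vector of scores in \[0, 1\], max exactly 1.
#' @export
hub_scores <- function(pg, tol = 1e-10, max_iter = 1000) {
  stop_if_not(inherits(pg, "projection_graph"), "`pg` must be a projection_graph")
  stop_if_not(pg$L >= 1, "graph has no edges: hub scores undefined")
  a <- pg$adjacency
  x <- rep(1, pg$n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% (a %*% x))   # h <- A a, a <- A h  (A symmetric)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) stop("power iteration collapsed to zero vector", call. = FALSE)
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      scores <- y / max(y)
      names(scores) <- pg$nodes
      return(scores)
    }
    x <- y
  }
  stop(sprintf("hub scores did not converge in %d iterations", max_iter), call. = FALSE)
}

#' Group-level hub degree
#'
#' Mean hub score of the species belonging to each functional group (the
#' per-type "hub degree" compared across pollinator types).
#'
#' @inheritParams hub_scores
#' @return named numeric vector, one mean score per functional group.
#' @export
group_hub_degree <- function(pg, tol = 1e-10, max_iter = 1000) {
  stop_if_not(!is.null(pg$groups), "pollinator graph has no functional group labels")
  s <- hub_scores(pg, tol = tol, max_iter = max_iter)
  grp <- pg$groups[pg$nodes]
  keep <- !is.na(grp)
  tapply(s[keep], grp[keep], mean)
}
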