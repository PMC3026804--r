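#' Unipartite projection graphs
#'
#' A `projection_graph` is an undirected multigraph on one mode of a bipartite
#' network. Nodes of the chosen mode are linked whenever they share at least
#' one partner in the other mode; the edge multiplicity equals the number of
#' shared partners. Self-loops are never stored. The simple-graph reduction
#' (multiplicity collapsed to presence/absence) is what all Table-style
#' metrics are computed on.
#'
#' @param mult symmetric nonnegative integer matrix of shared-partner counts
#'   with zero diagonal; dimnames give node ids.
#' @param groups optional named character vector of node labels (functional
#'   groups, for pollinator graphs).
#' @return object of class `projection_graph` with elements `nodes`, `mult`
#'   (multiplicity matrix), `adjacency` (0/1 simple reduction), `n`, `L`
#'   (simple edge count), `groups`.
#' @export
projection_graph <- function(mult, groups = NULL) {
  stop_if_not(is.matrix(mult) && nrow(mult) == ncol(mult),
              "`mult` must be a square matrix")
  stop_if_not(all(mult >= 0) && all(mult == floor(mult)),
              "multiplicities must be nonnegative integers")
  stop_if_not(all(diag(mult) == 0), "self-loops are not allowed")
  stop_if_not(isTRUE(all.equal(mult, t(mult))), "`mult` must be symmetric")
  nodes <- rownames(mult) %||% as.character(seq_len(nrow(mult)))
  dimnames(mult) <- list(nodes, nodes)
  adj <- (mult > 0) + 0L
  if (!is.null(groups)) groups <- groups[nodes]
  structure(list(nodes = nodes, mult = mult, adjacency = adj,
                 n = nrow(mult), L = sum(adj) / 2L, groups = groups),
            class = "projection_graph")
}

#' Project the plant (row) mode of an incidence matrix
#'
#' Plants are linked when they share at least one pollinator species; the
#' multiplicity of a plant pair is the number of species they share
#' (presence/absence, not visit counts). Plants sharing no pollinator remain
#' as isolated nodes: every censused plant counts in degree and connectance
#' denominators.
#'
#' @param inc an `incidence_matrix` from [build_incidence()], or a binary
#'   matrix.
#' @return a [projection_graph()] on plants.
#' @export
project_plants <- function(inc) {
  m <- if (inherits(inc, "incidence_matrix")) inc$presence else inc
  assert_binary_matrix(m)
  shared <- tcrossprod(m)        # shared[i,j] = # species visiting both i and j
  diag(shared) <- 0
  projection_graph(shared)
}

#' Project the pollinator (column) mode of an incidence matrix
#'
#' Mirror of [project_plants()] with the roles of rows and columns swapped:
#' two pollinator species are linked when they visit at least one common
#' plant, with multiplicity the number of shared plants. Functional-group
#' labels are carried along when available.
#'
#' @inheritParams project_plants
#' @return a [projection_graph()] on pollinator species.
#' @export
project_pollinators <- function(inc) {
  groups <- NULL
  if (inherits(inc, "incidence_matrix")) {
    groups <- inc$groups
    m <- inc$presence
  } else m <- inc
  assert_binary_matrix(m)
  shared <- crossprod(m)
  diag(shared) <- 0
  projection_graph(shared, groups = groups)
}

#' @export
print.projection_graph <- function(x, ...) {
  cat(sprintf("<projection_graph> %d nodes, %d simple edges (%d shared-partner lines)\n",
              x$n, x$L, sum(x$mult) / 2))
  invisible(x)
}

# igraph view of the simple reduction (used for shortest paths).
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}
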