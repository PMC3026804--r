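#' Hurlbert's PIE
#'
#' Probability of an Interspecific Encounter with small-sample correction:
#' `(N / (N - 1)) * (1 - sum(p_i^2))` for total count N and species
#' proportions p_i.
#'
#' @param counts nonnegative species count vector with total >= 2.
#' @return scalar in \[0, 1\].
#' @export
hurlbert_pie <- function(counts) {
  stop_if_not(is.numeric(counts) && all(counts >= 0), "counts must be nonnegative")
  n <- sum(counts)
  stop_if_not(n >= 2, "need total count >= 2")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

check_pair <- function(x, y) {
  stop_if_not(is.numeric(x) && is.numeric(y) && length(x) == length(y),
              "vectors must be numeric and of equal length")
  stop_if_not(all(x >= 0) && all(y >= 0), "abundances must be nonnegative")
  stop_if_not(sum(x) + sum(y) > 0, "both vectors are all zero")
}

#' Bray-Curtis dissimilarity
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)`; 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param x,y nonnegative abundance vectors of equal length, not both zero.
#' @return scalar in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Morisita-Horn dissimilarity
#'
#' One minus the Morisita-Horn similarity
#' `2 sum(x_i y_i) / ((dx + dy) X Y)` with `dx = sum(x_i^2)/X^2`,
#' `dy = sum(y_i^2)/Y^2` and X, Y the totals.
#'
#' @inheritParams bray_curtis
#' @return scalar in \[0, 1\].
#' @export
morisita_horn <- function(x, y) {
  check_pair(x, y)
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) return(1)
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  1 - 2 * sum(x * y) / ((dx + dy) * X * Y)
}

#' Pairwise dissimilarity matrix over assemblages
#'
#' @param counts matrix of species counts, one row per assemblage
#'   (population), one column per species.
#' @param method `"bray_curtis"` or `"morisita_horn"`.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(counts, method = c("bray_curtis", "morisita_horn")) {
  method <- match.arg(method)
  f <- switch(method, bray_curtis = bray_curtis, morisita_horn = morisita_horn)
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- f(counts[i, ], counts[j, ])
    }
  }
  d
}

#' Assemblage descriptors per population
#'
#' Summarizes the pollinator assemblage of each population from a visitation
#' table: total visits (abundance), observed species richness and Hurlbert's
#' PIE on species visit totals, plus the population x species count table and
#' pairwise Bray-Curtis / Morisita-Horn dissimilarity matrices.
#'
#' @param visits a [visitation_table()].
#' @return list with `summary` (data.frame: population_id, abundance, s_obs,
#'   hurlbert_pie), `counts` (populations x species), `bray_curtis`,
#'   `morisita_horn`.
#' @export
assemblage_summary <- function(visits) {
  visits <- visitation_table(as.data.frame(visits))
  rows <- visits[visits$visits > 0, , drop = FALSE]
  stop_if_not(nrow(rows) > 0, "no visits recorded")
  pops <- unique(as.character(visits$population_id))
  pops <- pops[id_order(pops)]
  species <- unique(as.character(rows$pollinator_species))
  species <- species[id_order(species)]
  counts <- matrix(0, length(pops), length(species), dimnames = list(pops, species))
  agg <- stats::aggregate(visits ~ population_id + pollinator_species, data = rows, FUN = sum)
  counts[cbind(match(as.character(agg$population_id), pops),
               match(as.character(agg$pollinator_species), species))] <- agg$visits
  summary <- data.frame(
    population_id = pops,
    abundance = rowSums(counts),
    s_obs = rowSums(counts > 0),
    hurlbert_pie = apply(counts, 1, function(x) if (sum(x) >= 2) hurlbert_pie(x) else NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, counts = counts,
       bray_curtis = if (length(pops) > 1) dissimilarity_matrix(counts, "bray_curtis") else NULL,
       morisita_horn = if (length(pops) > 1) dissimilarity_matrix(counts, "morisita_horn") else NULL)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition, e.g. for comparing
#' hub degree or functional specialization across pollinator types.
#'
#' @param values numeric response vector.
#' @param group_labels grouping vector of the same length (>= 2 groups).
#' @return list with `f`, `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(values, group_labels) {
  keep <- is.finite(values) & !is.na(group_labels)
  values <- values[keep]; group_labels <- as.character(group_labels[keep])
  g <- unique(group_labels)
  stop_if_not(length(g) >= 2, "need at least 2 groups")
  n <- length(values)
  df1 <- length(g) - 1L
  df2 <- n - length(g)
  stop_if_not(df2 >= 1, "need at least 1 residual degree of freedom")
  grand <- mean(values)
  means <- tapply(values, group_labels, mean)
  sizes <- tapply(values, group_labels, length)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[group_labels])^2)
  if (ssw == 0) stop("zero within-group variance: F undefined", call. = FALSE)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p_value = pf(f, df1, df2, lower.tail = FALSE))
}
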