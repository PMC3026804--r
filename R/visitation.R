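#' Construct and validate a visitation table
#'
#' A visitation table holds raw pollinator survey records: one row per
#' (population, survey, plant, pollinator species) with the number of visits
#' recorded during that survey, the observation time, and the number of open
#' flowers on the plant. Rows with `visits = 0` and `pollinator_species = NA`
#' are allowed as effort placeholders: they record that a plant was watched
#' during a survey without receiving any visit, which the census filter needs
#' in order to distinguish "unobserved" from "observed but unvisited".
#'
#' @param df data.frame with columns `population_id`, `survey`, `plant_id`,
#'   `pollinator_species`, `functional_group`, `visits`, `minutes_observed`,
#'   `open_flowers`.
#' @return the validated data.frame with class `visitation_table`.
#' @export
visitation_table <- function(df) {
  required <- c("population_id", "survey", "plant_id", "pollinator_species",
                "functional_group", "visits", "minutes_observed", "open_flowers")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("visitation table is missing columns: ", paste(missing, collapse = ", "),
         "; expected header: ", paste(required, collapse = ", "), call. = FALSE)
  }
  stop_if_not(is.numeric(df$visits) && all(is.finite(df$visits)) && all(df$visits >= 0),
              "`visits` must be nonnegative and finite")
  stop_if_not(all(df$visits == floor(df$visits)), "`visits` must be whole numbers")
  stop_if_not(is.numeric(df$minutes_observed) && all(df$minutes_observed > 0),
              "`minutes_observed` must be positive")
  stop_if_not(all(is.na(df$open_flowers) | df$open_flowers >= 0),
              "`open_flowers` must be nonnegative")
  visited <- df[df$visits > 0, , drop = FALSE]
  key <- paste(visited$population_id, visited$survey, visited$plant_id,
               visited$pollinator_species, sep = "\r")
  stop_if_not(!anyDuplicated(key),
              "duplicate (population, survey, plant, species) records with visits > 0")
  class(df) <- c("visitation_table", "data.frame")
  df
}

# Total observation minutes per plant: each distinct (plant, survey) pair
# contributes its minutes once, regardless of how many species rows it has.
plant_effort <- function(visits) {
  u <- visits[!duplicated(paste(visits$population_id, visits$plant_id,
                                visits$survey, sep = "\r")),
              c("population_id", "plant_id", "survey", "minutes_observed")]
  stats::aggregate(minutes_observed ~ population_id + plant_id, data = u, FUN = sum)
}

#' Apply the census filter to a visitation table
#'
#' Retains exactly the plants censused for *strictly more* than `min_minutes`
#' in total AND receiving at least one visit (summed over all surveys and
#' species). A plant observed for exactly 15 minutes is dropped. The counts
#' of plants dropped per reason are attached as the `"dropped"` attribute and
#' reported via `message()`.
#'
#' @param visits a [visitation_table()].
#' @param min_minutes minutes threshold (default 15; strict inequality).
#' @return filtered `visitation_table`, with attribute `dropped` = named
#'   vector `c(too_few_minutes, no_visits, kept)`.
#' @export
filter_plants <- function(visits, min_minutes = 15) {
  visits <- visitation_table(as.data.frame(visits))
  eff <- plant_effort(visits)
  vis <- stats::aggregate(visits ~ population_id + plant_id, data = visits, FUN = sum)
  tab <- merge(eff, vis, by = c("population_id", "plant_id"), all = TRUE)
  tab$visits[is.na(tab$visits)] <- 0
  enough_time <- tab$minutes_observed > min_minutes
  any_visit <- tab$visits >= 1
  keep <- enough_time & any_visit
  if (!any(keep)) stop("no plants survive filter (> ", min_minutes,
                       " min and >= 1 visit)", call. = FALSE)
  dropped <- c(too_few_minutes = sum(!enough_time),
               no_visits = sum(enough_time & !any_visit),
               kept = sum(keep))
  keep_key <- paste(tab$population_id, tab$plant_id, sep = "\r")[keep]
  out <- visits[paste(visits$population_id, visits$plant_id, sep = "\r") %in% keep_key, ,
                drop = FALSE]
  rownames(out) <- NULL
  out <- visitation_table(out)
  attr(out, "dropped") <- dropped
  message(sprintf("filter_plants: kept %d plants (%d dropped for effort <= %g min, %d for zero visits)",
                  dropped[["kept"]], dropped[["too_few_minutes"]], min_minutes,
                  dropped[["no_visits"]]))
  out
}

#' Build the bipartite incidence matrix from visitation records
#'
#' Aggregates visits over surveys into a plants x pollinator-species count
#' matrix plus its 0/1 presence indicator. Rows and columns are ordered by id
#' (radix/C-locale) so output is deterministic. Placeholder zero-visit rows
#' contribute nothing; plants appearing only in placeholders become all-zero
#' rows only if `visits` was not filtered first.
#'
#' @param visits a [visitation_table()], normally already passed through
#'   [filter_plants()].
#' @return object of class `incidence_matrix`: list with `presence`, `counts`
#'   (matrices with plant rownames / species colnames), `plants`,
#'   `pollinators`, `groups` (functional group per species).
#' @export
build_incidence <- function(visits) {
  visits <- visitation_table(as.data.frame(visits))
  plants <- unique(as.character(visits$plant_id))
  plants <- plants[id_order(plants)]
  rows <- visits[visits$visits > 0, , drop = FALSE]
  species <- unique(as.character(rows$pollinator_species))
  species <- species[id_order(species)]
  counts <- matrix(0L, length(plants), length(species),
                   dimnames = list(plants, species))
  if (nrow(rows)) {
    agg <- stats::aggregate(visits ~ plant_id + pollinator_species, data = rows, FUN = sum)
    counts[cbind(match(as.character(agg$plant_id), plants),
                 match(as.character(agg$pollinator_species), species))] <-
      as.integer(agg$visits)
  }
  groups <- rep(NA_character_, length(species))
  names(groups) <- species
  if (nrow(rows)) {
    g <- rows[!duplicated(as.character(rows$pollinator_species)),
              c("pollinator_species", "functional_group")]
    groups[as.character(g$pollinator_species)] <- as.character(g$functional_group)
  }
  structure(list(presence = (counts >= 1) + 0L, counts = counts,
                 plants = plants, pollinators = species, groups = groups),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d plants x %d pollinator species, fill %.3f\n",
              length(x$plants), length(x$pollinators),
              mean(x$presence)))
  invisible(x)
}
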