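# File formats: CSV tables with provenance headers, Pajek .net multigraphs,
# GraphML export. CSVs are comma-separated UTF-8 with a header row; lines
# starting with '#' are provenance comments and are skipped on read.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  c(sprintf("# pollinet %s", as.character(utils::packageVersion("pollinet"))),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    if (!is.null(config_hash)) sprintf("# config: %s", config_hash))
}

write_table_with_header <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_checked_csv <- function(path, required, what) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file %s is missing columns: %s; expected header: %s",
                 what, path, paste(missing, collapse = ", "),
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a visitation survey CSV
#'
#' Expects columns `population_id, survey, plant_id, pollinator_species,
#' functional_group, visits, minutes_observed, open_flowers` (see the data
#' dictionary in `inst/extdata/data_dictionary.csv`). Rows are
#' schema-validated; negative visits or non-positive minutes are errors.
#'
#' @param path CSV path.
#' @return a [visitation_table()].
#' @export
read_visitation <- function(path) {
  df <- read_checked_csv(path, c("population_id", "survey", "plant_id",
                                 "pollinator_species", "functional_group",
                                 "visits", "minutes_observed", "open_flowers"),
                         "visitation")
  message(sprintf("read_visitation: %d rows from %s", nrow(df), path))
  visitation_table(df)
}

#' Read a plant table CSV
#'
#' Expects at least `population_id, plant_id, x, y, flowers`; fitness
#' component columns (`fruits`, `seeds`, `juveniles`, ...) are carried along
#' when present.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plants <- function(path) {
  df <- read_checked_csv(path, c("population_id", "plant_id", "x", "y", "flowers"),
                         "plant")
  stop_if_not(all(df$flowers >= 1), "`flowers` must be >= 1")
  df
}

#' Read a population table CSV
#'
#' Expects `population_id, x_km, y_km`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_populations <- function(path) {
  df <- read_checked_csv(path, c("population_id", "x_km", "y_km"), "population")
  stop_if_not(!anyDuplicated(df$population_id), "duplicate population ids")
  df
}

#' Write the three study tables of a synthetic study
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  stop_if_not(inherits(study, "pollination_study"), "`study` must be a pollination_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(visits = file.path(dir, "visitation.csv"),
             plants = file.path(dir, "plants.csv"),
             populations = file.path(dir, "populations.csv"))
  write_table_with_header(as.data.frame(study$visits), paths["visits"], seed = study$seed)
  write_table_with_header(study$plants, paths["plants"], seed = study$seed)
  write_table_with_header(study$populations, paths["populations"], seed = study$seed)
  invisible(paths)
}

#' Write a projection graph as a Pajek .net file
#'
#' Vertices are listed with quoted labels; each shared-partner line is
#' written as its own edge line (`collapse = TRUE` writes one line per pair
#' with the multiplicity as edge weight instead).
#'
#' @param g a [projection_graph()].
#' @param path output path.
#' @param collapse write one weighted line per pair instead of parallel
#'   lines (default FALSE).
#' @return invisibly, `path`.
#' @export
write_pajek <- function(g, path, collapse = FALSE) {
  stop_if_not(inherits(g, "projection_graph"), "`g` must be a projection_graph")
  lines <- c(sprintf("*Vertices %d", g$n),
             sprintf("%d \"%s\"", seq_len(g$n), g$nodes),
             "*Edges")
  idx <- which(upper.tri(g$mult) & g$mult > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    m <- g$mult[idx]
    if (collapse) {
      lines <- c(lines, sprintf("%d %d %d", idx[, 1], idx[, 2], m))
    } else {
      rep_i <- rep(idx[, 1], m); rep_j <- rep(idx[, 2], m)
      lines <- c(lines, sprintf("%d %d 1", rep_i, rep_j))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a Pajek .net file written by [write_pajek()]
#'
#' Parallel edge lines accumulate multiplicity; weighted lines contribute
#' their weight.
#'
#' @param path .net path.
#' @return a [projection_graph()].
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  ehead <- grep("^\\*Edges", lines, ignore.case = TRUE)
  stop_if_not(length(vhead) == 1 && length(ehead) == 1, "not a Pajek .net file")
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead], ignore.case = TRUE))
  vlines <- lines[(vhead + 1):(ehead - 1)]
  labels <- sub("^\\s*\\d+\\s+\"(.*)\".*$", "\\1", vlines)
  mult <- matrix(0L, n, n, dimnames = list(labels, labels))
  elines <- lines[-seq_len(ehead)]
  elines <- elines[nzchar(trimws(elines))]
  for (l in elines) {
    f <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    w <- if (length(f) >= 3) f[3] else 1
    mult[f[1], f[2]] <- mult[f[1], f[2]] + as.integer(w)
    mult[f[2], f[1]] <- mult[f[1], f[2]]
  }
  projection_graph(mult)
}

#' Write a projection graph as GraphML
#'
#' One edge element per simple edge, with the shared-partner multiplicity as
#' a `weight` attribute; node functional groups (when present) are exported
#' as a `group` attribute. Export-only: intended for external layout tools.
#'
#' @inheritParams write_pajek
#' @return invisibly, `path`.
#' @export
write_graphml <- function(g, path) {
  stop_if_not(inherits(g, "projection_graph"), "`g` must be a projection_graph")
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  nodes <- vapply(seq_len(g$n), function(i) {
    grp <- if (!is.null(g$groups) && !is.na(g$groups[i]))
      sprintf("<data key=\"group\">%s</data>", esc(g$groups[i])) else ""
    sprintf("  <node id=\"n%d\"><data key=\"label\">%s</data>%s</node>",
            i, esc(g$nodes[i]), grp)
  }, character(1))
  idx <- which(upper.tri(g$mult) & g$mult > 0, arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    sprintf("  <edge source=\"n%d\" target=\"n%d\"><data key=\"weight\">%d</data></edge>",
            idx[, 1], idx[, 2], g$mult[idx])
  } else character(0)
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "<key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
    "<key id=\"group\" for=\"node\" attr.name=\"group\" attr.type=\"string\"/>",
    "<key id=\"weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"int\"/>",
    "<graph edgedefault=\"undirected\">",
    nodes, edges, "</graph>", "</graphml>"), path, useBytes = TRUE)
  invisible(path)
}

#' Write an incidence matrix as dense CSV
#'
#' @param inc an `incidence_matrix`.
#' @param path output path.
#' @param what `"presence"` (default) or `"counts"`.
#' @return invisibly, `path`.
#' @export
write_incidence <- function(inc, path, what = c("presence", "counts")) {
  what <- match.arg(what)
  write.csv(as.data.frame(inc[[what]]), path, row.names = TRUE)
  invisible(path)
}
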