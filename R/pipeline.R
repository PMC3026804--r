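#' Assemble a study configuration
#'
#' Collects file paths, thresholds, null-model sizes and seeds for
#' [run_pipeline()]. Either the three table paths or an in-memory
#' [simulate_study()] object must be supplied.
#'
#' @param visitation,plants,populations CSV paths (see [read_visitation()],
#'   [read_plants()], [read_populations()]).
#' @param study optional `pollination_study` object, used instead of paths.
#' @param min_minutes census filter threshold (default 15).
#' @param nodf_reps CE-null replicates for nestedness (default 1000).
#' @param rv_reps random-visitation null replicates (default 1000).
#' @param master_rows master-matrix rows for the visitation null (default
#'   100000; use 10000 for desk-scale runs).
#' @param sar_scheme spatial weight scheme (default `"inverse_distance"`).
#' @param seed master seed; all stage seeds are derived from it.
#' @param out_dir output directory, or NULL to skip writing files.
#' @return list of class `study_config`.
#' @export
study_config <- function(visitation = NULL, plants = NULL, populations = NULL,
                         study = NULL, min_minutes = 15, nodf_reps = 1000,
                         rv_reps = 1000, master_rows = 100000,
                         sar_scheme = "inverse_distance", seed = 1,
                         out_dir = NULL) {
  if (is.null(study)) {
    for (p in c(visitation, plants, populations)) {
      stop_if_not(!is.null(p) && file.exists(p), sprintf("input path missing: %s", p %||% "<NULL>"))
    }
  }
  if (nodf_reps < 100 || rv_reps < 100) {
    warning("null-model replicates below 100: p-values will be coarse")
  }
  structure(list(visitation = visitation, plants = plants, populations = populations,
                 study = study, min_minutes = min_minutes, nodf_reps = nodf_reps,
                 rv_reps = rv_reps, master_rows = master_rows,
                 sar_scheme = sar_scheme, seed = seed, out_dir = out_dir),
            class = "study_config")
}

config_digest <- function(config) {
  fields <- config[c("min_minutes", "nodf_reps", "rv_reps", "master_rows",
                     "sar_scheme", "seed")]
  paste(names(fields), vapply(fields, format, character(1)),
        sep = "=", collapse = ";")
}

# Difference matrix of a per-population metric, for Mantel tests.
metric_distance <- function(x, ids) {
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(ids, ids)
  d
}

#' Run the full analysis pipeline
#'
#' Executes: census filter -> incidence -> plant and pollinator projections
#' -> architecture metrics -> CE and random-visitation null models ->
#' assemblage descriptors -> pollinator-type comparisons (hub degree and
#' functional specialization ANOVA) -> residualization -> spatial regression
#' of per-capita juvenile production on residualized metrics -> partial
#' Mantel tests of metric differences against assemblage dissimilarity.
#' Writes a network-summary CSV (one row per population), a
#' predictor-by-metric CSV of the assemblage correlates, a performance SAR
#' CSV, a JSON report and a plain-text log; all outputs carry a provenance
#' header and are byte-identical across runs with the same config.
#'
#' @param config a [study_config()].
#' @return invisibly, a list with all intermediate objects (`networks`,
#'   `table1`, `table2`, `assemblage`, `performance_sar`, `anova`, `log`).
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "study_config"), "`config` must be a study_config")
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  note("pollinet pipeline; config %s", config_digest(config))

  if (!is.null(config$study)) {
    visits <- config$study$visits
    plants <- config$study$plants
    populations <- config$study$populations
  } else {
    visits <- stage("read_visitation", read_visitation(config$visitation))
    plants <- stage("read_plants", read_plants(config$plants))
    populations <- stage("read_populations", read_populations(config$populations))
  }
  pops <- unique(as.character(populations$population_id))
  pops <- pops[id_order(pops)]
  note("inputs: %d populations, %d plants, %d visit rows", length(pops),
       nrow(plants), nrow(visits))

  networks <- list()
  t1 <- list()
  pol_groups <- list()
  for (pid in pops) {
    v <- visits[visits$population_id == pid, , drop = FALSE]
    filt <- stage(paste0("filter:", pid),
                  suppressMessages(filter_plants(v, config$min_minutes)))
    dropped <- attr(filt, "dropped")
    note("%s: filter kept %d plants (%d effort, %d zero-visit dropped)", pid,
         dropped[["kept"]], dropped[["too_few_minutes"]], dropped[["no_visits"]])
    inc <- stage(paste0("incidence:", pid), build_incidence(filt))
    g <- project_plants(inc)
    pg <- project_pollinators(inc)
    met <- network_metrics(g, inc)
    ce_seed <- child_seed(config$seed, match(pid, pops))
    nt <- stage(paste0("nodf_null:", pid),
                nodf_null_test(inc$presence, reps = config$nodf_reps, seed = ce_seed))
    rv_seed <- child_seed(config$seed, 1000 + match(pid, pops))
    rv <- stage(paste0("rv_null:", pid),
                random_visitation_ensemble(inc, reps = config$rv_reps,
                                           master_rows = config$master_rows,
                                           seed = rv_seed))
    networks[[pid]] <- list(incidence = inc, plant_graph = g, pollinator_graph = pg,
                            metrics = met, nodf_null = nt, rv_null = rv)
    t1[[pid]] <- data.frame(
      population_id = pid,
      n_plants = met$n, n_pollinators = length(inc$pollinators),
      nestedness = met$nodf,
      relative_nestedness = nt$relative_nestedness,
      nestedness_p = nt$ensemble$p_value,
      normalized_degree = met$normalized_degree_mean,
      normalized_degree_se = met$normalized_degree_se,
      degree_p = rv$mean_degree$p_value,
      connectance = met$connectance,
      connectance_p = rv$connectance$p_value,
      clustering = met$clustering,
      clustering_p = rv$clustering$p_value,
      stringsAsFactors = FALSE)
    # pollinator-type scores for the across-population ANOVA
    hub <- tryCatch(group_hub_degree(pg), error = function(e) NULL)
    fs <- tryCatch(suppressWarnings(group_specialization(pg)), error = function(e) NULL)
    if (!is.null(hub)) {
      pol_groups[[pid]] <- data.frame(
        population_id = pid, functional_group = names(hub),
        hub_degree = as.numeric(hub),
        fs = if (!is.null(fs)) as.numeric(fs[names(hub)]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  table1 <- do.call(rbind, t1); rownames(table1) <- NULL

  assem <- stage("assemblage", assemblage_summary(
    suppressMessages(filter_plants(visits, config$min_minutes))))
  assem_sum <- assem$summary[match(pops, assem$summary$population_id), ]

  pol_df <- if (length(pol_groups)) do.call(rbind, pol_groups) else NULL
  anova_res <- list()
  if (!is.null(pol_df)) {
    keep <- names(which(table(pol_df$functional_group) >= 2))
    sub <- pol_df[pol_df$functional_group %in% keep, ]
    anova_res$hub_degree <- tryCatch(
      one_way_anova(sub$hub_degree, sub$functional_group), error = function(e) NULL)
    anova_res$functional_specialization <- tryCatch(
      one_way_anova(sub$fs, sub$functional_group), error = function(e) NULL)
  }

  # architecture -> function: SAR of per-capita juveniles on residualized
  # metrics, plus Table-2-style assemblage correlates
  performance_sar <- NULL
  table2 <- NULL
  if (length(pops) >= 4) {
    coords <- as.matrix(populations[match(pops, populations$population_id),
                                    c("x_km", "y_km")])
    W <- stage("spatial_weights", spatial_weights(coords, config$sar_scheme))
    geo <- as.matrix(dist(coords)); dimnames(geo) <- list(pops, pops)
    metr <- data.frame(
      nestedness = table1$nestedness,
      degree = table1$normalized_degree,
      connectance = table1$connectance,
      clustering = table1$clustering)
    resid_covar <- c(nestedness = NA, degree = "abundance",
                     connectance = "abundance", clustering = "s_obs")
    resids <- metr
    for (m in names(metr)) {
      cv <- resid_covar[[m]]
      if (!is.na(cv)) resids[[m]] <- residualize(metr[[m]], assem_sum[[cv]])
    }
    # Table-2-style grid: SAR slope of each metric on each assemblage
    # predictor, and partial Mantels against the dissimilarity matrices
    preds <- c("abundance", "s_obs", "hurlbert_pie")
    rows <- list()
    for (m in names(metr)) {
      row <- list(metric = m)
      for (p in preds) {
        fit <- tryCatch(suppressWarnings(
          fit_sar_mix(metr[[m]], matrix(assem_sum[[p]], ncol = 1,
                                        dimnames = list(NULL, p)), W)),
          error = function(e) NULL)
        row[[paste0(p, "_coef")]] <- if (is.null(fit)) NA else unname(fit$coefficients[p])
        row[[paste0(p, "_se")]] <- if (is.null(fit)) NA else unname(fit$se[p])
        row[[paste0(p, "_p")]] <- if (is.null(fit)) NA else unname(fit$p_value[p])
      }
      md <- metric_distance(metr[[m]], pops)
      for (dn in c("bray_curtis", "morisita_horn")) {
        mt <- tryCatch(partial_mantel(md, assem[[dn]], geo,
                                      seed = child_seed(config$seed, 2000 + match(m, names(metr))),
                                      perms = 1000),
                       error = function(e) NULL)
        row[[paste0(dn, "_r")]] <- if (is.null(mt)) NA else mt$statistic
        row[[paste0(dn, "_p")]] <- if (is.null(mt)) NA else mt$p_value
      }
      rows[[m]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    table2 <- do.call(rbind, rows); rownames(table2) <- NULL

    if ("juveniles" %in% names(plants)) {
      juv <- tapply(plants$juveniles, as.character(plants$population_id), mean)[pops]
      perf_rows <- list()
      for (m in names(resids)) {
        fit <- tryCatch(suppressWarnings(
          fit_sar_mix(log1p(juv), matrix(resids[[m]], ncol = 1,
                                         dimnames = list(NULL, m)), W)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          perf_rows[[m]] <- data.frame(
            metric = m, slope = unname(fit$coefficients[m]),
            se = unname(fit$se[m]), z = unname(fit$z[m]),
            p = unname(fit$p_value[m]), rho = fit$rho,
            stringsAsFactors = FALSE)
        }
      }
      performance_sar <- do.call(rbind, perf_rows); rownames(performance_sar) <- NULL
      note("performance SAR fitted on %d populations", length(pops))
    } else {
      note("no `juveniles` column in plant table: performance SAR skipped")
    }
  } else {
    note("fewer than 4 populations: spatial statistics skipped")
  }

  bundle <- list(networks = networks, table1 = table1, table2 = table2,
                 assemblage = assem, pollinator_types = pol_df,
                 anova = anova_res, performance_sar = performance_sar,
                 log = log, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    dg <- config_digest(config)
    write_table_with_header(table1, file.path(config$out_dir, "network_summary.csv"),
                            seed = config$seed, config_hash = dg)
    if (!is.null(table2))
      write_table_with_header(table2, file.path(config$out_dir, "assemblage_correlates.csv"),
                              seed = config$seed, config_hash = dg)
    if (!is.null(performance_sar))
      write_table_with_header(performance_sar,
                              file.path(config$out_dir, "performance_sar.csv"),
                              seed = config$seed, config_hash = dg)
    report <- list(
      config = dg,
      table1 = table1,
      table2 = table2,
      performance_sar = performance_sar,
      anova = anova_res,
      assemblage = assem_sum)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeLines(c(provenance_header(config$seed, dg), log),
               file.path(config$out_dir, "log.txt"))
    for (pid in pops) {
      write_pajek(networks[[pid]]$plant_graph,
                  file.path(config$out_dir, sprintf("%s_plants.net", pid)))
    }
  }
  invisible(bundle)
}
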