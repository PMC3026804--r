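# Synthetic-data module: pollinator pools, visitation surveys, spatial
# layouts and the downstream multiplicative fitness chain. Defaults emulate
# the scale of the field study this package's analysis chain targets: eight
# populations of 90 marked plants (of which ~47-90 survive the census
# filter), visited by ~30-41 pollinator species from eight functional
# groups, surveyed in five-minute intervals.

FUNCTIONAL_GROUPS <- c("large_bee", "small_bee", "wasp", "beefly",
                       "hoverfly", "beetle", "butterfly", "other")
FORAGING_MODES <- c("indiscriminate", "distance_limited", "within_plant")

# Stylized field composition: bees and beeflies dominate, the rest are rarer.
default_group_weights <- function() {
  w <- c(large_bee = 0.22, small_bee = 0.22, wasp = 0.08, beefly = 0.14,
         hoverfly = 0.12, beetle = 0.10, butterfly = 0.06, other = 0.06)
  w / sum(w)
}

#' Simulate a pollinator species pool
#'
#' Draws a heavy-tailed (lognormal) relative-abundance distribution over
#' `n_species` pollinator species, assigns each species to one of the eight
#' functional groups, and gives each a foraging mode. Beeflies forage
#' indiscriminately over all plants, hoverflies are distance-limited, and
#' beetles concentrate on few plants (within-plant foragers); species of the
#' remaining groups draw their mode from `default_mode_mix`.
#'
#' @param n_species number of species (>= 1).
#' @param abundance_shape lognormal sdlog of the abundance distribution
#'   (default 1: strongly uneven, a few dominant species).
#' @param group_weights probability vector over the eight functional groups.
#' @param default_mode_mix named probabilities over the three foraging modes
#'   for groups without a fixed mode.
#' @param seed RNG seed.
#' @return data.frame of class `pollinator_pool` with columns `species_id`,
#'   `functional_group`, `relative_abundance`, `foraging_mode`.
#' @export
simulate_pool <- function(n_species, abundance_shape = 1,
                          group_weights = default_group_weights(),
                          default_mode_mix = c(indiscriminate = 0.25,
                                               distance_limited = 0.5,
                                               within_plant = 0.25),
                          seed = NULL) {
  stop_if_not(is_count(n_species) && n_species >= 1, "`n_species` must be >= 1")
  stop_if_not(abundance_shape > 0, "`abundance_shape` must be positive")
  stop_if_not(length(group_weights) == 8, "`group_weights` must have length 8")
  stop_if_not(all(group_weights >= 0) && sum(group_weights) > 0 && all(is.finite(group_weights)),
              "`group_weights` must be normalizable (nonnegative, positive sum)")
  if (is.null(names(group_weights))) names(group_weights) <- FUNCTIONAL_GROUPS
  stop_if_not(setequal(names(group_weights), FUNCTIONAL_GROUPS),
              "`group_weights` names must be the eight functional groups")
  stop_if_not(setequal(names(default_mode_mix), FORAGING_MODES) &&
                all(default_mode_mix >= 0) && sum(default_mode_mix) > 0,
              "`default_mode_mix` must be probabilities over the three foraging modes")
  with_seed(seed, {
    ab <- rlnorm(n_species, meanlog = 0, sdlog = abundance_shape)
    ab <- ab / sum(ab)
    grp <- sample(FUNCTIONAL_GROUPS, n_species, replace = TRUE,
                  prob = group_weights[FUNCTIONAL_GROUPS])
    mode <- ifelse(grp == "beefly", "indiscriminate",
            ifelse(grp == "hoverfly", "distance_limited",
            ifelse(grp == "beetle", "within_plant", NA)))
    free <- is.na(mode)
    if (any(free)) {
      mode[free] <- sample(FORAGING_MODES, sum(free), replace = TRUE,
                           prob = default_mode_mix[FORAGING_MODES])
    }
    structure(data.frame(
      species_id = sprintf("sp%03d", seq_len(n_species)),
      functional_group = grp,
      relative_abundance = ab,
      foraging_mode = mode,
      stringsAsFactors = FALSE
    ), class = c("pollinator_pool", "data.frame"))
  })
}

#' Simulate a plant population layout
#'
#' Plants are scattered uniformly over a square plot (metre scale), with
#' negative-binomial flower numbers (>= 1); the population itself sits at a
#' km-scale coordinate used for inter-population distances.
#'
#' @param population_id identifier string.
#' @param n_plants number of plants (>= 2).
#' @param extent side of the square plot in metres (default 30).
#' @param flowers_mu,flowers_size negative-binomial mean/size of flower
#'   counts (defaults 30 and 2: overdispersed tens of flowers).
#' @param population_coord numeric length-2 km-scale coordinate.
#' @param seed RNG seed.
#' @return list of class `simulated_population`: `population_id`,
#'   `plant_ids`, `plant_coords` (n x 2, metres), `flowers_per_plant`,
#'   `population_coord`.
#' @export
simulate_population <- function(population_id, n_plants, extent = 30,
                                flowers_mu = 30, flowers_size = 2,
                                population_coord = c(0, 0), seed = NULL) {
  stop_if_not(is_count(n_plants) && n_plants >= 2, "need >= 2 plants")
  stop_if_not(extent > 0, "`extent` must be positive")
  with_seed(seed, {
    coords <- cbind(x = runif(n_plants, 0, extent), y = runif(n_plants, 0, extent))
    flowers <- 1L + rnbinom(n_plants, mu = flowers_mu - 1, size = flowers_size)
    ids <- sprintf("%s_p%03d", population_id, seq_len(n_plants))
    rownames(coords) <- ids
    structure(list(population_id = population_id, plant_ids = ids,
                   plant_coords = coords,
                   flowers_per_plant = as.integer(flowers),
                   population_coord = as.numeric(population_coord)),
              class = "simulated_population")
  })
}

# Per-survey plant-choice weights for one species, normalized to mean 1 so
# the expected per-plant visit rate is comparable across modes.
forage_weights <- function(mode, coords, flowers, d, distance_range, within_plant_k) {
  n <- length(flowers)
  w <- switch(mode,
    indiscriminate = flowers,
    distance_limited = {
      anchor <- sample.int(n, 1, prob = flowers)
      flowers * exp(-d[anchor, ] / distance_range)
    },
    within_plant = {
      sub <- sample.int(n, min(within_plant_k, n), prob = flowers)
      w0 <- numeric(n); w0[sub] <- flowers[sub]
      w0
    })
  w * n / sum(w)
}

#' Simulate pollinator visitation surveys
#'
#' For each survey and plant, every pollinator species produces visits as a
#' Poisson count whose rate is `visit_rate x relative_abundance x
#' minutes_per_plant x w`, where the plant-choice weight `w` depends on the
#' species' foraging mode: indiscriminate species spread over all plants in
#' proportion to flower display; distance-limited species concentrate around
#' a per-survey anchor plant with an exponential distance kernel; within-
#' plant foragers restrict each survey to a small random plant subset. Plant
#' x survey combinations with no visit are recorded as zero-visit placeholder
#' rows so observation effort is fully book-kept (total minutes = surveys x
#' plants x minutes_per_plant).
#'
#' @param pool a [simulate_pool()] result.
#' @param pop a [simulate_population()] result.
#' @param surveys number of survey rounds (>= 1; default 6, field practice
#'   5-7).
#' @param minutes_per_plant observation minutes per plant per survey
#'   (default 5, the census interval).
#' @param visit_rate expected visits per plant-minute summed over the whole
#'   pool (default 0.16, calibrated for a mean per-plant richness near 4
#'   under the default survey design).
#' @param distance_range exponential kernel range in metres for
#'   distance-limited foragers (default 5).
#' @param within_plant_k plants per survey available to within-plant
#'   foragers (default 2).
#' @param seed RNG seed.
#' @return a [visitation_table()].
#' @export
simulate_visitation <- function(pool, pop, surveys = 6, minutes_per_plant = 5,
                                visit_rate = 0.16, distance_range = 5,
                                within_plant_k = 2, seed = NULL) {
  stop_if_not(inherits(pool, "pollinator_pool") && nrow(pool) >= 1,
              "`pool` must be a non-empty pollinator_pool")
  stop_if_not(inherits(pop, "simulated_population") && length(pop$plant_ids) >= 1,
              "`pop` must be a non-empty simulated_population")
  stop_if_not(is_count(surveys) && surveys >= 1, "`surveys` must be >= 1")
  stop_if_not(minutes_per_plant > 0, "`minutes_per_plant` must be positive")
  n <- length(pop$plant_ids)
  d <- as.matrix(dist(pop$plant_coords))
  flowers <- pop$flowers_per_plant
  with_seed(seed, {
    recs <- vector("list", surveys * nrow(pool))
    ri <- 0L
    for (s in seq_len(surveys)) {
      for (k in seq_len(nrow(pool))) {
        w <- forage_weights(pool$foraging_mode[k], pop$plant_coords, flowers,
                            d, distance_range, within_plant_k)
        lambda <- visit_rate * pool$relative_abundance[k] * minutes_per_plant * w
        v <- rpois(n, lambda)
        hit <- which(v > 0)
        ri <- ri + 1L
        if (length(hit)) {
          recs[[ri]] <- data.frame(
            population_id = pop$population_id, survey = s,
            plant_id = pop$plant_ids[hit],
            pollinator_species = pool$species_id[k],
            functional_group = pool$functional_group[k],
            visits = v[hit], minutes_observed = minutes_per_plant,
            open_flowers = flowers[hit], stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, recs[seq_len(ri)][!vapply(recs[seq_len(ri)], is.null, logical(1))])
    # effort placeholders for plant x survey pairs that drew no visit at all
    seen <- if (is.null(out)) character(0) else paste(out$plant_id, out$survey, sep = "\r")
    all_pairs <- expand.grid(plant_id = pop$plant_ids, survey = seq_len(surveys),
                             stringsAsFactors = FALSE)
    miss <- all_pairs[!(paste(all_pairs$plant_id, all_pairs$survey, sep = "\r") %in% seen), ]
    if (nrow(miss)) {
      ph <- data.frame(population_id = pop$population_id, survey = miss$survey,
                       plant_id = miss$plant_id, pollinator_species = NA_character_,
                       functional_group = NA_character_, visits = 0L,
                       minutes_observed = minutes_per_plant,
                       open_flowers = flowers[match(miss$plant_id, pop$plant_ids)],
                       stringsAsFactors = FALSE)
      out <- if (is.null(out)) ph else rbind(out, ph)
    }
    out <- out[order(out$survey, out$plant_id, out$pollinator_species,
                     method = "radix", na.last = TRUE), ]
    rownames(out) <- NULL
    visitation_table(out)
  })
}

#' Fitness-chain parameters
#'
#' @param so_ratio_mean mean proportion of ovules setting seed (default 0.6).
#' @param fruits_per_plant_mean expected ripe fruits per plant at the
#'   baseline connectivity (default 15).
#' @param germination_prob per-seed germination probability (default 0.5).
#' @param survival_prob seedling-to-adult survival probability (default 0.4).
#' @param architecture_effect log-scale effect of latent connectivity on
#'   expected fruit production (default 0; see [simulate_study()] for the
#'   coupled default).
#' @param noise_sd sd of log-scale environmental noise (> 0; default 0.3).
#' @param spatial_autocorr_range exponential covariance range (same units as
#'   the coordinates; default 10).
#' @param ovules_per_fruit ovules per fruit (default 25).
#' @param seeds_planted seeds planted per maternal plant in the emergence
#'   trial (default 10, the protocol value).
#' @return validated list of class `fitness_chain_params`.
#' @export
fitness_chain_params <- function(so_ratio_mean = 0.6, fruits_per_plant_mean = 15,
                                 germination_prob = 0.5, survival_prob = 0.4,
                                 architecture_effect = 0, noise_sd = 0.3,
                                 spatial_autocorr_range = 10,
                                 ovules_per_fruit = 25, seeds_planted = 10) {
  stop_if_not(is_prob(so_ratio_mean) && is_prob(germination_prob) && is_prob(survival_prob),
              "probabilities must lie in [0, 1]")
  stop_if_not(fruits_per_plant_mean > 0, "`fruits_per_plant_mean` must be positive")
  stop_if_not(noise_sd > 0, "`noise_sd` must be positive")
  stop_if_not(spatial_autocorr_range > 0, "`spatial_autocorr_range` must be positive")
  stop_if_not(is_count(seeds_planted) && seeds_planted >= 1, "`seeds_planted` must be >= 1")
  structure(list(so_ratio_mean = so_ratio_mean,
                 fruits_per_plant_mean = fruits_per_plant_mean,
                 germination_prob = germination_prob, survival_prob = survival_prob,
                 architecture_effect = architecture_effect, noise_sd = noise_sd,
                 spatial_autocorr_range = spatial_autocorr_range,
                 ovules_per_fruit = ovules_per_fruit, seeds_planted = seeds_planted),
            class = "fitness_chain_params")
}

# Spatially autocorrelated Gaussian noise with exponential covariance.
correlated_noise <- function(coords, sd, range) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  S <- sd^2 * exp(-d / range)
  L <- chol(S + diag(1e-10, n))
  as.numeric(crossprod(L, rnorm(n)))
}

#' Simulate the downstream fitness chain
#'
#' Per plant: seeds per fruit are binomial over ovules with the SO ratio;
#' fruit number is Poisson with a log-scale mean shifted by
#' `architecture_effect x latent_connectivity` plus (spatially
#' autocorrelated, if coordinates are supplied) environmental noise; lifetime
#' seeds = fruits x seeds/fruit; emergence and survival rates come from
#' binomial trials on the planted-seed experiment (10 seeds per maternal
#' plant); juveniles = seeds x survivors / planted.
#'
#' @param latent_connectivity numeric vector, one latent connectivity score
#'   per plant (e.g. normalized degree in the realized network).
#' @param params a [fitness_chain_params()].
#' @param coords optional n x 2 coordinates for autocorrelated noise.
#' @param log_offset extra additive term on the log fruit scale (scalar or
#'   per-plant vector), used for population-level fertility fields.
#' @param seed RNG seed.
#' @return data.frame with columns `latent_connectivity`, `so_ratio`,
#'   `seeds_per_fruit`, `fruits`, `seeds`, `germinants`, `survivors`,
#'   `juveniles`.
#' @export
simulate_performance <- function(latent_connectivity, params = fitness_chain_params(),
                                 coords = NULL, log_offset = 0, seed = NULL) {
  stop_if_not(inherits(params, "fitness_chain_params"), "invalid `params`")
  stop_if_not(is.numeric(latent_connectivity) && !anyNA(latent_connectivity) &&
                all(is.finite(latent_connectivity)),
              "`latent_connectivity` must be finite and free of NaN")
  n <- length(latent_connectivity)
  with_seed(seed, {
    noise <- if (is.null(coords)) rnorm(n, 0, params$noise_sd) else
      correlated_noise(coords, params$noise_sd, params$spatial_autocorr_range)
    seeds_per_fruit <- rbinom(n, params$ovules_per_fruit, params$so_ratio_mean)
    log_mu <- log(params$fruits_per_plant_mean) +
      params$architecture_effect * latent_connectivity + noise + log_offset
    fruits <- rpois(n, exp(log_mu))
    seeds <- fruits * seeds_per_fruit
    germinants <- rbinom(n, params$seeds_planted, params$germination_prob)
    survivors <- rbinom(n, germinants, params$survival_prob)
    data.frame(latent_connectivity = latent_connectivity,
               so_ratio = seeds_per_fruit / params$ovules_per_fruit,
               seeds_per_fruit = seeds_per_fruit, fruits = fruits, seeds = seeds,
               germinants = germinants, survivors = survivors,
               juveniles = seeds * survivors / params$seeds_planted)
  })
}

#' Simulate a complete multi-population study
#'
#' End-to-end synthetic fixture: for each population, a pollinator pool, a
#' spatial plant layout, visitation surveys, and the downstream fitness chain
#' coupled to the realized network. The latent connectivity score of a plant
#' is its normalized degree in the plant projection of the (filtered)
#' visitation network, so `architecture_effect > 0` makes well-connected
#' plants produce more fruit. Assemblage richness, evenness and visitation
#' rate vary across populations so that network metrics vary too. A
#' population-level spatially autocorrelated fertility field (over the
#' km-scale coordinates) is added on top of plant-level noise, so
#' population means are themselves spatially structured.
#'
#' @param n_pops number of populations (default 8; >= 3 required by the
#'   downstream spatial models, a warning is issued below that).
#' @param n_plants plants marked per population (scalar or vector; default 90).
#' @param species_range inclusive range the per-population pool richness is
#'   drawn from (default `c(31, 41)`).
#' @param surveys,minutes_per_plant,visit_rate passed to
#'   [simulate_visitation()]; `visit_rate` is additionally scaled per
#'   population by a lognormal factor (sdlog `rate_sdlog`).
#' @param rate_sdlog between-population spread of visitation rate (default 0.25).
#' @param params a [fitness_chain_params()]; its `architecture_effect`
#'   (default 2 here) is the log-scale effect of normalized degree on fruit
#'   production and its `noise_sd` applies at the plant level.
#' @param pop_noise_sd sd of the population-level autocorrelated fertility
#'   field (default 0.15).
#' @param extent_km side of the square (km) the populations are scattered in
#'   (default 50).
#' @param min_minutes census filter threshold (default 15).
#' @param seed RNG seed; the study is byte-identical given the seed.
#' @return list of class `pollination_study`: `visits` (one
#'   [visitation_table()] over all populations), `plants` (data.frame with
#'   coordinates, flowers, latent connectivity and fitness components),
#'   `populations` (data.frame with km coordinates and pool sizes), `pools`
#'   (list of pollinator pools), `params`, `seed`.
#' @export
simulate_study <- function(n_pops = 8, n_plants = 90, species_range = c(31, 41),
                           surveys = 6, minutes_per_plant = 5, visit_rate = 0.16,
                           rate_sdlog = 0.25,
                           params = fitness_chain_params(architecture_effect = 2),
                           pop_noise_sd = 0.15, extent_km = 50,
                           min_minutes = 15, seed = NULL) {
  stop_if_not(is_count(n_pops) && n_pops >= 1, "`n_pops` must be >= 1")
  if (n_pops < 3) warning("n_pops < 3: downstream spatial models will not be fittable")
  n_plants <- rep(n_plants, length.out = n_pops)
  stop_if_not(all(n_plants >= 2), "each population needs >= 2 plants")
  stop_if_not(length(species_range) == 2 && species_range[1] <= species_range[2],
              "`species_range` must be an inclusive range")
  with_seed(seed, {
    pop_ids <- sprintf("pop%02d", seq_len(n_pops))
    pop_coords <- cbind(x_km = runif(n_pops, 0, extent_km),
                        y_km = runif(n_pops, 0, extent_km))
    rownames(pop_coords) <- pop_ids
    pop_field <- correlated_noise(pop_coords, pop_noise_sd, extent_km / 3)
    richness <- sample(seq(species_range[1], species_range[2]), n_pops, replace = TRUE)
    # richer pools also get flatter abundance distributions
    shapes <- runif(n_pops, 0.7, 1.2)
    rates <- visit_rate * rlnorm(n_pops, 0, rate_sdlog)

    pools <- vector("list", n_pops); names(pools) <- pop_ids
    all_visits <- vector("list", n_pops)
    all_plants <- vector("list", n_pops)
    for (i in seq_len(n_pops)) {
      pools[[i]] <- simulate_pool(richness[i], abundance_shape = shapes[i])
      pop <- simulate_population(pop_ids[i], n_plants[i],
                                 population_coord = pop_coords[i, ])
      vis <- simulate_visitation(pools[[i]], pop, surveys = surveys,
                                 minutes_per_plant = minutes_per_plant,
                                 visit_rate = rates[i])
      all_visits[[i]] <- vis
      # latent connectivity: normalized degree in the filtered projection
      latent <- setNames(numeric(n_plants[i]), pop$plant_ids)
      filt <- tryCatch(suppressMessages(filter_plants(vis, min_minutes)),
                       error = function(e) NULL)
      if (!is.null(filt)) {
        g <- project_plants(build_incidence(filt))
        latent[g$nodes] <- rowSums(g$adjacency) / (g$n - 1)
      }
      perf <- simulate_performance(latent, params, coords = pop$plant_coords,
                                   log_offset = pop_field[i])
      all_plants[[i]] <- data.frame(
        population_id = pop_ids[i], plant_id = pop$plant_ids,
        x = pop$plant_coords[, 1], y = pop$plant_coords[, 2],
        flowers = pop$flowers_per_plant, perf,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    visits <- visitation_table(do.call(rbind, all_visits))
    populations <- data.frame(population_id = pop_ids, pop_coords,
                              n_plants = n_plants, pool_richness = richness,
                              visit_rate = rates, row.names = NULL,
                              stringsAsFactors = FALSE)
    structure(list(visits = visits, plants = do.call(rbind, all_plants),
                   populations = populations, pools = pools, params = params,
                   seed = seed),
              class = "pollination_study")
  })
}

#' @export
print.pollination_study <- function(x, ...) {
  cat(sprintf("<pollination_study> %d populations, %d plants, %d visit records\n",
              nrow(x$populations), nrow(x$plants), sum(x$visits$visits > 0)))
  invisible(x)
}
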