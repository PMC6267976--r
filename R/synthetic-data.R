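#' Configuration for a synthetic trait-filtered landscape
#'
#' Describes a simulated field survey: quadrats spread over crossed soil-pH
#' and pine-basal-area gradients, a regional species pool with lognormal
#' seed mass and SRL and normal flowering dates, and Gaussian
#' environmental-filtering kernels whose optima shift linearly along the
#' gradients. The kernel operates on a per-trait working scale (log for
#' seed mass and SRL, raw days for flowering date) so that multiplicative
#' traits filter multiplicatively.
#'
#' The gradient directions of the optima follow the field pattern the model
#' is meant to emulate: community seed mass declines with pH and rises with
#' basal area, while SRL and flowering date rise with pH and decline with
#' basal area (sunny, high-pH sites select fast-foraging, late-flowering
#' species; shaded sites select the converse).
#'
#' @param n_species species-pool size (default 79).
#' @param n_quadrats number of quadrats (default 96).
#' @param ph_range,ba_range gradient ranges (defaults pH 5.5-7.5,
#'   basal area 0-59 m^2 ha^-1).
#' @param filter_strength kernel width as a multiple of the species pool's
#'   trait standard deviation on the working scale; smaller = stronger
#'   filtering (default 0.6, strong filtering).
#' @param optimum_amplitude how far the kernel optimum sweeps across the
#'   gradients, in working-scale trait SD units (default 1).
#' @param concentration Dirichlet concentration of realized cover around the
#'   kernel expectation; larger = less sampling noise. The default (22)
#'   puts quadrat-level CWM noise near one tenth of the CWM signal range.
#' @param seed integer seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_species = 79, n_quadrats = 96,
                             ph_range = c(5.5, 7.5), ba_range = c(0, 59),
                             filter_strength = 0.6, optimum_amplitude = 1,
                             concentration = 22, seed = 1) {
  if (n_species < 5) stop("need at least 5 species", call. = FALSE)
  if (n_quadrats < 1) stop("need at least 1 quadrat", call. = FALSE)
  if (diff(ph_range) <= 0 || diff(ba_range) <= 0) {
    stop("gradient ranges must be ordered (low, high)", call. = FALSE)
  }
  if (filter_strength <= 0) stop("filter_strength must be > 0", call. = FALSE)
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  structure(list(
    n_species = n_species, n_quadrats = n_quadrats,
    ph_range = ph_range, ba_range = ba_range,
    trait_means = c(seed_mass = log(0.8), srl = log(100), flowering_date = 185),
    trait_sds = c(seed_mass = 1.0, srl = 0.5, flowering_date = 25),
    # gradient direction of each trait optimum: (pH slope, BA slope)
    optimum_signs = rbind(
      seed_mass = c(ph = -0.5, ba = 0.5),
      srl = c(ph = 0.5, ba = -0.5),
      flowering_date = c(ph = 0.5, ba = -0.5)
    ),
    optimum_amplitude = optimum_amplitude,
    filter_strength = filter_strength,
    concentration = concentration,
    seed = seed
  ), class = "landscape_config")
}

# trait table -> working-scale matrix (log for the multiplicative traits)
working_traits <- function(traits) {
  tm <- trait_matrix(traits)
  cbind(seed_mass = log(tm[, "seed_mass"]),
        srl = log(tm[, "srl"]),
        flowering_date = tm[, "flowering_date"])
}

# kernel optimum per trait at given environments, on the working scale
kernel_optima <- function(cfg, ph, ba, pool_stats) {
  u_ph <- 2 * (ph - mean(cfg$ph_range)) / diff(cfg$ph_range)
  u_ba <- 2 * (ba - mean(cfg$ba_range)) / diff(cfg$ba_range)
  out <- sapply(rownames(cfg$optimum_signs), function(tr) {
    pool_stats$mean[tr] + cfg$optimum_amplitude * pool_stats$sd[tr] *
      (cfg$optimum_signs[tr, "ph"] * u_ph + cfg$optimum_signs[tr, "ba"] * u_ba)
  })
  matrix(out, nrow = length(ph), dimnames = list(NULL, rownames(cfg$optimum_signs)))
}

# expected relative abundances: Gaussian fitness kernel per trait, multiplied
# across traits and normalized within each environment
kernel_expected <- function(cfg, tw, optima, pool_stats) {
  sigmas <- cfg$filter_strength * pool_stats$sd
  E <- matrix(0, nrow(optima), nrow(tw))
  for (q in seq_len(nrow(optima))) {
    logw <- rep(0, nrow(tw))
    for (tr in colnames(tw)) {
      logw <- logw - (tw[, tr] - optima[q, tr])^2 / (2 * sigmas[tr]^2)
    }
    w <- exp(logw - max(logw))
    E[q, ] <- w / sum(w)
  }
  colnames(E) <- rownames(tw)
  E
}

#' Generate a synthetic trait-filtered landscape
#'
#' Draws a species pool, scatters quadrats uniformly over the pH and basal
#' area gradients, computes each species' expected relative cover at each
#' quadrat from the Gaussian filtering kernel, and realizes percent cover
#' with Dirichlet sampling noise. The returned truth record carries the
#' generating expectations, so downstream fits can be scored against the
#' known surfaces.
#'
#' @param cfg a [landscape_config()].
#' @return list with `traits` (a `trait_table`), `community` (cover
#'   `community_matrix`), `env` (an `environment_table`) and `truth`
#'   (kernel optima, expected relative abundances, expected CWM per
#'   quadrat, pool working-scale statistics). If `n_quadrats` < 20 the
#'   result carries a `too_small_for_fitting` flag.
#' @export
generate_landscape <- function(cfg = landscape_config()) {
  stopifnot(inherits(cfg, "landscape_config"))
  old_seed_state <- set_local_seed(cfg$seed)
  on.exit(restore_seed_state(old_seed_state), add = TRUE)
  S <- cfg$n_species; Q <- cfg$n_quadrats
  traits <- trait_table(data.frame(
    species_id = sprintf("sp%02d", seq_len(S)),
    seed_mass = stats::rlnorm(S, cfg$trait_means["seed_mass"],
                              cfg$trait_sds["seed_mass"]),
    srl = stats::rlnorm(S, cfg$trait_means["srl"], cfg$trait_sds["srl"]),
    flowering_date = pmin(pmax(stats::rnorm(S, cfg$trait_means["flowering_date"],
                                            cfg$trait_sds["flowering_date"]),
                               60), 330)
  ))
  env <- environment_table(data.frame(
    sample_id = sprintf("q%03d", seq_len(Q)),
    soil_ph = stats::runif(Q, cfg$ph_range[1], cfg$ph_range[2]),
    pine_ba = stats::runif(Q, cfg$ba_range[1], cfg$ba_range[2])
  ))
  tw <- working_traits(traits)
  pool_stats <- list(mean = colMeans(tw), sd = apply(tw, 2, stats::sd))
  optima <- kernel_optima(cfg, env$soil_ph, env$pine_ba, pool_stats)
  E <- kernel_expected(cfg, tw, optima, pool_stats)
  # Dirichlet realization of relative cover, rescaled to percent
  cover <- t(apply(E, 1, function(e) {
    g <- stats::rgamma(S, shape = cfg$concentration * pmax(e, 1e-12))
    100 * g / sum(g)
  }))
  dimnames(cover) <- list(env$sample_id, traits$species_id)
  community <- community_matrix(cover, kind = "cover")
  tm <- trait_matrix(traits)
  expected_cwm <- E %*% tm
  truth <- list(
    config = cfg,
    optima = optima,
    expected_abundance = E,
    expected_cwm = data.frame(unit_id = env$sample_id, expected_cwm,
                              row.names = NULL),
    pool_stats = pool_stats
  )
  out <- list(traits = traits, community = community, env = env, truth = truth)
  if (Q < 20) attr(out, "too_small_for_fitting") <- TRUE
  out
}

#' Configuration for a synthetic factorial sowing experiment
#'
#' A 2x2 light-by-parent-material design emulated through its environmental
#' surrogates: sun vs. shade map to pine basal area 0 vs. 59 m^2 ha^-1, and
#' limestone vs. basalt soils to pH 6.8 vs. 5.9. Each pot is sown with a
#' fixed number of seeds per species; emergence of each species is an
#' independent binomial draw with probability proportional to the same
#' Gaussian filtering kernel that shaped the landscape, evaluated at the
#' treatment's environment (competition is deliberately not modeled:
#' post-emergence survival in such sowing experiments is near-total).
#'
#' @param species character vector of 5 species ids to sow, or `NULL` to
#'   use the five species with the highest expected landscape cover.
#' @param treatments data frame with columns `treatment`, `soil_ph`,
#'   `pine_ba` (default: the 2x2 sun/shade x limestone/basalt design).
#' @param pots_per_cell replicate pots per treatment (default 17, 17, 16, 16).
#' @param seeds_per_species seeds sown per species per pot (default 12).
#' @param emergence_max emergence probability of a species whose traits sit
#'   exactly at the kernel optimum (default 0.6).
#' @param seed integer seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(species = NULL,
                              treatments = data.frame(
                                treatment = c("sun-limestone", "sun-basalt",
                                              "shade-limestone", "shade-basalt"),
                                soil_ph = c(6.8, 5.9, 6.8, 5.9),
                                pine_ba = c(0, 0, 59, 59)
                              ),
                              pots_per_cell = c(17, 17, 16, 16),
                              seeds_per_species = 12,
                              emergence_max = 0.6,
                              seed = 2) {
  stopifnot(all(c("treatment", "soil_ph", "pine_ba") %in% names(treatments)))
  if (nrow(treatments) < 1) stop("need at least one treatment", call. = FALSE)
  pots_per_cell <- rep_len(pots_per_cell, nrow(treatments))
  if (any(pots_per_cell < 1)) stop("pots_per_cell must be >= 1", call. = FALSE)
  if (seeds_per_species < 1) stop("seeds_per_species must be >= 1", call. = FALSE)
  if (emergence_max <= 0 || emergence_max > 1) {
    stop("emergence_max must be in (0, 1]", call. = FALSE)
  }
  structure(list(species = species, treatments = treatments,
                 pots_per_cell = pots_per_cell,
                 seeds_per_species = seeds_per_species,
                 emergence_max = emergence_max, seed = seed),
            class = "experiment_config")
}

#' Generate a synthetic sowing experiment from a landscape
#'
#' Sows the chosen species subset into replicate pots per treatment and
#' draws per-species emergence counts from the landscape's filtering kernel
#' evaluated at each treatment's environment. Pots in which no seed of any
#' species emerges are retained but flagged (downstream analysis excludes
#' them, mirroring standard practice).
#'
#' @param landscape output of [generate_landscape()] (supplies the trait
#'   table, kernel configuration and pool statistics).
#' @param cfg an [experiment_config()].
#' @return list with `counts` (count `community_matrix`, pots x species,
#'   with treatment labels), `truth` (per-treatment emergence probabilities
#'   and expected relative abundances) and `species` (the sown subset).
#' @export
generate_experiment <- function(landscape, cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  traits <- landscape$traits
  lcfg <- landscape$truth$config
  pool_stats <- landscape$truth$pool_stats
  species <- cfg$species
  if (is.null(species)) {
    mean_cover <- colMeans(landscape$truth$expected_abundance)
    species <- names(sort(mean_cover, decreasing = TRUE))[1:5]
  }
  unknown <- setdiff(species, traits$species_id)
  if (length(unknown) > 0) {
    stop("species not in trait table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sub <- trait_table(as.data.frame(traits)[match(species, traits$species_id), ])
  tw <- working_traits(sub)
  tre <- cfg$treatments
  optima <- kernel_optima(lcfg, tre$soil_ph, tre$pine_ba, pool_stats)
  sigmas <- lcfg$filter_strength * pool_stats$sd
  # emergence probability: kernel fitness rescaled so the best-adapted
  # species in each treatment emerges at emergence_max
  emerg <- matrix(0, nrow(tre), length(species),
                  dimnames = list(tre$treatment, species))
  for (q in seq_len(nrow(tre))) {
    logw <- rep(0, length(species))
    for (tr in colnames(tw)) {
      logw <- logw - (tw[, tr] - optima[q, tr])^2 / (2 * sigmas[tr]^2)
    }
    emerg[q, ] <- cfg$emergence_max * exp(logw - max(logw))
  }
  expected_rel <- emerg / rowSums(emerg)
  old_seed_state <- set_local_seed(cfg$seed)
  on.exit(restore_seed_state(old_seed_state), add = TRUE)
  pots <- list(); labels <- character(0)
  for (q in seq_len(nrow(tre))) {
    for (r in seq_len(cfg$pots_per_cell[q])) {
      pots[[length(pots) + 1]] <-
        stats::rbinom(length(species), cfg$seeds_per_species, emerg[q, ])
      labels <- c(labels, tre$treatment[q])
    }
  }
  counts <- do.call(rbind, pots)
  dimnames(counts) <- list(
    sprintf("pot%03d", seq_len(nrow(counts))), species)
  counts <- community_matrix(counts, kind = "count", treatment = labels)
  list(
    counts = counts,
    truth = list(emergence_prob = emerg, expected_rel_abundance = expected_rel,
                 treatments = tre, config = cfg),
    species = species
  )
}
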