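#' Default seven-species pool
#'
#' The default species pool emulates a dominance experiment drawn from
#' Central European mesophilic grassland: four grasses (one of them, `Ae`, a
#' tall, highly productive dominant), one forb and two legumes. Monoculture
#' mean yields and trait means are realistic per-species values for such
#' communities (g m^-2; height cm; SLA mm^2 mg^-1; leaf N/P/K mg g^-1; AMF
#' colonization %).
#'
#' @return Tibble with `species_id`, `functional_group`, `mu_M` (expected
#'   monoculture yield), and one column per species-level trait mean.
#' @export
species_pool_default <- function() {
  tibble(
    species_id = c("Ae", "Ap", "Dg", "Pt", "Gp", "Tp", "Tr"),
    functional_group = c("grass", "grass", "grass", "grass",
                         "forb", "legume", "legume"),
    mu_M = c(276.4, 66.2, 40.8, 20.2, 73.5, 46.6, 2.1),
    plant_height = c(45.6, 29.0, 23.7, 12.5, 27.9, 15.2, 11.9),
    sla = c(24.4, 17.1, 23.3, 29.7, 18.2, 25.5, 19.9),
    leaf_n = c(23.7, 17.7, 22.0, 16.1, 26.3, 40.7, 41.3),
    leaf_p = c(3.6, 2.8, 3.3, 2.6, 4.2, 2.5, 2.6),
    leaf_k = c(25.5, 23.8, 26.3, 27.8, 14.2, 10.2, 8.7),
    amf_colonization = c(40.6, 30.7, 33.5, 11.0, 65.5, 77.6, 86.5)
  )
}

oy_trait_units <- c(plant_height = "cm", sla = "mm2 mg-1", leaf_n = "mg g-1",
                    leaf_p = "mg g-1", leaf_k = "mg g-1",
                    amf_colonization = "%")

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic experiment
#' generator. Defaults emulate a four-block dominance-experiment design with
#' richness levels 1/2/6/7 over the seven-species pool (the top level is the
#' full pool) and 85 plots in total (7 monocultures, 46 two-species, 24
#' six-species and 8 full-mixture plots).
#'
#' @param n_blocks Number of blocks (default 4).
#' @param richness_levels Sown richness levels (default `c(1, 2, 6, 7)`).
#' @param level_plots Named total plot count per richness level; levels
#'   without an entry get one plot per species subset.
#' @param pool Species pool as in [species_pool_default()].
#' @param dominant Species id of the dominant; default the grass with the
#'   highest monoculture yield.
#' @param ce_slope Complementarity gain per unit log2 richness (fractional
#'   proportional overyielding shared by all species; default 0.15).
#' @param se_dominance Extra relative yield of the dominant species in
#'   mixtures (fraction; default 0.25).
#' @param biomass_cv Coefficient of variation of the multiplicative
#'   lognormal biomass noise (default 0.15).
#' @param block_sd_biomass SD of the log-scale block intercept shared by all
#'   yields in a block (default 0.10).
#' @param extinction_prob Per-species probability of local extinction in
#'   plots with sown richness >= `extinction_min_richness` (default 0).
#' @param extinction_min_richness See `extinction_prob` (default 6).
#' @param trait_plasticity Named vector: per-trait slope vs. log2 richness
#'   (trait units per doubling of richness). Defaults encode taller growth in
#'   mixtures and declining leaf N, leaf P and AMF colonization.
#' @param trait_sd Named vector of residual SDs of species-level trait values.
#' @param trait_block_sd Additive Gaussian block-intercept SD shared by all
#'   species-level trait values of one trait within a block (default 0).
#' @param plot_level_vars Tibble parameterizing plot-level community root
#'   traits and soil variables: `variable`, `unit`, `intercept`, `slope`
#'   (per log2 richness), `dom_shift` (additive shift when the dominant is
#'   present), `block_sd`, `noise_sd`. Default directions follow long-term
#'   grassland observations: root length density increases and specific root
#'   length decreases with richness; soil organic C, total N and
#'   plant-available P and K increase while soil pH decreases.
#' @return A validated list of class `oy_sim_config`.
#' @export
sim_config <- function(n_blocks = 4,
                       richness_levels = c(1, 2, 6, 7),
                       level_plots = c("1" = 7, "2" = 46, "6" = 24, "7" = 8),
                       pool = species_pool_default(),
                       dominant = NULL,
                       ce_slope = 0.15,
                       se_dominance = 0.25,
                       biomass_cv = 0.15,
                       block_sd_biomass = 0.10,
                       extinction_prob = 0,
                       extinction_min_richness = 6,
                       trait_plasticity = c(plant_height = 1.5, sla = 0,
                                            leaf_n = -0.8, leaf_p = -0.1,
                                            leaf_k = 0, amf_colonization = -2),
                       trait_sd = c(plant_height = 5, sla = 2.5, leaf_n = 3,
                                    leaf_p = 0.4, leaf_k = 2.5,
                                    amf_colonization = 10),
                       trait_block_sd = 0,
                       plot_level_vars = NULL) {
  pool <- check_schema(pool, "pool", c("species_id", "functional_group", "mu_M"))
  if (anyDuplicated(pool$species_id)) {
    abort("Duplicated species_id in pool.", class = "oy_validation_error")
  }
  if (any(pool$mu_M <= 0)) {
    abort("Monoculture mean yields must be positive.", class = "oy_validation_error")
  }
  if (is.null(dominant)) {
    grasses <- filter(pool, .data$functional_group == "grass")
    dominant <- if (nrow(grasses)) grasses$species_id[which.max(grasses$mu_M)]
                else pool$species_id[which.max(pool$mu_M)]
  }
  if (se_dominance != 0 && !dominant %in% pool$species_id) {
    abort("A dominant species must exist in the pool when se_dominance != 0.",
          class = "oy_validation_error")
  }
  if (is.null(plot_level_vars)) {
    plot_level_vars <- tibble(
      variable  = c("rld", "srl", "soil_ph", "soil_organic_c", "soil_total_n",
                    "soil_p", "soil_k"),
      unit      = c("cm cm-3", "m g-1", "pH", "g kg-1", "g kg-1",
                    "mg kg-1", "mg kg-1"),
      intercept = c(25, 120, 7.3, 15, 1.5, 40, 140),
      slope     = c(3, -8, -0.06, 0.8, 0.07, 2, 5),
      dom_shift = c(2, 0, -0.06, 0.8, 0.07, 2, 5),
      block_sd  = c(2, 8, 0.05, 0.8, 0.08, 3, 8),
      noise_sd  = c(4, 15, 0.08, 1.2, 0.12, 5, 12)
    )
  } else {
    plot_level_vars <- check_schema(plot_level_vars, "plot_level_vars",
      c("variable", "intercept", "slope", "dom_shift", "block_sd", "noise_sd"))
    if (!"unit" %in% names(plot_level_vars)) plot_level_vars$unit <- NA_character_
  }
  stopifnot(n_blocks >= 1, all(richness_levels >= 1),
            richness_levels == as.integer(richness_levels))
  sds <- c(biomass_cv, block_sd_biomass, trait_sd, trait_block_sd,
           plot_level_vars$block_sd, plot_level_vars$noise_sd, extinction_prob)
  if (any(sds < 0)) {
    abort("All noise SDs and probabilities must be >= 0.",
          class = "oy_validation_error")
  }
  traits <- names(trait_plasticity)
  if (!all(traits %in% names(pool)) || !setequal(traits, names(trait_sd))) {
    abort("trait_plasticity/trait_sd names must match trait columns of the pool.",
          class = "oy_validation_error")
  }
  structure(list(
    n_blocks = as.integer(n_blocks),
    richness_levels = sort(as.integer(richness_levels)),
    level_plots = level_plots, pool = pool, dominant = dominant,
    ce_slope = ce_slope, se_dominance = se_dominance,
    biomass_cv = biomass_cv, block_sd_biomass = block_sd_biomass,
    extinction_prob = extinction_prob,
    extinction_min_richness = extinction_min_richness,
    trait_plasticity = trait_plasticity, trait_sd = trait_sd,
    trait_block_sd = trait_block_sd, plot_level_vars = plot_level_vars
  ), class = "oy_sim_config")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate the sown design
#'
#' Builds a blocked design: every species gets a monoculture; at each higher
#' richness level the species subsets of that size are enumerated (sampled
#' without replacement when there are more than 2000) and replicated
#' round-robin up to the level's target plot count; replicate plots of one
#' mixture identity are placed in different blocks, balancing block loads
#' within each richness level. Deterministic given the seed.
#'
#' @param config An [sim_config()].
#' @param seed Optional integer seed (only consumed when subsets must be
#'   sampled).
#' @return Design tibble (`plot_id`, `block`, `mixture_id`, `species_id`,
#'   `sown_proportion`, `sown_richness`) with the species pool attached as
#'   attribute `"species"`.
#' @export
generate_design <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "oy_sim_config"))
  pool <- config$pool$species_id
  n <- length(pool)
  if (any(config$richness_levels > n)) {
    abort(sprintf("Richness level %d infeasible with a %d-species pool.",
                  max(config$richness_levels), n), class = "oy_validation_error")
  }
  with_seed_if(seed, {
    mixtures <- purrr::map_dfr(config$richness_levels, function(s) {
      subsets <- if (choose(n, s) <= 2000) {
        combn(pool, s, simplify = FALSE)
      } else {
        purrr::map(seq_len(200), \(i) sort(sample(pool, s)))
        # note: duplicates possible only for astronomically large pools
      }
      subsets <- unique(purrr::map(subsets, sort))
      k <- length(subsets)
      target <- config$level_plots[[as.character(s)]] %||% k
      if (target < k) subsets <- subsets[seq_len(target)]
      k <- length(subsets)
      reps <- rep(floor(target / k), k) + (seq_len(k) <= target %% k)
      tibble(
        sown_richness = s,
        mixture_id = purrr::map_chr(subsets, paste, collapse = "+"),
        n_reps = reps
      )
    })

    plots <- mixtures |>
      tidyr::uncount(.data$n_reps, .id = "replicate") |>
      mutate(plot_id = sprintf("p%03d", dplyr::row_number()))

    # block assignment: replicates of one identity in distinct blocks,
    # balancing block loads within each richness level
    plots$block <- NA_integer_
    for (s in unique(plots$sown_richness)) {
      idx_level <- which(plots$sown_richness == s)
      load <- integer(config$n_blocks)
      for (mid in unique(plots$mixture_id[idx_level])) {
        idx <- idx_level[plots$mixture_id[idx_level] == mid]
        used <- integer(0)
        for (i in idx) {
          avail <- setdiff(seq_len(config$n_blocks), used)
          if (!length(avail)) {
            used <- integer(0) # more replicates than blocks: start a new round
            avail <- seq_len(config$n_blocks)
          }
          b <- avail[which.min(load[avail])]
          plots$block[i] <- b
          load[b] <- load[b] + 1L
          used <- c(used, b)
        }
      }
    }

    design <- plots |>
      mutate(species_id = strsplit(.data$mixture_id, "+", fixed = TRUE)) |>
      tidyr::unnest("species_id") |>
      mutate(block = sprintf("B%d", .data$block),
             sown_proportion = 1 / .data$sown_richness) |>
      select("plot_id", "block", "mixture_id", "species_id",
             "sown_proportion", "sown_richness")
    attr(design, "species") <- config$pool |>
      select("species_id", "functional_group") |>
      mutate(active = TRUE)
    design
  })
}

#' Generate species-level biomass with known ground truth
#'
#' Monoculture yields are lognormal around the species' expected monoculture
#' yield `mu_M` with CV `biomass_cv`. In mixtures the expected yield of
#' species i is
#' `p_i * mu_M_i * (1 + ce_slope * log2(S) + se_dominance * I[dominant])`,
#' multiplied by a shared lognormal block factor and mean-one lognormal plot
#' noise; optional Bernoulli extinction thins species at high richness. The
#' ground truth feeds the noise-free expected yields through the additive
#' partition against the true monoculture means.
#'
#' @inheritParams generate_design
#' @param design A design from [generate_design()].
#' @return List with `biomass` (tibble; zero-biomass species are omitted) and
#'   `truth` (list: `effects` per-plot true NE/CE/SE, `reference` true
#'   monoculture means).
#' @export
generate_biomass <- function(design, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "oy_sim_config"))
  pool <- select(config$pool, "species_id", "mu_M")
  sdlog <- sqrt(log(1 + config$biomass_cv^2))

  base <- design |>
    left_join(pool, by = "species_id") |>
    mutate(expected = ifelse(
      .data$sown_richness == 1L, .data$mu_M,
      .data$sown_proportion * .data$mu_M *
        (1 + config$ce_slope * log2(.data$sown_richness) +
           config$se_dominance * (.data$species_id == config$dominant))))

  truth_ref <- rename(pool, M = "mu_M")
  truth_ds <- oy_dataset(
    design,
    base |>
      transmute(.data$plot_id, .data$species_id, biomass_g_m2 = .data$expected),
    species = attr(design, "species") %||% NULL
  )
  truth_effects <- partition_effects(truth_ds, reference = truth_ref) |>
    as_tibble() |>
    select("plot_id", NE_true = "NE", CE_true = "CE", SE_true = "SE")

  biomass <- with_seed_if(seed, {
    blocks <- sort(unique(design$block))
    block_eff <- setNames(stats::rnorm(length(blocks), 0, config$block_sd_biomass),
                          blocks)
    base |>
      mutate(
        eps = stats::rlnorm(n(), meanlog = -sdlog^2 / 2, sdlog = sdlog),
        extinct = .data$sown_richness >= config$extinction_min_richness &
          stats::runif(n()) < config$extinction_prob,
        biomass_g_m2 = ifelse(.data$extinct, 0,
                              .data$expected * exp(block_eff[.data$block]) * .data$eps)
      ) |>
      filter(.data$biomass_g_m2 > 0) |>
      select("plot_id", "species_id", "biomass_g_m2")
  })
  attr(biomass, "species") <- NULL # not inherited from the design table

  list(biomass = biomass,
       truth = list(effects = truth_effects, reference = truth_ref,
                    ce_slope = config$ce_slope,
                    se_dominance = config$se_dominance,
                    dominant = config$dominant))
}

#' Generate species-level traits and plot-level soil/root variables
#'
#' Species-level trait values are the species' pool mean plus a plasticity
#' shift proportional to log2 sown richness plus Gaussian noise (generated
#' only for species present at harvest). Plot-level variables (community root
#' traits and soil properties) are linear in log2 richness with an additive
#' shift when the dominant species is present, additive Gaussian block
#' intercepts, and Gaussian noise. AMF colonization is truncated to [0, 100]
#' and other species-level traits to positive values.
#'
#' @inheritParams generate_biomass
#' @param biomass Biomass tibble from [generate_biomass()].
#' @return Long trait tibble (`plot_id`, `species_id`, `variable`, `value`,
#'   `unit`).
#' @export
generate_traits_and_soil <- function(design, biomass, config = sim_config(),
                                     seed = NULL) {
  stopifnot(inherits(config, "oy_sim_config"))
  traits <- names(config$trait_plasticity)
  with_seed_if(seed, {
    present <- design |>
      inner_join(select(biomass, "plot_id", "species_id"),
                 by = c("plot_id", "species_id"))
    pool_means <- config$pool |>
      select("species_id", dplyr::all_of(traits)) |>
      tidyr::pivot_longer(-"species_id", names_to = "variable",
                          values_to = "pool_mean")
    blocks <- sort(unique(design$block))
    trait_block <- tidyr::expand_grid(variable = traits, block = blocks) |>
      mutate(block_eff = stats::rnorm(n(), 0, config$trait_block_sd))
    sp_tab <- present |>
      tidyr::expand_grid(variable = traits) |>
      left_join(pool_means, by = c("species_id", "variable")) |>
      left_join(trait_block, by = c("variable", "block")) |>
      mutate(
        value = .data$pool_mean +
          unname(config$trait_plasticity[.data$variable]) *
            log2(.data$sown_richness) +
          .data$block_eff +
          stats::rnorm(n(), 0, config$trait_sd[.data$variable]),
        value = ifelse(.data$variable == "amf_colonization",
                       pmin(pmax(.data$value, 0), 100),
                       pmax(.data$value, 0.1)),
        unit = unname(oy_trait_units[.data$variable])
      ) |>
      select("plot_id", "species_id", "variable", "value", "unit")

    dom_present <- present |>
      summarise(dom = any(.data$species_id == config$dominant), .by = "plot_id")
    plot_info <- design |>
      distinct(.data$plot_id, .data$block, .data$sown_richness) |>
      left_join(dom_present, by = "plot_id") |>
      mutate(dom = tidyr::replace_na(.data$dom, FALSE))
    pv <- config$plot_level_vars
    pv_block <- tidyr::expand_grid(variable = pv$variable, block = blocks) |>
      left_join(select(pv, "variable", "block_sd"), by = "variable") |>
      mutate(block_eff = stats::rnorm(n(), 0, .data$block_sd))
    plot_tab <- plot_info |>
      tidyr::expand_grid(distinct(pv, .data$variable)) |>
      left_join(pv, by = "variable") |>
      left_join(select(pv_block, "variable", "block", "block_eff"),
                by = c("variable", "block")) |>
      mutate(
        value = .data$intercept + .data$slope * log2(.data$sown_richness) +
          .data$dom_shift * .data$dom + .data$block_eff +
          stats::rnorm(n(), 0, .data$noise_sd),
        species_id = NA_character_
      ) |>
      select("plot_id", "species_id", "variable", "value", "unit")

    bind_rows(sp_tab, plot_tab) |>
      arrange(.data$plot_id, .data$variable, .data$species_id)
  })
}

#' Simulate a full virtual experiment
#'
#' Runs [generate_design()], [generate_biomass()] and
#' [generate_traits_and_soil()] under one seed and assembles the result into
#' a validated dataset. Identical configuration and seed reproduce the output
#' bit for bit.
#'
#' @param config An [sim_config()].
#' @param seed Integer seed governing all randomness.
#' @return List with `dataset` (an [oy_dataset()]) and `truth` (ground-truth
#'   per-plot effects and generator parameters).
#' @examples
#' sim <- simulate_experiment(seed = 42)
#' sim$dataset
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL) {
  with_seed_if(seed, {
    design <- generate_design(config)
    bio <- generate_biomass(design, config)
    traits <- generate_traits_and_soil(design, bio$biomass, config)
    ds <- oy_dataset(design, bio$biomass, traits,
                     species = attr(design, "species"))
    list(dataset = ds, truth = bio$truth)
  })
}
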