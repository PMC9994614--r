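test_that("the default design honours the blocked dominance layout", {
  design <- generate_design(sim_config(), seed = 1)
  plots <- dplyr::distinct(design, plot_id, block, mixture_id, sown_richness)
  expect_equal(nrow(plots), 85)
  expect_equal(sum(plots$sown_richness == 1), 7)  # one monoculture per species
  expect_equal(table(plots$sown_richness)[c("2", "6", "7")],
               c("2" = 46L, "6" = 24L, "7" = 8L), ignore_attr = TRUE)

  # every unordered pair occurs as an identity, replicated at least twice
  pairs <- plots[plots$sown_richness == 2, ]
  expect_equal(dplyr::n_distinct(pairs$mixture_id), choose(7, 2))
  expect_true(all(table(pairs$mixture_id) >= 2))

  # replicates of one identity sit in different blocks (up to 4 replicates)
  reps <- plots |>
    dplyr::summarise(n = dplyr::n(), nb = dplyr::n_distinct(block),
                     .by = mixture_id)
  expect_true(all(reps$nb == pmin(reps$n, 4)))

  # equal sowing proportions and consistent richness bookkeeping
  expect_true(all(abs(design$sown_proportion * design$sown_richness - 1) < 1e-12))
  sums <- dplyr::summarise(design, s = sum(sown_proportion), .by = plot_id)
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("design generation is deterministic and rejects infeasible levels", {
  expect_identical(generate_design(sim_config(), seed = 5),
                   generate_design(sim_config(), seed = 5))
  cfg_bad <- sim_config(richness_levels = c(1, 2, 9),
                        level_plots = c("1" = 7, "2" = 42, "9" = 8))
  expect_error(generate_design(cfg_bad), class = "oy_validation_error",
               regexp = "infeasible")
})

test_that("a noise-free null generator produces exactly zero effects", {
  cfg <- sim_config(ce_slope = 0, se_dominance = 0, biomass_cv = 0,
                    block_sd_biomass = 0)
  design <- generate_design(cfg, seed = 2)
  bio <- generate_biomass(design, cfg, seed = 2)
  ds <- oy_dataset(design, bio$biomass, species = attr(design, "species"))
  pe <- partition_effects(ds) # empirical reference is exact here
  expect_true(all(abs(pe$NE) < 1e-9))
  expect_true(all(abs(pe$CE) < 1e-9))
  expect_true(all(abs(pe$SE) < 1e-9))
  expect_true(all(abs(bio$truth$effects$NE_true) < 1e-9))
})

test_that("pure complementarity gives SE = 0 and CE growing with richness", {
  cfg <- sim_config(ce_slope = 0.2, se_dominance = 0, biomass_cv = 0,
                    block_sd_biomass = 0)
  design <- generate_design(cfg, seed = 3)
  bio <- generate_biomass(design, cfg, seed = 3)
  ds <- oy_dataset(design, bio$biomass, species = attr(design, "species"))
  pe <- partition_effects(ds)
  mix <- pe[pe$is_mixture, ]
  expect_true(all(abs(mix$SE) < 1e-9))  # uniform proportional gain
  expect_true(all(mix$CE > 0))
  by_s <- dplyr::summarise(tibble::as_tibble(mix), ce = mean(CE),
                           .by = sown_richness)
  expect_true(all(diff(by_s$ce[order(by_s$sown_richness)]) > 0))
  # ground truth is the same noise-free partition
  chk <- dplyr::inner_join(tibble::as_tibble(pe), bio$truth$effects,
                           by = "plot_id")
  expect_equal(chk$CE, chk$CE_true, tolerance = 1e-9)
})

test_that("dominance advantage yields positive selection where the dominant grows", {
  cfg <- sim_config(ce_slope = 0, se_dominance = 0.3, biomass_cv = 0,
                    block_sd_biomass = 0)
  design <- generate_design(cfg, seed = 4)
  bio <- generate_biomass(design, cfg, seed = 4)
  ds <- oy_dataset(design, bio$biomass, species = attr(design, "species"))
  pe <- partition_effects(ds)
  dom_plots <- unique(design$plot_id[design$species_id == cfg$dominant &
                                       design$sown_richness > 1])
  dom <- pe[pe$plot_id %in% dom_plots, ]
  expect_true(all(dom$SE > 0))  # high-M species overperforms
  expect_true(all(dom$NE > 0))
  other <- pe[pe$is_mixture & !pe$plot_id %in% dom_plots, ]
  expect_true(all(abs(other$NE) < 1e-9))
  # decomposition agrees with the closed-form oracle on a dominant pair
  sp <- partition_species(pe)
  one <- sp[sp$plot_id == dom_plots[1], ]
  orc <- oracle_partition(one$Y, one$M, one$RY_exp)
  expect_equal(sum(one$SE_i), orc$SE, tolerance = 1e-9)
})

test_that("soil responses carry the configured richness slope", {
  cfg <- sim_config(trait_plasticity = c(plant_height = 0),
                    trait_sd = c(plant_height = 5))
  design <- generate_design(cfg, seed = 6)
  ph_row <- cfg$plot_level_vars[cfg$plot_level_vars$variable == "soil_ph", ]
  expect_lt(ph_row$slope, 0)
  neg <- withr::with_seed(60, replicate(200, {
    bio <- generate_biomass(design, cfg)
    tr <- generate_traits_and_soil(design, bio$biomass, cfg)
    d <- tr[tr$variable == "soil_ph", ]
    d <- dplyr::inner_join(d, dplyr::distinct(design, plot_id, sown_richness),
                           by = "plot_id")
    coef(lm(value ~ log2(sown_richness), data = d))[2] < 0
  }))
  expect_gte(mean(neg), 0.95)
})

test_that("the complementarity slope is recovered from replicate experiments", {
  # implied slope: CE = ce_slope * log2(S) * mean(M_sown) under the uniform
  # proportional-gain model, estimated here with the empirical monoculture
  # reference (which carries a small upward convexity bias, see vignette)
  cfg <- sim_config(se_dominance = 0, block_sd_biomass = 0) # cv 0.15, ce 0.15
  design <- generate_design(cfg, seed = 90)
  est <- withr::with_seed(91, replicate(100, {
    bio <- generate_biomass(design, cfg)
    ds <- oy_dataset(design, bio$biomass, species = attr(design, "species"))
    pe <- partition_effects(ds)
    msown <- dplyr::summarise(partition_species(pe), mM = mean(M),
                              .by = plot_id)
    d <- dplyr::inner_join(tibble::as_tibble(pe), msown, by = "plot_id") |>
      dplyr::filter(is_mixture)
    x <- log2(d$sown_richness) * d$mM
    sum(x * d$CE) / sum(x^2)
  }))
  expect_lt(abs(median(est) - cfg$ce_slope), 0.2 * cfg$ce_slope)
})

test_that("simulation is bit-reproducible and extinction thins realized richness", {
  s1 <- simulate_experiment(seed = 77)
  s2 <- simulate_experiment(seed = 77)
  expect_identical(s1$dataset$design, s2$dataset$design)
  expect_identical(s1$dataset$biomass, s2$dataset$biomass)
  expect_identical(s1$dataset$traits, s2$dataset$traits)

  cfg_ext <- sim_config(extinction_prob = 0.4, extinction_min_richness = 6)
  se <- simulate_experiment(cfg_ext, seed = 78)
  rr <- realized_richness(se$dataset)
  high <- dplyr::distinct(se$dataset$design, plot_id, sown_richness) |>
    dplyr::filter(sown_richness >= 6) |>
    dplyr::inner_join(rr, by = "plot_id")
  expect_true(any(high$realized_richness < high$sown_richness))
  expect_silent(validate_dataset(se$dataset))
})
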