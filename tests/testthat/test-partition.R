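test_that("monoculture reference averages a species' monoculture plots", {
  design <- tibble::tibble(
    plot_id = c("m1", "m2", "m3"), block = c("B1", "B2", "B1"),
    mixture_id = c("A", "A", "B"), species_id = c("A", "A", "B"),
    sown_proportion = 1
  )
  biomass <- tibble::tibble(plot_id = c("m1", "m2", "m3"),
                            species_id = c("A", "A", "B"),
                            biomass_g_m2 = c(180, 220, 150))
  ref <- monoculture_reference(oy_dataset(design, biomass))
  expect_equal(ref$M[ref$species_id == "A"], 200)       # mean of 180, 220
  expect_equal(ref$M[ref$species_id == "B"], 150)       # single monoculture
  expect_equal(ref$n_monocultures, c(2L, 1L))
})

test_that("an active species without a monoculture is a configuration error", {
  design <- tibble::tibble(
    plot_id = c("m1", "x1", "x1"), block = "B1",
    mixture_id = c("A", "AB", "AB"), species_id = c("A", "A", "B"),
    sown_proportion = c(1, 0.5, 0.5)
  )
  biomass <- tibble::tibble(plot_id = c("m1", "x1"), species_id = c("A", "B"),
                            biomass_g_m2 = c(100, 10))
  expect_error(monoculture_reference(oy_dataset(design, biomass)),
               class = "oy_configuration_error")
  # a monoculture harvested at zero biomass is equally unusable
  ds0 <- toy_dataset(y_mono_b = 0)
  expect_error(monoculture_reference(ds0), class = "oy_configuration_error")
})

test_that("worked two-species partitions match hand values and the oracle", {
  # pure selection: dRY = (0.25, -0.25) averages to zero
  ds <- toy_dataset(y_mix = c(150, 25))
  pe <- partition_effects(ds)
  x1 <- pe[pe$plot_id == "x1", ]
  expect_equal(c(x1$NE, x1$CE, x1$SE), c(25, 0, 25))
  orc <- oracle_partition(Y = c(150, 25), M = c(200, 100), p = c(0.5, 0.5))
  expect_equal(c(x1$NE, x1$CE, x1$SE), c(orc$NE, orc$CE, orc$SE))

  # pure complementarity: equal dRY forces SE = 0
  ds2 <- toy_dataset(y_mix = c(120, 60))
  x2 <- partition_effects(ds2)[3, ]
  expect_equal(c(x2$NE, x2$CE, x2$SE), c(30, 30, 0))
  orc2 <- oracle_partition(c(120, 60), c(200, 100), c(0.5, 0.5))
  expect_equal(c(x2$NE, x2$CE, x2$SE), c(orc2$NE, orc2$CE, orc2$SE))

  # per-species internals for the selection case
  sp <- partition_species(pe)
  sx <- sp[sp$plot_id == "x1", ]
  expect_equal(sx$RY_obs, c(0.75, 0.25))
  expect_equal(sx$dRY, c(0.25, -0.25))
  expect_equal(sx$SE_i, c(12.5, 12.5))
  expect_equal(sum(sx$CE_i), 0)
})

test_that("monoculture plots report zero biodiversity effects", {
  pe <- partition_effects(toy_dataset())
  mono <- pe[!pe$is_mixture, ]
  expect_equal(nrow(mono), 2)
  expect_true(all(mono$NE == 0 & mono$CE == 0 & mono$SE == 0))
})

test_that("partition identities hold on randomized plots", {
  rp <- random_partition_dataset(300, seed = 42)
  pe <- partition_effects(rp$dataset, reference = rp$reference)
  mix <- pe[pe$is_mixture, ]
  tol <- 1e-9 * pmax(1, abs(mix$NE))
  expect_true(all(abs(mix$NE - mix$CE - mix$SE) < tol))

  # NE equals the direct closed form Y_total - sum(p_i M_i), plot by plot
  per <- partition_species(pe)
  direct <- per |>
    dplyr::summarise(NE_direct = sum(Y) - sum(RY_exp * M), .by = plot_id)
  chk <- dplyr::inner_join(tibble::as_tibble(mix), direct, by = "plot_id")
  expect_true(all(abs(chk$NE - chk$NE_direct) < 1e-9 * pmax(1, abs(chk$NE))))

  # closed-form complementarity/selection oracle agrees per plot
  orc <- per |>
    dplyr::filter(S > 1) |>
    dplyr::group_by(plot_id) |>
    dplyr::summarise(
      CE_o = dplyr::n() * mean(dRY) * mean(M),
      SE_o = dplyr::n() * mean((dRY - mean(dRY)) * (M - mean(M))),
      .groups = "drop")
  chk2 <- dplyr::inner_join(tibble::as_tibble(mix), orc, by = "plot_id")
  expect_equal(chk2$CE, chk2$CE_o, tolerance = 1e-9)
  expect_equal(chk2$SE, chk2$SE_o, tolerance = 1e-9)
})

test_that("partition is equivariant under rescaling all biomasses", {
  rp <- random_partition_dataset(50, seed = 7)
  pe1 <- partition_effects(rp$dataset, reference = rp$reference)
  c_scale <- 3.7
  ds2 <- oy_dataset(
    rp$dataset$design,
    dplyr::mutate(rp$dataset$biomass, biomass_g_m2 = biomass_g_m2 * c_scale)
  )
  ref2 <- dplyr::mutate(rp$reference, M = M * c_scale)
  pe2 <- partition_effects(ds2, reference = ref2)
  expect_equal(pe2$NE, pe1$NE * c_scale, tolerance = 1e-10)
  expect_equal(pe2$CE, pe1$CE * c_scale, tolerance = 1e-10)
  expect_equal(pe2$SE, pe1$SE * c_scale, tolerance = 1e-10)
})

test_that("degenerate configurations behave as defined", {
  # equal monoculture yields force SE = 0 regardless of yields
  design <- tibble::tibble(
    plot_id = rep("x1", 2), block = "B1", mixture_id = "AB",
    species_id = c("A", "B"), sown_proportion = 0.5
  )
  biomass <- tibble::tibble(plot_id = "x1", species_id = c("A", "B"),
                            biomass_g_m2 = c(91, 17))
  ref <- tibble::tibble(species_id = c("A", "B"), M = c(120, 120))
  pe <- partition_effects(oy_dataset(design, biomass), reference = ref)
  expect_equal(pe$SE, 0)

  # every sown species absent at harvest: all-negative NE, not an error
  ds_dead <- oy_dataset(design,
                        tibble::tibble(plot_id = "x1",
                                       species_id = "A", biomass_g_m2 = 0))
  pe_dead <- partition_effects(ds_dead, reference = ref)
  expect_equal(pe_dead$NE, -120) # -(0.5*120 + 0.5*120)
})

test_that("signed_sqrt is the odd order-preserving square root", {
  expect_equal(signed_sqrt(c(0, -4, 25)), c(0, -2, 5))
  y <- withr::with_seed(1, stats::rnorm(200, sd = 30))
  expect_equal(signed_sqrt(-y), -signed_sqrt(y))          # odd
  expect_true(all(diff(signed_sqrt(sort(y))) >= 0))       # monotone
  expect_equal(signed_sqrt(y)^2 * sign(y), y)             # inverse
})

test_that("grand-mean effect test detects shifts and respects exact nulls", {
  # yields exactly at expectation: all effects zero, F = 0, p = 1
  design <- tibble::tibble(
    plot_id = rep(c("x1", "x2"), each = 2), block = "B1",
    mixture_id = rep(c("AB", "AB2"), each = 2),
    species_id = rep(c("A", "B"), 2), sown_proportion = 0.5
  )
  ref <- tibble::tibble(species_id = c("A", "B"), M = c(200, 100))
  bio0 <- tibble::tibble(plot_id = rep(c("x1", "x2"), each = 2),
                         species_id = rep(c("A", "B"), 2),
                         biomass_g_m2 = rep(c(100, 50), 2))
  pe0 <- partition_effects(oy_dataset(design, bio0), reference = ref)
  t0 <- tidy(test_effects_positive(pe0))
  expect_true(all(t0$statistic == 0))
  expect_true(all(t0$p.value == 1))

  # strong overyielding with small noise is detected decisively
  cfg <- sim_config(ce_slope = 0.3, se_dominance = 0, biomass_cv = 0.03,
                    block_sd_biomass = 0)
  sim <- withr::with_seed(3, {
    design <- generate_design(cfg)
    generate_biomass(design, cfg) |>
      (\(b) partition_effects(oy_dataset(design, b$biomass),
                              reference = b$truth$reference))()
  })
  tt <- tidy(test_effects_positive(sim, effects = "NE"))
  expect_lt(tt$p.value, 0.001)
  expect_gt(tt$estimate, 0)
})

test_that("a saturated error stratum is refused", {
  # a single mixture plot cannot support the test at all
  expect_error(test_effects_positive(partition_effects(toy_dataset())),
               class = "oy_validation_error")
  # two singleton mixture identities leave no residual degrees of freedom
  design <- tibble::tibble(
    plot_id = rep(c("x1", "x2"), each = 2), block = "B1",
    mixture_id = rep(c("AB", "AB2"), each = 2),
    species_id = rep(c("A", "B"), 2), sown_proportion = 0.5
  )
  bio <- tibble::tibble(plot_id = rep(c("x1", "x2"), each = 2),
                        species_id = rep(c("A", "B"), 2),
                        biomass_g_m2 = c(150, 60, 90, 40))
  ref <- tibble::tibble(species_id = c("A", "B"), M = c(200, 100))
  pe <- partition_effects(oy_dataset(design, bio), reference = ref)
  expect_error(test_effects_positive(pe, effects = "NE"),
               class = "oy_validation_error")
})
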