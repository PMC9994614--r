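# Small in-code fixtures and independent oracles shared across tests.

# Two-plot fixture: one monoculture of A, one A+B mixture sown 50:50.
toy_dataset <- function(y_mix = c(150, 25), y_mono_a = 200, y_mono_b = 100) {
  design <- tibble::tibble(
    plot_id = c("m1", "m2", "x1", "x1"),
    block = c("B1", "B2", "B1", "B1"),
    mixture_id = c("A", "B", "AB", "AB"),
    species_id = c("A", "B", "A", "B"),
    sown_proportion = c(1, 1, 0.5, 0.5)
  )
  biomass <- tibble::tibble(
    plot_id = c("m1", "m2", "x1", "x1"),
    species_id = c("A", "B", "A", "B"),
    biomass_g_m2 = c(y_mono_a, y_mono_b, y_mix)
  )
  oy_dataset(design, biomass)
}

# Independent brute-force evaluation of the additive partition for one plot,
# written from the closed forms rather than the per-species decomposition:
#   NE = Y_total - sum(p_i * M_i)
#   CE = S * mean(dRY) * mean(M)
#   SE = S * cov_pop(dRY, M)
oracle_partition <- function(Y, M, p) {
  S <- length(Y)
  dRY <- Y / M - p
  NE <- sum(Y) - sum(p * M)
  CE <- S * mean(dRY) * mean(M)
  SE <- S * mean((dRY - mean(dRY)) * (M - mean(M)))
  list(NE = NE, CE = CE, SE = SE)
}

# Independent sequential (Type-I) SS via explicit orthogonal projections:
# SS gained by the richness term once block is in the model.
oracle_richness_ss <- function(y, block, richness, mixture_id) {
  proj_ss <- function(X) {
    q <- qr(X)
    sum(qr.fitted(q, y)^2)
  }
  X1 <- stats::model.matrix(~block)
  X2 <- stats::model.matrix(~block + richness)
  proj_ss(X2) - proj_ss(X1)
}

# Random plot batch for partition property tests: `n_plots` plots over a
# pool of `n_pool` species, random richness, proportions and yields.
random_partition_dataset <- function(n_plots, n_pool = 10, seed = 1) {
  withr::with_seed(seed, {
    pool <- sprintf("s%02d", seq_len(n_pool))
    M <- stats::runif(n_pool, 10, 400)
    rows <- lapply(seq_len(n_plots), function(i) {
      S <- sample(1:8, 1)
      sp <- sample(pool, S)
      p <- stats::runif(S, 0.2, 1)
      p <- p / sum(p)
      y <- stats::runif(S, 0, 300) * (stats::runif(S) > 0.05) # some absences
      tibble::tibble(
        plot_id = sprintf("p%05d", i), block = "B1",
        mixture_id = sprintf("p%05d", i),
        species_id = sp, sown_proportion = p, biomass_g_m2 = y
      )
    })
    tab <- dplyr::bind_rows(rows)
    list(
      dataset = oy_dataset(
        design = tab[c("plot_id", "block", "mixture_id", "species_id",
                       "sown_proportion")],
        biomass = dplyr::filter(tab, biomass_g_m2 > 0)[
          c("plot_id", "species_id", "biomass_g_m2")]
      ),
      reference = tibble::tibble(species_id = pool, M = M),
      raw = tab
    )
  })
}

# Generator configuration with every effect switched off (noise only);
# plot-level table reduced to one soil variable for speed.
null_sim_config <- function(noise_cv = 0.15, soil_sd = 0.08, ...) {
  sim_config(
    ce_slope = 0, se_dominance = 0,
    biomass_cv = noise_cv, block_sd_biomass = 0,
    trait_plasticity = c(plant_height = 0), trait_sd = c(plant_height = 5),
    plot_level_vars = tibble::tibble(
      variable = "soil_ph", unit = "pH", intercept = 7.3,
      slope = 0, dom_shift = 0, block_sd = 0, noise_sd = soil_sd),
    ...
  )
}

# Attach one plot-level variable from the trait table to a plot frame.
join_plot_variable <- function(pf, ds, variable) {
  v <- ds$traits[ds$traits$variable == variable & is.na(ds$traits$species_id),
                 c("plot_id", "value")]
  names(v)[2] <- variable
  dplyr::left_join(pf, v, by = "plot_id")
}
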