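#' Monoculture reference yields
#'
#' Computes the monoculture yield M_i for every active species as the
#' arithmetic mean of its biomass across all monoculture plots (sown richness
#' 1), pooling over blocks. Monoculture plots with no biomass row for their
#' species contribute 0 to the mean.
#'
#' @param ds An `oy_dataset`.
#' @return Tibble `species_id`, `M` (g m^-2), `n_monocultures`.
#' @details Every active species must have at least one monoculture plot with
#'   positive mean yield; otherwise partitioning is undefined for plots
#'   containing it and an error of class `oy_configuration_error` asks the
#'   caller to flag the species inactive (the standard handling for species
#'   that went extinct pool-wide).
#' @export
monoculture_reference <- function(ds) {
  stopifnot(inherits(ds, "oy_dataset"))
  active <- ds$species$species_id[ds$species$active]
  mono <- ds$design |>
    filter(.data$sown_richness == 1L, .data$species_id %in% active) |>
    select("plot_id", "species_id") |>
    left_join(ds$biomass, by = c("plot_id", "species_id")) |>
    mutate(biomass_g_m2 = tidyr::replace_na(.data$biomass_g_m2, 0)) |>
    summarise(M = mean(.data$biomass_g_m2), n_monocultures = n(),
              .by = "species_id")
  missing <- setdiff(active, mono$species_id)
  if (length(missing)) {
    abort(sprintf(
      "Active species without a monoculture plot: %s. Flag them inactive to exclude them from partitioning.",
      paste(missing, collapse = ", ")), class = "oy_configuration_error")
  }
  zero <- mono$species_id[mono$M <= 0]
  if (length(zero)) {
    abort(sprintf(
      "Monoculture reference yield is zero for: %s. Flag them inactive to exclude them from partitioning.",
      paste(zero, collapse = ", ")), class = "oy_configuration_error")
  }
  arrange(mono, .data$species_id)
}

#' Additive partitioning of overyielding
#'
#' Partitions each plot's deviation from its expected yield into
#' complementarity and selection components (Loreau-Hector additive
#' partition). For species i with monoculture yield M_i, expected relative
#' yield RY_exp,i equal to its sown proportion, and observed relative yield
#' RY_obs,i = Y_i / M_i:
#' \deqn{\Delta RY_i = RY_{obs,i} - RY_{exp,i}}
#' \deqn{SE_i = (\Delta RY_i - \overline{\Delta RY})(M_i - \bar M)}
#' \deqn{CE_i = M_i \Delta RY_i - SE_i}
#' with unweighted means over the S sown species; plot totals are
#' SE = sum(SE_i), CE = sum(CE_i), NE = SE + CE. Species sown but absent at
#' harvest enter with Y_i = 0 (so dRY_i = -RY_exp,i); they are not dropped
#' from S. Monoculture plots carry no biodiversity effect and are reported
#' with NE = CE = SE = 0 and `is_mixture = FALSE`.
#'
#' @param ds An `oy_dataset`.
#' @param reference Monoculture reference, default [monoculture_reference()].
#'   Supplying a known reference table (`species_id`, `M`) is useful for
#'   calibration against ground truth.
#' @return A tibble of class `oy_partition`, one row per plot: `plot_id`,
#'   `block`, `mixture_id`, `sown_richness`, `S`, `NE`, `CE`, `SE` (g m^-2),
#'   `is_mixture`. The per-species internals are attached as the attribute
#'   `"species"` and returned by [partition_species()].
#' @examples
#' ds <- simulate_experiment(seed = 1)$dataset
#' pe <- partition_effects(ds)
#' head(pe)
#' @export
partition_effects <- function(ds, reference = monoculture_reference(ds)) {
  stopifnot(inherits(ds, "oy_dataset"))
  reference <- check_schema(reference, "reference", c("species_id", "M"))
  active <- ds$species$species_id[ds$species$active]

  tab <- ds$design |>
    filter(.data$species_id %in% active) |>
    left_join(ds$biomass, by = c("plot_id", "species_id")) |>
    mutate(Y = tidyr::replace_na(.data$biomass_g_m2, 0)) |>
    left_join(select(reference, "species_id", "M"), by = "species_id")
  if (any(is.na(tab$M))) {
    abort(sprintf("No monoculture reference for species: %s.",
                  paste(unique(tab$species_id[is.na(tab$M)]), collapse = ", ")),
          class = "oy_configuration_error")
  }
  if (!nrow(tab)) {
    abort("No active sown species; nothing to partition.",
          class = "oy_configuration_error")
  }

  per_species <- tab |>
    group_by(.data$plot_id) |>
    mutate(
      S = n(),
      RY_exp = .data$sown_proportion,
      RY_obs = .data$Y / .data$M,
      dRY = .data$RY_obs - .data$RY_exp,
      SE_i = (.data$dRY - mean(.data$dRY)) * (.data$M - mean(.data$M)),
      CE_i = .data$M * .data$dRY - .data$SE_i
    ) |>
    ungroup() |>
    select("plot_id", "species_id", "S", "M", "Y",
           "RY_exp", "RY_obs", "dRY", "SE_i", "CE_i")

  plots <- per_species |>
    summarise(S = .data$S[1], SE = sum(.data$SE_i), CE = sum(.data$CE_i),
              .by = "plot_id") |>
    mutate(
      is_mixture = .data$S > 1L,
      # monocultures: no mixture, no biodiversity effect by convention
      SE = ifelse(.data$is_mixture, .data$SE, 0),
      CE = ifelse(.data$is_mixture, .data$CE, 0),
      NE = .data$SE + .data$CE
    )

  out <- ds$design |>
    distinct(.data$plot_id, .data$block, .data$mixture_id, .data$sown_richness) |>
    inner_join(plots, by = "plot_id") |>
    select("plot_id", "block", "mixture_id", "sown_richness", "S",
           "NE", "CE", "SE", "is_mixture")
  attr(out, "species") <- per_species
  class(out) <- c("oy_partition", class(out))
  out
}

#' Per-species partition internals
#'
#' @param x An `oy_partition` result.
#' @return Long tibble with `plot_id`, `species_id`, `S`, `M`, `Y`, `RY_exp`,
#'   `RY_obs`, `dRY`, `SE_i`, `CE_i`.
#' @export
partition_species <- function(x) {
  stopifnot(inherits(x, "oy_partition"))
  attr(x, "species")
}

#' Square-root transform with sign reconstruction
#'
#' `signed_sqrt(y) = sign(y) * sqrt(|y|)`: the odd, order-preserving
#' square-root used to normalize biodiversity effects that take both signs.
#'
#' @param y Numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' signed_sqrt(c(-4, 0, 25)) # -2 0 5
#' @export
signed_sqrt <- function(y) sign(y) * sqrt(abs(y))

#' Test biodiversity effects against zero
#'
#' Tests, for each effect (NE, CE, SE), whether its grand mean across mixture
#' plots differs from zero, after the signed square-root transform. An ANOVA
#' of the transformed effect on block, sown species richness (log2, as a
#' covariate) and mixture identity supplies the error stratum: the test
#' compares the grand-mean sum of squares `n * mean(y)^2` against the model's
#' residual mean square, giving an F statistic with 1 and residual df.
#' Monoculture plots are excluded: biodiversity effects are defined for
#' mixtures.
#'
#' @param x An `oy_partition` result.
#' @param effects Which effect columns to test.
#' @param transform Transform applied before testing (default [signed_sqrt()];
#'   use `identity` for untransformed tests).
#' @return Object of class `oy_effect_test`; see [tidy.oy_effect_test()].
#' @export
test_effects_positive <- function(x, effects = c("NE", "CE", "SE"),
                                  transform = signed_sqrt) {
  stopifnot(inherits(x, "oy_partition"))
  mix <- filter(as_tibble(x), .data$is_mixture)
  if (nrow(mix) < 2) {
    abort("Need at least two mixture plots to test effects.",
          class = "oy_validation_error")
  }
  dat <- mix |>
    mutate(block = factor(.data$block),
           mixture_id = factor(.data$mixture_id),
           logS = log2(.data$sown_richness))

  res <- purrr::map_dfr(effects, function(eff) {
    y <- transform(mix[[eff]])
    if (all(y == 0)) {
      return(tibble(effect = eff, estimate = 0, statistic = 0,
                    df1 = 1, df2 = NA_real_, p.value = 1))
    }
    terms <- c(
      if (nlevels(dat$block) > 1) "block",
      if (n_distinct(dat$logS) > 1) "logS",
      if (nlevels(dat$mixture_id) > 1) "mixture_id"
    )
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fit <- lm(as.formula(paste("y ~", rhs)), data = dat)
    rdf <- fit$df.residual
    if (rdf < 1) {
      abort("Saturated model: no residual degrees of freedom. Drop design terms.",
            class = "oy_validation_error")
    }
    ms_res <- sum(fit$residuals^2) / rdf
    fstat <- length(y) * mean(y)^2 / ms_res
    tibble(effect = eff, estimate = mean(y), statistic = fstat,
           df1 = 1, df2 = rdf, p.value = pf(fstat, 1, rdf, lower.tail = FALSE))
  })
  structure(list(table = res, n = nrow(mix), transform_label =
                   if (identical(transform, identity)) "identity" else "signed_sqrt",
                 error_stratum = "model residual"),
            class = "oy_effect_test")
}

#' @export
print.oy_effect_test <- function(x, ...) {
  cat("Grand-mean tests of biodiversity effects against zero\n")
  cat(sprintf("  %d mixture plots; transform: %s; error stratum: %s\n\n",
              x$n, x$transform_label, x$error_stratum))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a biodiversity-effect test
#'
#' @param x An `oy_effect_test`.
#' @param ... Unused.
#' @return One row per effect: `effect`, `estimate` (grand mean on the
#'   transformed scale), `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
tidy.oy_effect_test <- function(x, ...) x$table

#' @rdname tidy.oy_effect_test
#' @export
glance.oy_effect_test <- function(x, ...) {
  tibble(n_mixture_plots = x$n, transform = x$transform_label,
         error_stratum = x$error_stratum)
}
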