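#' Community-weighted mean of a species-level trait
#'
#' CWM = sum_i p_i t_i, where p_i is species i's share of the plot's
#' sown-species biomass among species present at harvest (biomass > 0) and
#' t_i the species' trait value measured in that plot.
#'
#' @param ds An `oy_dataset` with a trait table.
#' @param trait Trait name (value of the `variable` column).
#' @param missing_trait What to do when a species present in a plot has no
#'   trait record there: `"error"` (default) or `"renormalize"` (drop the
#'   species from the weighting, renormalize p over the measured species, and
#'   emit a warning naming the plots affected).
#' @return Tibble `plot_id`, `trait`, `cwm`.
#' @export
cwm <- function(ds, trait, missing_trait = c("error", "renormalize")) {
  stopifnot(inherits(ds, "oy_dataset"))
  missing_trait <- match.arg(missing_trait)
  tr <- species_trait_values(ds, trait)
  present <- ds$biomass |>
    filter(.data$biomass_g_m2 > 0,
           .data$species_id %in% ds$species$species_id[ds$species$active])
  if (!nrow(present)) {
    abort("No plot has positive biomass; CWM undefined.",
          class = "oy_validation_error")
  }
  tab <- present |>
    left_join(tr, by = c("plot_id", "species_id"))
  gaps <- filter(tab, is.na(.data$t))
  if (nrow(gaps)) {
    msg <- sprintf("No `%s` value for %d present species record(s) (e.g. %s in %s).",
                   trait, nrow(gaps), gaps$species_id[1], gaps$plot_id[1])
    if (missing_trait == "error") {
      abort(paste(msg, "Use missing_trait = \"renormalize\" to drop them from the weighting."),
            class = "oy_missing_trait_error")
    }
    warn(paste(msg, "Weights renormalized over measured species."))
    tab <- filter(tab, !is.na(.data$t))
  }
  tab |>
    group_by(.data$plot_id) |>
    summarise(cwm = sum(.data$biomass_g_m2 * .data$t) / sum(.data$biomass_g_m2),
              .groups = "drop") |>
    mutate(trait = trait, .after = "plot_id")
}

species_trait_values <- function(ds, trait) {
  if (is.null(ds$traits)) {
    abort("Dataset has no trait table.", class = "oy_schema_error")
  }
  tr <- ds$traits |>
    filter(.data$variable == trait, !is.na(.data$species_id)) |>
    select("plot_id", "species_id", t = "value")
  if (!nrow(tr)) {
    abort(sprintf("No species-level records for trait `%s`.", trait),
          class = "oy_missing_trait_error")
  }
  tr
}

#' Pool-wide species trait means
#'
#' Unweighted arithmetic mean of each species-level trait value over all
#' plots where the species was measured. These means define the
#' composition/abundance ("fixed") component of the CWM decomposition.
#'
#' @param ds An `oy_dataset` with a trait table.
#' @param trait Optional trait name to restrict to.
#' @return Tibble `species_id`, `trait`, `mean_value`, `n_plots`.
#' @export
species_mean_traits <- function(ds, trait = NULL) {
  stopifnot(inherits(ds, "oy_dataset"))
  if (is.null(ds$traits)) {
    abort("Dataset has no trait table.", class = "oy_schema_error")
  }
  tr <- filter(ds$traits, !is.na(.data$species_id))
  if (!is.null(trait)) tr <- filter(tr, .data$variable %in% trait)
  if (!nrow(tr)) {
    abort("No species-level trait records.", class = "oy_missing_trait_error")
  }
  tr |>
    summarise(mean_value = mean(.data$value), n_plots = n(),
              .by = c("species_id", "variable")) |>
    rename(trait = "variable") |>
    arrange(.data$trait, .data$species_id)
}

#' Decompose the CWM into composition/abundance and adjustment components
#'
#' For each plot, `cwm_specific` is the CWM from plot-specific trait values;
#' `cwm_fixed` re-computes it with the same biomass weights but pool-wide
#' species trait means, so it varies only through species composition and
#' abundance; `cwm_adjust = cwm_specific - cwm_fixed` captures intraspecific
#' trait adjustment. The identity specific = fixed + adjust holds exactly by
#' construction.
#'
#' @inheritParams cwm
#' @return Tibble of class `oy_cwm_decomposition`: `plot_id`, `trait`,
#'   `cwm_specific`, `cwm_fixed`, `cwm_adjust`.
#' @examples
#' sim <- simulate_experiment(seed = 1)
#' head(decompose_cwm(sim$dataset, "plant_height"))
#' @export
decompose_cwm <- function(ds, trait, missing_trait = c("error", "renormalize")) {
  stopifnot(inherits(ds, "oy_dataset"))
  missing_trait <- match.arg(missing_trait)
  means <- species_mean_traits(ds, trait)
  tr <- species_trait_values(ds, trait)
  present <- ds$biomass |>
    filter(.data$biomass_g_m2 > 0,
           .data$species_id %in% ds$species$species_id[ds$species$active]) |>
    left_join(tr, by = c("plot_id", "species_id")) |>
    left_join(select(means, "species_id", t_bar = "mean_value"),
              by = "species_id")
  gaps <- filter(present, is.na(.data$t))
  if (nrow(gaps)) {
    msg <- sprintf("No `%s` value for %d present species record(s) (e.g. %s in %s).",
                   trait, nrow(gaps), gaps$species_id[1], gaps$plot_id[1])
    if (missing_trait == "error") {
      abort(paste(msg, "Use missing_trait = \"renormalize\" to drop them from the weighting."),
            class = "oy_missing_trait_error")
    }
    warn(paste(msg, "Weights renormalized over measured species."))
    present <- filter(present, !is.na(.data$t))
  }
  out <- present |>
    group_by(.data$plot_id) |>
    summarise(
      cwm_specific = sum(.data$biomass_g_m2 * .data$t) / sum(.data$biomass_g_m2),
      cwm_fixed = sum(.data$biomass_g_m2 * .data$t_bar) / sum(.data$biomass_g_m2),
      .groups = "drop") |>
    mutate(trait = trait, .after = "plot_id") |>
    mutate(cwm_adjust = .data$cwm_specific - .data$cwm_fixed)
  class(out) <- c("oy_cwm_decomposition", class(out))
  out
}

#' Sequential attribution of richness-explained CWM variance
#'
#' Fits, for each of the three decomposition components (specific CWM,
#' composition/abundance, adjustment), a sequential (Type-I) ANOVA with terms
#' in the order block, species richness, mixture identity, and extracts the
#' sum of squares attributed to the richness term. All three are expressed as
#' a percentage of the total sum of squares of the specific CWM, so the
#' components are commensurable, and the covariation share is defined as
#' specific% - fixed% - adjust% (it can be negative when composition and
#' adjustment trend in opposite directions along the richness gradient).
#'
#' @param decomp A [decompose_cwm()] result (may stack several traits).
#' @param design Design table or `oy_dataset` supplying `block`,
#'   `sown_richness` and `mixture_id` per plot.
#' @param richness_coding `"log2"` (default; log2 richness as a continuous
#'   covariate) or `"factor"`.
#' @return Tibble of class `oy_variance_attribution`, one row per trait:
#'   `trait`, `ss_total`, `pct_richness_specific`, `pct_richness_fixed`,
#'   `pct_richness_adjust`, `pct_richness_covariation`.
#' @export
attribute_variance <- function(decomp, design,
                               richness_coding = c("log2", "factor")) {
  richness_coding <- match.arg(richness_coding)
  if (inherits(design, "oy_dataset")) design <- design$design
  covars <- design |>
    distinct(.data$plot_id, .data$block, .data$mixture_id, .data$sown_richness)
  dat <- decomp |>
    as_tibble() |>
    inner_join(covars, by = "plot_id") |>
    mutate(block = factor(.data$block), mixture_id = factor(.data$mixture_id),
           richness = if (richness_coding == "log2") log2(.data$sown_richness)
                      else factor(.data$sown_richness))
  if (n_distinct(dat$sown_richness) < 2) {
    abort("Need at least two richness levels for variance attribution.",
          class = "oy_validation_error")
  }

  purrr::map_dfr(split(dat, dat$trait), function(d) {
    terms <- c(
      if (n_distinct(d$block) > 1) "block", "richness",
      if (n_distinct(d$mixture_id) > 1) "mixture_id"
    )
    ss_rich <- function(y) {
      fit <- lm(as.formula(paste("y ~", paste(terms, collapse = " + "))),
                data = d)
      # only the sequential sums of squares are used; the per-term F tests
      # (unreliable on saturated fits) are discarded
      an <- suppressWarnings(anova(fit))
      list(rich = an["richness", "Sum Sq"], total = sum(an[, "Sum Sq"]))
    }
    sp <- ss_rich(d$cwm_specific)
    if (sp$total <= 0) {
      abort(sprintf("Specific CWM of `%s` has zero total sum of squares.",
                    d$trait[1]), class = "oy_validation_error")
    }
    fx <- ss_rich(d$cwm_fixed)
    ad <- ss_rich(d$cwm_adjust)
    pct <- function(ss) 100 * ss / sp$total
    tibble(
      trait = d$trait[1],
      ss_total = sp$total,
      pct_richness_specific = pct(sp$rich),
      pct_richness_fixed = pct(fx$rich),
      pct_richness_adjust = pct(ad$rich),
      pct_richness_covariation =
        pct(sp$rich) - pct(fx$rich) - pct(ad$rich)
    )
  }) |>
    structure(class = c("oy_variance_attribution", class(tibble())))
}

#' z-transform a numeric vector
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (used to put
#' the composition/abundance and adjustment components of differently scaled
#' traits on a common axis for plotting).
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Standardized numeric vector.
#' @export
ztransform <- function(x) {
  if (length(x) < 2 || !all(is.finite(x))) {
    abort("ztransform needs >= 2 finite values.", class = "oy_validation_error")
  }
  s <- sd(x)
  if (s == 0) {
    abort("ztransform undefined for a constant vector.",
          class = "oy_validation_error")
  }
  (x - mean(x)) / s
}
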