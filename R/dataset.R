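#' Assemble and validate a biodiversity-experiment dataset
#'
#' Bundles the three tables describing a designed biodiversity experiment --
#' sown design, species-level biomass at harvest, and trait/soil measurements
#' -- into a validated dataset object. All tables are long/tidy, one value per
#' row.
#'
#' @param design Data frame with one row per plot x sown species:
#'   `plot_id`, `block`, `mixture_id`, `species_id`, `sown_proportion`.
#'   Replicate plots sharing a `mixture_id` must have identical sown species
#'   sets, and sown proportions must sum to 1 within each plot.
#' @param biomass Data frame with columns `plot_id`, `species_id`,
#'   `biomass_g_m2` (non-negative, g m^-2). Every row must refer to a species
#'   sown in that plot. Sown species without a row are treated as absent
#'   (zero biomass) downstream.
#' @param traits Optional data frame with columns `plot_id`, `species_id`
#'   (`NA` for plot-level variables such as soil properties or community root
#'   traits), `variable`, `value`, `unit`.
#' @param species Optional species pool table with columns `species_id`,
#'   `functional_group` (grass/forb/legume), `active`. When omitted it is
#'   inferred from the design (all species active, functional group unknown).
#'
#' @return An object of class `oy_dataset`: a list of tibbles `species`,
#'   `design`, `biomass`, `traits`, with `sown_richness` added to the design.
#' @examples
#' design <- tibble::tibble(
#'   plot_id = c("p1", "p2", "p2"), block = "B1",
#'   mixture_id = c("A", "AB", "AB"),
#'   species_id = c("A", "A", "B"),
#'   sown_proportion = c(1, 0.5, 0.5)
#' )
#' biomass <- tibble::tibble(
#'   plot_id = c("p1", "p2", "p2"), species_id = c("A", "A", "B"),
#'   biomass_g_m2 = c(200, 150, 25)
#' )
#' ds <- oy_dataset(design, biomass)
#' ds$design
#' @export
oy_dataset <- function(design, biomass, traits = NULL, species = NULL) {
  design <- check_schema(design, "design",
    c("plot_id", "block", "mixture_id", "species_id", "sown_proportion"))
  biomass <- check_schema(biomass, "biomass",
    c("plot_id", "species_id", "biomass_g_m2"))
  if (!is.null(traits)) {
    traits <- check_schema(traits, "traits",
      c("plot_id", "species_id", "variable", "value"))
    if (!"unit" %in% names(traits)) traits$unit <- NA_character_
  }

  design <- design |>
    mutate(across(c("plot_id", "block", "mixture_id", "species_id"), as.character)) |>
    group_by(.data$plot_id) |>
    mutate(sown_richness = n_distinct(.data$species_id)) |>
    ungroup()

  if (is.null(species)) {
    species <- tibble(
      species_id = sort(unique(design$species_id)),
      functional_group = NA_character_,
      active = TRUE
    )
  } else {
    species <- check_schema(species, "species", c("species_id"))
    if (!"functional_group" %in% names(species)) species$functional_group <- NA_character_
    if (!"active" %in% names(species)) species$active <- TRUE
    species <- as_tibble(species) |>
      mutate(species_id = as.character(.data$species_id))
  }

  ds <- structure(
    list(species = species, design = design,
         biomass = mutate(as_tibble(biomass),
                          across(c("plot_id", "species_id"), as.character)),
         traits = if (is.null(traits)) NULL else
           mutate(as_tibble(traits), plot_id = as.character(.data$plot_id),
                  species_id = as.character(.data$species_id))),
    class = "oy_dataset"
  )
  validate_dataset(ds)
}

check_schema <- function(x, table, required) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", table), class = "oy_schema_error")
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("Table `%s` is missing required column(s): %s.",
                  table, paste0("`", missing, "`", collapse = ", ")),
          class = "oy_schema_error")
  }
  as_tibble(x)
}

#' Validate a dataset against its structural invariants
#'
#' Checks uniqueness of species ids, the per-plot sum-to-one constraint on
#' sown proportions, consistency of replicate mixtures, referential integrity
#' of the biomass and trait tables against the design, and finiteness of all
#' measured values. Errors carry classes `oy_schema_error`,
#' `oy_referential_error` or `oy_validation_error`.
#'
#' @param ds An `oy_dataset`.
#' @param tol Tolerance for the sown-proportion sum (default `1e-6`).
#' @return `ds`, invisibly unchanged, if all checks pass.
#' @export
validate_dataset <- function(ds, tol = 1e-6) {
  stopifnot(inherits(ds, "oy_dataset"))
  sp <- ds$species
  if (anyDuplicated(sp$species_id)) {
    abort("Duplicated species_id in species pool.", class = "oy_validation_error")
  }
  if (!any(sp$active)) {
    abort("Species pool has no active species.", class = "oy_validation_error")
  }

  d <- ds$design
  if (anyDuplicated(d[c("plot_id", "species_id")])) {
    abort("Duplicated plot_id x species_id rows in design.",
          class = "oy_validation_error")
  }
  unknown <- setdiff(d$species_id, sp$species_id)
  if (length(unknown)) {
    abort(sprintf("Design refers to species not in the pool: %s.",
                  paste(unknown, collapse = ", ")),
          class = "oy_referential_error")
  }
  if (!is.numeric(d$sown_proportion) || any(!is.finite(d$sown_proportion)) ||
      any(d$sown_proportion < 0 | d$sown_proportion > 1)) {
    abort("sown_proportion must be finite and within [0, 1].",
          class = "oy_validation_error")
  }
  bad <- d |>
    summarise(s = sum(.data$sown_proportion), .by = "plot_id") |>
    filter(abs(.data$s - 1) > tol)
  if (nrow(bad)) {
    abort(sprintf("Sown proportions do not sum to 1 in plot(s): %s.",
                  paste(head(bad$plot_id, 5), collapse = ", ")),
          class = "oy_validation_error")
  }
  # replicate plots of one mixture identity must share the sown species set
  comp <- d |>
    group_by(.data$mixture_id, .data$plot_id) |>
    summarise(set = paste(sort(.data$species_id), collapse = "|"),
              .groups = "drop") |>
    summarise(n_sets = n_distinct(.data$set), .by = "mixture_id") |>
    filter(.data$n_sets > 1)
  if (nrow(comp)) {
    abort(sprintf("Replicate plots of mixture identity %s differ in sown species.",
                  paste(comp$mixture_id, collapse = ", ")),
          class = "oy_validation_error")
  }

  b <- ds$biomass
  if (!is.numeric(b$biomass_g_m2) || any(!is.finite(b$biomass_g_m2)) ||
      any(b$biomass_g_m2 < 0)) {
    abort("biomass_g_m2 must be finite and non-negative.",
          class = "oy_validation_error")
  }
  orphan <- anti_join(b, d, by = c("plot_id", "species_id"))
  if (nrow(orphan)) {
    abort(sprintf(
      "Biomass rows refer to species not sown in their plot (e.g. %s in %s).",
      orphan$species_id[1], orphan$plot_id[1]), class = "oy_referential_error")
  }
  if (anyDuplicated(b[c("plot_id", "species_id")])) {
    abort("Duplicated plot_id x species_id rows in biomass.",
          class = "oy_validation_error")
  }

  tr <- ds$traits
  if (!is.null(tr)) {
    if (!is.numeric(tr$value) || any(!is.finite(tr$value))) {
      abort("Trait values must be finite numbers.", class = "oy_validation_error")
    }
    if (any(!tr$plot_id %in% d$plot_id)) {
      abort("Trait rows refer to unknown plot_id.", class = "oy_referential_error")
    }
    sp_rows <- filter(tr, !is.na(.data$species_id))
    if (nrow(sp_rows)) {
      orphan <- anti_join(sp_rows, d, by = c("plot_id", "species_id"))
      if (nrow(orphan)) {
        abort(sprintf(
          "Species-level trait rows for species not sown in their plot (e.g. %s in %s).",
          orphan$species_id[1], orphan$plot_id[1]),
          class = "oy_referential_error")
      }
    }
  }
  invisible(ds)
}

#' @export
print.oy_dataset <- function(x, ...) {
  cat("<oy_dataset>\n")
  cat("  species:", nrow(x$species), "(", sum(x$species$active), "active )\n")
  cat("  plots:  ", n_distinct(x$design$plot_id),
      " richness levels:", paste(sort(unique(x$design$sown_richness)), collapse = "/"), "\n")
  cat("  biomass rows:", nrow(x$biomass), "\n")
  if (!is.null(x$traits)) {
    cat("  trait rows:  ", nrow(x$traits), "(",
        n_distinct(x$traits$variable), "variables )\n")
  }
  invisible(x)
}

#' Read a dataset from delimited files
#'
#' Reads the three (optionally four) tables of the documented on-disk schema
#' and returns a validated [oy_dataset()]. File schemas:
#' `design.csv` (plot_id, block, mixture_id, species_id, sown_proportion),
#' `biomass.csv` (plot_id, species_id, biomass_g_m2),
#' `traits.csv` (plot_id, species_id, variable, value, unit),
#' `species.csv` (species_id, functional_group, active).
#'
#' @param design_path,biomass_path Paths to the design and biomass tables.
#' @param traits_path,species_path Optional paths to trait and species tables.
#' @param delim Field delimiter (default comma).
#' @return A validated `oy_dataset`.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(design_path, biomass_path, traits_path = NULL,
                         species_path = NULL, delim = ",") {
  for (p in c(design_path, biomass_path, traits_path, species_path)) {
    if (!file.exists(p)) {
      abort(sprintf("File not found: %s", p), class = "oy_schema_error")
    }
  }
  rd <- function(p) {
    x <- readr::read_delim(p, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
    attr(x, "spec") <- NULL
    attr(x, "problems") <- NULL
    x
  }
  oy_dataset(
    design  = rd(design_path),
    biomass = rd(biomass_path),
    traits  = if (!is.null(traits_path)) rd(traits_path),
    species = if (!is.null(species_path)) rd(species_path)
  )
}

#' Write a dataset to delimited files
#'
#' Writes `design.csv`, `biomass.csv` and (when present) `traits.csv` and
#' `species.csv` under `dir`, mirroring the schemas read by [read_dataset()].
#' Round-tripping through disk reproduces the tables.
#'
#' @param ds An `oy_dataset`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter (default comma).
#' @return The paths written, invisibly.
#' @export
write_dataset <- function(ds, dir, delim = ",") {
  stopifnot(inherits(ds, "oy_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_delim(x, p, delim = delim, progress = FALSE)
    p
  }
  paths <- c(
    wr(select(ds$design, -"sown_richness"), "design.csv"),
    wr(ds$biomass, "biomass.csv"),
    if (!is.null(ds$traits)) wr(ds$traits, "traits.csv"),
    wr(ds$species, "species.csv")
  )
  invisible(paths)
}

#' Realized species richness per plot
#'
#' Counts, for every plot in the design, the sown species whose harvested
#' biomass strictly exceeds `threshold`. Species sown but without a biomass
#' row count as absent; a plot where every sown species died has realized
#' richness 0.
#'
#' @param design Design table (as in [oy_dataset()]) or an `oy_dataset`.
#' @param biomass Biomass table; ignored when `design` is an `oy_dataset`.
#' @param threshold Presence threshold in g m^-2 (default 0: any positive
#'   biomass counts).
#' @return Tibble with `plot_id`, `realized_richness`.
#' @export
realized_richness <- function(design, biomass = NULL, threshold = 0) {
  if (inherits(design, "oy_dataset")) {
    biomass <- design$biomass
    design <- design$design
  }
  stopifnot(is.numeric(threshold), threshold >= 0)
  present <- biomass |>
    filter(.data$biomass_g_m2 > threshold) |>
    summarise(realized_richness = n_distinct(.data$species_id), .by = "plot_id")
  design |>
    distinct(.data$plot_id) |>
    left_join(present, by = "plot_id") |>
    mutate(realized_richness = as.integer(
      tidyr::replace_na(.data$realized_richness, 0L)))
}

#' One-row-per-plot modelling frame
#'
#' Collapses a dataset to the per-plot covariates used throughout the
#' modelling functions: block, mixture identity, sown and realized richness,
#' total sown-species biomass, and a 0/1 sown-presence indicator column
#' `pres_<species_id>` for every active species.
#'
#' @param ds An `oy_dataset`.
#' @param threshold Presence threshold passed to [realized_richness()].
#' @return A tibble with one row per plot.
#' @export
plot_frame <- function(ds, threshold = 0) {
  stopifnot(inherits(ds, "oy_dataset"))
  base <- ds$design |>
    distinct(.data$plot_id, .data$block, .data$mixture_id, .data$sown_richness)
  totals <- ds$biomass |>
    summarise(biomass_total = sum(.data$biomass_g_m2), .by = "plot_id")
  pres <- ds$design |>
    filter(.data$species_id %in% ds$species$species_id[ds$species$active]) |>
    distinct(.data$plot_id, .data$species_id) |>
    mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "species_id", values_from = "present",
                       values_fill = 0L, names_prefix = "pres_")
  base |>
    left_join(realized_richness(ds$design, ds$biomass, threshold), by = "plot_id") |>
    left_join(totals, by = "plot_id") |>
    mutate(biomass_total = tidyr::replace_na(.data$biomass_total, 0)) |>
    left_join(pres, by = "plot_id") |>
    mutate(across(dplyr::starts_with("pres_"), \(x) tidyr::replace_na(x, 0L)))
}
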