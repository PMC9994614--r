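#' Two-order model comparison for richness vs. species identity
#'
#' Separates the effect of species richness from the effect of a focal
#' species' presence by fitting, with maximum likelihood, a null mixed model
#' with random intercepts for block and mixture identity, then adding the two
#' fixed terms in both orders:
#' * model 1: richness first, then the focal species' sown-presence indicator;
#' * model 2: presence first, then richness.
#'
#' Each added term is assessed by a likelihood-ratio test against the
#' preceding model. The focal species' identity effect counts as significant
#' only when it is significant in both orders; the richness effect counts as
#' "neutralized" when it is at least marginally significant in model 1 but
#' loses significance in model 2, i.e. once fitted after the presence term --
#' the signature that the species' presence carries the richness effect.
#'
#' @param data Per-plot data frame (see [plot_frame()]) containing `block`,
#'   `mixture_id`, the richness column, the presence indicator
#'   `pres_<focal_species>` and the response column.
#' @param response Name of the response column.
#' @param focal_species Species id; its indicator column is
#'   `pres_<focal_species>`.
#' @param richness `"sown"` (default) or `"realized"`: which richness column
#'   (`sown_richness` / `realized_richness`) enters the models.
#' @param richness_coding `"log2"` (continuous log2 covariate, default) or
#'   `"factor"`.
#' @param transform Optional function applied to the response before fitting
#'   (e.g. [signed_sqrt()] for biodiversity effects, `sqrt` for community
#'   biomass and root traits).
#' @param alpha Significance level for the verdicts (default 0.05).
#' @param marginal Upper bound of the marginal band (default 0.10).
#' @return Object of class `oy_seqfit`; `tidy()` returns the term-level LRTs
#'   and `glance()` the fit metadata. The one-row verdict summary is in
#'   `$summary`.
#' @examples
#' sim <- simulate_experiment(seed = 1)
#' pf <- plot_frame(sim$dataset)
#' fit <- fit_model_sequence(pf, "biomass_total", "Ae", transform = sqrt)
#' tidy(fit)
#' @export
fit_model_sequence <- function(data, response, focal_species,
                               richness = c("sown", "realized"),
                               richness_coding = c("log2", "factor"),
                               transform = NULL,
                               alpha = 0.05, marginal = 0.10) {
  richness <- match.arg(richness)
  richness_coding <- match.arg(richness_coding)
  data <- as_tibble(data)
  rich_col <- paste0(richness, "_richness")
  pres_col <- paste0("pres_", focal_species)
  for (col in c(response, rich_col, pres_col, "block", "mixture_id")) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` not found in data.", col),
            class = "oy_schema_error")
    }
  }
  y <- data[[response]]
  if (!all(is.finite(y))) {
    abort("Response contains non-finite values.", class = "oy_validation_error")
  }
  if (!is.null(transform)) y <- transform(y)
  n_pres <- sum(data[[pres_col]] > 0)
  if (n_pres < 2 || n_pres > nrow(data) - 2) {
    abort(sprintf("Focal species `%s` must be present in >= 2 and absent from >= 2 plots.",
                  focal_species), class = "oy_validation_error")
  }

  d <- tibble(
    y = y,
    rich = if (richness_coding == "log2") log2(data[[rich_col]])
           else factor(data[[rich_col]]),
    pres = as.numeric(data[[pres_col]] > 0),
    block = factor(data$block),
    mixture_id = factor(data$mixture_id)
  )

  # mixture identity confounded with plots (all singletons): single random factor
  random <- "(1 | block) + (1 | mixture_id)"
  if (max(table(d$mixture_id)) == 1L) {
    warn("Every mixture identity occurs in a single plot; dropping its random intercept.")
    random <- "(1 | block)"
  }

  if (var(d$y) == 0) {
    # degenerate response: every LRT is exactly null
    lrt <- tidyr::expand_grid(order = c("model1", "model2"),
                              term = c("richness", "identity")) |>
      mutate(step = rep(1:2, 2), statistic = 0, df = 1L, p.value = 1,
             .after = "term")
    summary <- seq_verdicts(response, focal_species, lrt,
                            dir_rich = 0, dir_pres = 0, alpha, marginal)
    return(structure(list(summary = summary, lrt = lrt, n = nrow(d),
                          random = random, richness = richness,
                          richness_coding = richness_coding,
                          alpha = alpha, marginal = marginal),
                     class = "oy_seqfit"))
  }

  fit_ml <- function(fixed, label) {
    f <- as.formula(paste("y ~", fixed, "+", random))
    tryCatch(
      suppressMessages(lme4::lmer(f, data = d, REML = FALSE,
                                  control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) abort(
        sprintf("Model `%s` failed to fit: %s", label, conditionMessage(e)),
        class = "oy_convergence_error")
    )
  }
  m0 <- fit_ml("1", "null")
  mr <- fit_ml("rich", "richness")
  mi <- fit_ml("pres", "identity")
  mri <- fit_ml("rich + pres", "richness + identity")

  lrt_row <- function(small, big, order, step, term) {
    an <- suppressMessages(anova(small, big))
    tibble(order = order, term = term, step = step,
           statistic = max(0, an$Chisq[2]), df = an$Df[2],
           p.value = an$`Pr(>Chisq)`[2])
  }
  lrt <- bind_rows(
    lrt_row(m0, mr, "model1", 1, "richness"),
    lrt_row(mr, mri, "model1", 2, "identity"),
    lrt_row(m0, mi, "model2", 1, "identity"),
    lrt_row(mi, mri, "model2", 2, "richness")
  )

  fe <- lme4::fixef(mri)
  dir_rich <- if (richness_coding == "log2") sign(fe[["rich"]])
              else sign(stats::cov(as.numeric(as.character(d$rich)), d$y))
  dir_pres <- sign(fe[["pres"]])

  structure(list(
    summary = seq_verdicts(response, focal_species, lrt,
                           dir_rich, dir_pres, alpha, marginal),
    lrt = lrt, n = nrow(d), random = random, richness = richness,
    richness_coding = richness_coding, alpha = alpha, marginal = marginal
  ), class = "oy_seqfit")
}

seq_verdicts <- function(response, species, lrt, dir_rich, dir_pres,
                         alpha, marginal) {
  g <- function(order, term, what) {
    lrt[[what]][lrt$order == order & lrt$term == term]
  }
  p_r1 <- g("model1", "richness", "p.value")
  p_r2 <- g("model2", "richness", "p.value")
  p_i1 <- g("model1", "identity", "p.value")
  p_i2 <- g("model2", "identity", "p.value")
  tibble(
    response = response, species = species,
    chisq_richness_m1 = g("model1", "richness", "statistic"), p_richness_m1 = p_r1,
    chisq_identity_m1 = g("model1", "identity", "statistic"), p_identity_m1 = p_i1,
    chisq_identity_m2 = g("model2", "identity", "statistic"), p_identity_m2 = p_i2,
    chisq_richness_m2 = g("model2", "richness", "statistic"), p_richness_m2 = p_r2,
    dir_richness = dir_rich, dir_identity = dir_pres,
    identity_significant = p_i1 < alpha & p_i2 < alpha,
    richness_neutralized = p_r1 < marginal & p_r2 >= alpha
  )
}

#' @export
print.oy_seqfit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Two-order model comparison: %s ~ richness (%s, %s) vs presence of %s\n",
              s$response, x$richness, x$richness_coding, s$species))
  cat(sprintf("  n = %d plots; random: %s\n", x$n, x$random))
  print(as.data.frame(x$lrt), row.names = FALSE, digits = 4)
  cat(sprintf("  identity significant in both orders: %s; richness neutralized: %s\n",
              s$identity_significant, s$richness_neutralized))
  invisible(x)
}

#' Tidy a two-order model comparison
#'
#' @param x An `oy_seqfit`.
#' @param ... Unused.
#' @return One row per added term and ordering: `order` (model1 = richness
#'   first, model2 = presence first), `term`, `step`, `statistic` (LRT
#'   chi-square), `df`, `p.value`.
#' @export
tidy.oy_seqfit <- function(x, ...) x$lrt

#' @rdname tidy.oy_seqfit
#' @export
glance.oy_seqfit <- function(x, ...) {
  tibble(n_plots = x$n, random = x$random, richness = x$richness,
         richness_coding = x$richness_coding,
         alpha = x$alpha, marginal = x$marginal)
}

#' Run the two-order comparison over a response x species grid
#'
#' @inheritParams fit_model_sequence
#' @param responses Character vector of response column names.
#' @param species Character vector of focal species ids.
#' @param transforms Optional named list mapping a response name to the
#'   transform applied before fitting.
#' @return Tibble with one verdict row per response x species (the `$summary`
#'   rows of [fit_model_sequence()] bound together).
#' @export
seq_test_grid <- function(data, responses, species,
                          richness = c("sown", "realized"),
                          richness_coding = c("log2", "factor"),
                          transforms = NULL, alpha = 0.05, marginal = 0.10) {
  richness <- match.arg(richness)
  richness_coding <- match.arg(richness_coding)
  grid <- tidyr::expand_grid(response = responses, sp = species)
  purrr::map2_dfr(grid$response, grid$sp, function(r, s) {
    fit_model_sequence(data, r, s, richness = richness,
                       richness_coding = richness_coding,
                       transform = transforms[[r]],
                       alpha = alpha, marginal = marginal)$summary
  })
}

#' Effect-summary classification table
#'
#' Condenses a [seq_test_grid()] result into one row per response: the
#' richness LRT from the richness-first ordering, a `+`/`-` cell per focal
#' species (filled only when the identity effect is significant in both
#' orderings, signed by the fitted coefficient), and whether the richness
#' effect was neutralized by any species' presence.
#'
#' @param results Verdict tibble from [seq_test_grid()].
#' @param marginal Marginal band used when labelling the richness direction.
#' @return Wide tibble, one row per response.
#' @export
classify_table <- function(results, marginal = 0.10) {
  sign_chr <- function(x) ifelse(x > 0, "+", ifelse(x < 0, "-", ""))
  cells <- results |>
    mutate(cell = ifelse(.data$identity_significant,
                         sign_chr(.data$dir_identity), "")) |>
    select("response", "species", "cell") |>
    tidyr::pivot_wider(names_from = "species", values_from = "cell")
  results |>
    summarise(
      richness_chisq = .data$chisq_richness_m1[1],
      richness_p = .data$p_richness_m1[1],
      richness_dir = ifelse(.data$p_richness_m1[1] < marginal,
                            sign_chr(.data$dir_richness[1]), ""),
      neutralized = ifelse(any(.data$richness_neutralized), "Yes", "No"),
      .by = "response") |>
    left_join(cells, by = "response") |>
    relocate("neutralized", .after = dplyr::last_col())
}
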