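#' Plot biodiversity effects along the richness gradient
#'
#' Scatter of NE, CE and SE (optionally signed-sqrt transformed) against sown
#' species richness for mixture plots, with per-level means.
#'
#' @param object An `oy_partition` result.
#' @param transform Transform for the y axis (default [signed_sqrt()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oy_partition <- function(object, transform = signed_sqrt, ...) {
  dat <- object |>
    as_tibble() |>
    filter(.data$is_mixture) |>
    tidyr::pivot_longer(c("NE", "CE", "SE"), names_to = "effect",
                        values_to = "value") |>
    mutate(value = transform(.data$value),
           effect = factor(.data$effect, levels = c("NE", "CE", "SE")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sown_richness, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "black") +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = sort(unique(dat$sown_richness))) +
    ggplot2::facet_wrap(ggplot2::vars(.data$effect)) +
    ggplot2::labs(x = "Sown species richness",
                  y = "Effect (signed-sqrt g m⁻²)")
}

#' Plot CWM decomposition components along the richness gradient
#'
#' Mirrors the classic composition-vs-adjustment display: both components are
#' z-transformed (their scales differ) and plotted against sown richness with
#' least-squares trend lines.
#'
#' @param object An `oy_cwm_decomposition` result.
#' @param design Design table or `oy_dataset` supplying `sown_richness`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oy_cwm_decomposition <- function(object, design, ...) {
  if (inherits(design, "oy_dataset")) design <- design$design
  dat <- object |>
    as_tibble() |>
    inner_join(distinct(design, .data$plot_id, .data$sown_richness),
               by = "plot_id") |>
    tidyr::pivot_longer(c("cwm_fixed", "cwm_adjust"), names_to = "component",
                        values_to = "value") |>
    mutate(component = dplyr::recode(.data$component,
                                     cwm_fixed = "composition/abundance",
                                     cwm_adjust = "adjustment")) |>
    group_by(.data$trait, .data$component) |>
    mutate(value = ztransform(.data$value)) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$sown_richness),
                                    y = .data$value, colour = .data$component)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::labs(x = "log2 sown species richness", y = "z-transformed component",
                  colour = NULL)
}

#' Plot richness-explained variance shares
#'
#' Bar chart of the composition/abundance, adjustment and covariation shares
#' of richness-explained CWM variance per trait (the three stack to the
#' specific-CWM share; covariation bars can be negative).
#'
#' @param object An `oy_variance_attribution` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oy_variance_attribution <- function(object, ...) {
  dat <- object |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::starts_with("pct_richness_"),
                        names_to = "component", names_prefix = "pct_richness_",
                        values_to = "pct") |>
    filter(.data$component != "specific") |>
    mutate(component = factor(.data$component,
                              levels = c("fixed", "adjust", "covariation"),
                              labels = c("composition/abundance", "adjustment",
                                         "covariation")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$trait, y = .data$pct,
                                    fill = .data$component)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "% of total specific-CWM SS explained by richness",
                  fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
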