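# ggplot2 views of the main result types: per-agent improvement profiles,
# the median (Q1, Q3) summary, and the effective-trust link.

#' Plot per-agent relative improvement against AI competence
#'
#' One line per agent, faceted by baseline trust; the zero line separates
#' agents who benefit from AI assistance from those who are harmed.
#'
#' @param improvements Output of [pair_and_improve()] (replicates are
#'   averaged before plotting).
#' @return A ggplot object.
#' @export
plot_improvement <- function(improvements) {
  avg <- average_improvements(improvements)
  ggplot2::ggplot(avg, ggplot2::aes(
    x = .data$alpha, y = .data$rel_improvement_pct,
    group = .data$agent_id,
    colour = factor(.data$competence),
    linetype = factor(.data$certainty)
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$baseline_trust),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "AI competence", y = "relative improvement (%)",
                  colour = "competence", linetype = "certainty")
}

#' @describeIn reproduce_table1 Median improvement with an interquartile
#'   ribbon per scenario.
#' @param object A `trustsim_table1`.
#' @param ... Unused.
#' @export
autoplot.trustsim_table1 <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$alpha, y = .data$median_pct,
    colour = .data$scenario, fill = .data$scenario
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1_pct, ymax = .data$q3_pct),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "AI competence",
                  y = "relative improvement, median (Q1, Q3) %")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the sigmoid effective-trust link
#'
#' Effective trust as a function of AI confidence, one curve per baseline
#' trust level.
#'
#' @param baseline_trust Trust levels to draw (default the canonical three).
#' @param params A [trust_params()].
#' @return A ggplot object.
#' @export
plot_effective_trust <- function(baseline_trust = c(0.3, 0.6, 0.9),
                                 params = trust_params()) {
  grid <- tidyr::expand_grid(
    baseline_trust = baseline_trust,
    kappa = seq(0, 1, by = 0.01)
  ) |>
    dplyr::mutate(tau = purrr::map2_dbl(
      .data$baseline_trust, .data$kappa,
      ~ effective_trust(.x, .y, params)
    ))
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$kappa, y = .data$tau,
    colour = factor(.data$baseline_trust)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "AI confidence", y = "effective trust",
                  colour = "baseline trust")
}
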