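#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an oracle-verification result
#'
#' @param x A `trustsim_verification` from [verify_oracle()].
#' @param ... Unused.
#' @return The per-cell tibble, one row per (mode, k, alpha, agent).
#' @export
tidy.trustsim_verification <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an oracle-verification result
#'
#' @param x A `trustsim_verification` from [verify_oracle()].
#' @param ... Unused.
#' @return A tibble with one row per mode: number of cells, maximum absolute
#'   z, number of failing cells, and the overall pass flag.
#' @export
glance.trustsim_verification <- function(x, ...) {
  tidy(x) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      max_abs_z = max(abs(.data$z)),
      n_fail = sum(!.data$pass),
      .by = "mode"
    ) |>
    dplyr::mutate(tolerance_se = attr(x, "tolerance_se"),
                  pass = .data$n_fail == 0)
}

#' Tidy the three-scenario summary table
#'
#' @param x A `trustsim_table1` from [reproduce_table1()].
#' @param ... Unused.
#' @return A plain tibble of the summary rows.
#' @export
tidy.trustsim_table1 <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row overview of the three-scenario summary table
#'
#' @param x A `trustsim_table1` from [reproduce_table1()].
#' @param ... Unused.
#' @return A tibble with one row per scenario: alpha range, median
#'   improvement at the lowest and highest alpha, and the improving-agent
#'   count at the highest alpha.
#' @export
glance.trustsim_table1 <- function(x, ...) {
  tidy(x) |>
    dplyr::summarise(
      alpha_min = min(.data$alpha),
      alpha_max = max(.data$alpha),
      median_at_min = .data$median_pct[which.min(.data$alpha)],
      median_at_max = .data$median_pct[which.max(.data$alpha)],
      n_improving_at_max = .data$n_improving[which.max(.data$alpha)],
      .by = "scenario"
    )
}
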