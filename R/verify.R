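# Oracle-equivalence verification: simulated accuracy vs the closed-form /
# quadrature expectation, cell by cell, in binomial standard-error units.

#' Verify the simulator against the analytic oracle
#'
#' Runs every cell of the canonical design — 27 agents x \{2, 3\} options
#' unassisted, x 7 AI competence levels under fixed trust, and x 7 levels
#' under conditional trust (two options) — and compares the simulated
#' accuracy with its expectation from the closed-form / quadrature oracle.
#' The discrepancy is reported as `z = (accuracy - expected) / SE` with
#' `SE = sqrt(expected * (1 - expected) / n_trials)`.
#'
#' @param seed Base seed.
#' @param n_trials Trials per cell (default 10000).
#' @param tolerance_se Pass threshold on `|z|` (default 4).
#' @return A tibble of class `trustsim_verification`, one row per cell, with
#'   `mode`, `k`, `alpha`, the traits, `accuracy`, `expected`, `se`, `z` and
#'   `pass`; the overall result is available via [glance()].
#' @export
verify_oracle <- function(seed = 1, n_trials = 10000, tolerance_se = 4) {
  agents <- build_agent_grid()
  design <- dplyr::bind_rows(
    tidyr::expand_grid(mode = "none", k = c(2L, 3L), alpha = NA_real_),
    tidyr::expand_grid(mode = "fixed", k = c(2L, 3L), alpha = build_alpha_grid()),
    tidyr::expand_grid(mode = "conditional", k = 2L, alpha = build_alpha_grid())
  )
  cells <- tidyr::expand_grid(design, agent_row = seq_len(nrow(agents)))
  rows <- purrr::pmap(cells, function(mode, k, alpha, agent_row) {
    profile <- agents[agent_row, ]
    model <- if (is.na(alpha)) NULL else ai_model(alpha)
    sim <- run_agent_trials(profile, model = model,
                            spec = task_spec(k, n_trials), mode = mode,
                            seed = seed)
    expected <- expected_accuracy(mode, profile$competence, profile$certainty,
                                  profile$baseline_trust, model, k)
    dplyr::mutate(sim, expected = expected)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      se = sqrt(.data$expected * (1 - .data$expected) / .data$n_trials),
      z = (.data$accuracy - .data$expected) / .data$se,
      pass = abs(.data$z) <= tolerance_se
    ) |>
    dplyr::select("mode", "k", "alpha", "agent_id", "competence", "certainty",
                  "baseline_trust", "n_trials", "accuracy", "expected",
                  "se", "z", "pass")
  class(out) <- c("trustsim_verification", class(out))
  attr(out, "tolerance_se") <- tolerance_se
  attr(out, "seed") <- seed
  out
}
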