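# Closed-form and quadrature expectations for every simulated quantity.
# These serve both as verification oracles for the Monte Carlo engine and as a
# fast "who benefits" calculator over the agent grid.

#' Expected accuracy of the unassisted two-stage decision
#'
#' The primary decision is correct with probability `competence`; the
#' certainty stage keeps it with probability `certainty` and otherwise moves
#' uniformly to one of the other k - 1 options. A kept correct decision stays
#' correct; a reversed wrong decision recovers the truth with probability
#' 1 / (k - 1). Hence
#' `h = o * c + (1 - o) * (1 - c) / (k - 1)`.
#'
#' @param competence,certainty Trait probabilities (vectorised).
#' @param n_options Number of options k >= 2.
#' @return Expected accuracy in \[0, 1\].
#' @examples
#' baseline_accuracy(0.9, 0.9, 2)  # 0.82
#' baseline_accuracy(0.9, 0.3, 2)  # 0.34
#' @export
baseline_accuracy <- function(competence, certainty, n_options = 2) {
  check_prob(competence, "competence")
  check_prob(certainty, "certainty")
  k <- check_count(n_options, "n_options", min = 2)
  competence * certainty + (1 - competence) * (1 - certainty) / (k - 1)
}

#' Expected accuracy with a fixed-trust AI adviser
#'
#' On conflicting trials the agent adopts the AI's prediction with constant
#' probability `trust`. A wrong post-uncertainty decision is repaired when the
#' AI is right and adopted; a right one is spoiled when the AI is wrong and
#' adopted; adopting a different wrong option never changes correctness. The
#' expectation collapses to `h + trust * (alpha - h)`.
#'
#' @param competence,certainty,trust Agent traits.
#' @param alpha AI competence.
#' @param n_options Number of options k.
#' @return Expected assisted accuracy in \[0, 1\].
#' @examples
#' assisted_accuracy_fixed(0.9, 0.3, 0.9, 0.9, 2)  # 0.844
#' @export
assisted_accuracy_fixed <- function(competence, certainty, trust, alpha,
                                    n_options = 2) {
  check_prob(trust, "trust")
  check_prob(alpha, "alpha")
  h <- baseline_accuracy(competence, certainty, n_options)
  h + trust * (alpha - h)
}

#' Expected effective trust under clipped-normal confidence
#'
#' Integrates the sigmoid effective-trust link against the confidence
#' distribution: a normal with mean `mu` and standard deviation `sigma`
#' clipped to \[0, 1\], i.e. a continuous density on (0, 1) plus point masses
#' at the bounds. The continuous part is evaluated by adaptive quadrature to
#' absolute error below 1e-6; `sigma = 0` degenerates to the sigmoid at `mu`.
#'
#' @param baseline_trust Agent baseline trust.
#' @param mu Mean of the (pre-clip) confidence normal.
#' @param sigma Standard deviation of the confidence normal.
#' @param params A [trust_params()].
#' @return The expectation of effective trust, in (0, 1).
#' @export
expected_effective_trust <- function(baseline_trust, mu, sigma,
                                     params = trust_params()) {
  check_prob(baseline_trust, "baseline_trust")
  check_prob(mu, "mu")
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be a non-negative number.")
  }
  if (sigma == 0) {
    return(effective_trust(baseline_trust, mu, params))
  }
  mass_lo <- pnorm(0, mean = mu, sd = sigma)
  mass_hi <- pnorm(1, mean = mu, sd = sigma, lower.tail = FALSE)
  cont <- integrate(
    function(x) effective_trust(baseline_trust, x, params) *
      dnorm(x, mean = mu, sd = sigma),
    lower = 0, upper = 1, rel.tol = 1e-9, abs.tol = 1e-9
  )$value
  mass_lo * effective_trust(baseline_trust, 0, params) +
    mass_hi * effective_trust(baseline_trust, 1, params) +
    cont
}

#' Expected accuracy with a confidence-conditional AI adviser
#'
#' Adoption on a conflicting trial happens with the effective trust of that
#' trial's confidence draw, whose distribution depends on whether the AI is
#' right. Writing `Ec`/`Ew` for the expected effective trust given a correct /
#' wrong prediction,
#' `accuracy = h + alpha * (1 - h) * Ec - (1 - alpha) * h * Ew`.
#'
#' @param competence,certainty,trust Agent traits.
#' @param model An [ai_model()] (carries alpha and the confidence parameters).
#' @param n_options Number of options k.
#' @param params A [trust_params()].
#' @return Expected assisted accuracy in \[0, 1\].
#' @export
assisted_accuracy_conditional <- function(competence, certainty, trust, model,
                                          n_options = 2,
                                          params = trust_params()) {
  check_prob(trust, "trust")
  h <- baseline_accuracy(competence, certainty, n_options)
  e_correct <- expected_effective_trust(trust, model$conf_mu_correct,
                                        model$conf_sigma, params)
  e_wrong <- expected_effective_trust(trust, model$conf_mu_wrong,
                                      model$conf_sigma, params)
  h + model$competence * (1 - h) * e_correct -
    (1 - model$competence) * h * e_wrong
}

#' Expected percent relative improvement over the unassisted baseline
#'
#' The percent change of expected assisted accuracy over the same agent's
#' unassisted expectation h; in fixed mode this is
#' `trust * (alpha / h - 1) * 100`.
#'
#' @param competence,certainty,trust Agent traits.
#' @param alpha AI competence (fixed mode) — ignored when `model` is given.
#' @param n_options Number of options k.
#' @param mode `"fixed"` or `"conditional"`.
#' @param model An [ai_model()] for conditional mode (defaults to
#'   `ai_model(alpha)`).
#' @param params A [trust_params()].
#' @return Percent relative improvement (can be negative).
#' @examples
#' expected_relative_improvement(0.9, 0.3, 0.9, 0.9)  # +148.24
#' @export
expected_relative_improvement <- function(competence, certainty, trust, alpha,
                                          n_options = 2, mode = "fixed",
                                          model = NULL,
                                          params = trust_params()) {
  h <- baseline_accuracy(competence, certainty, n_options)
  if (any(h == 0)) {
    abort("baseline accuracy is 0; relative improvement is undefined.")
  }
  assisted <- switch(
    check_mode(mode),
    fixed = assisted_accuracy_fixed(competence, certainty, trust, alpha,
                                    n_options),
    conditional = assisted_accuracy_conditional(
      competence, certainty, trust, model %||% ai_model(alpha), n_options,
      params),
    abort("`mode` must be \"fixed\" or \"conditional\" for an assisted run.")
  )
  (assisted - h) / h * 100
}

# expected accuracy for any mode; internal dispatch used by verify_oracle()
expected_accuracy <- function(mode, competence, certainty, trust,
                              model = NULL, n_options = 2,
                              params = trust_params()) {
  switch(
    check_mode(mode),
    none = baseline_accuracy(competence, certainty, n_options),
    fixed = assisted_accuracy_fixed(competence, certainty, trust,
                                    model$competence, n_options),
    conditional = assisted_accuracy_conditional(competence, certainty, trust,
                                                model, n_options, params)
  )
}
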