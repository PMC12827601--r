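#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data abort %||%
#' @importFrom stats median quantile rnorm runif dnorm pnorm integrate setNames
#' @importFrom utils write.csv
## usethis namespace: end
NULL

# ---- validation helpers ------------------------------------------------------

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1] (got %s).",
                  field, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d (got %s).", field, min, format(x)))
  }
  invisible(as.integer(x))
}

fmt_trait <- function(x) formatC(x, format = "fg", digits = 7, width = 1)

#' Identifier for an agent profile
#'
#' Agent identifiers are derived deterministically from the trait triple, so
#' the same (competence, certainty, baseline trust) always maps to the same id.
#'
#' @param competence,certainty,baseline_trust Trait probabilities in \[0, 1\].
#' @return A character vector of stable identifiers.
#' @export
agent_id <- function(competence, certainty, baseline_trust) {
  sprintf("o%s_c%s_t%s",
          fmt_trait(competence), fmt_trait(certainty), fmt_trait(baseline_trust))
}

# ---- domain types ------------------------------------------------------------

#' Construct and validate an agent profile
#'
#' A synthetic human decision-maker is described by three trait probabilities:
#' `competence` (the probability that the primary decision matches the true
#' label), `certainty` (the probability that the primary decision is kept
#' rather than reversed out of self-doubt) and `baseline_trust` (the a priori
#' probability of adopting a conflicting AI recommendation under fixed trust).
#'
#' @param competence,certainty,baseline_trust Probabilities in \[0, 1\].
#' @return A one-row tibble with the three traits and a stable `agent_id`.
#' @examples
#' agent_profile(0.9, 0.3, 0.9)
#' @export
agent_profile <- function(competence, certainty, baseline_trust) {
  check_prob(competence, "competence")
  check_prob(certainty, "certainty")
  check_prob(baseline_trust, "baseline_trust")
  tibble::tibble(
    agent_id = agent_id(competence, certainty, baseline_trust),
    competence = competence, certainty = certainty, baseline_trust = baseline_trust
  )
}

#' Construct and validate an AI adviser model
#'
#' The adviser predicts the true label with probability `competence`; errors
#' are uniform over the wrong options. In the conditional-trust mode it also
#' reports a confidence score drawn from a state-dependent normal distribution
#' (mean `conf_mu_correct` when the prediction is correct, `conf_mu_wrong` when
#' it is not, common standard deviation `conf_sigma`) clipped to \[0, 1\].
#'
#' @param competence Probability the AI's prediction is correct.
#' @param conf_mu_correct Mean confidence when correct (default 0.8).
#' @param conf_mu_wrong Mean confidence when incorrect (default 0.3).
#' @param conf_sigma Confidence standard deviation (default 0.1).
#' @return A one-row tibble describing the adviser.
#' @export
ai_model <- function(competence, conf_mu_correct = 0.8, conf_mu_wrong = 0.3,
                     conf_sigma = 0.1) {
  check_prob(competence, "competence")
  check_prob(conf_mu_correct, "conf_mu_correct")
  check_prob(conf_mu_wrong, "conf_mu_wrong")
  if (!is.numeric(conf_sigma) || length(conf_sigma) != 1 || is.na(conf_sigma) ||
      conf_sigma < 0) {
    abort("`conf_sigma` must be a non-negative number.")
  }
  tibble::tibble(
    competence = competence, conf_mu_correct = conf_mu_correct,
    conf_mu_wrong = conf_mu_wrong, conf_sigma = conf_sigma
  )
}

#' Parameters of the sigmoid effective-trust link
#'
#' Effective trust is `plogis(steepness * (baseline_trust * confidence -
#' offset))`: the product of baseline trust and AI confidence is pushed through
#' a logistic curve centred at `offset` with slope `steepness`.
#'
#' @param steepness Positive slope of the logistic link (default 10).
#' @param offset Midpoint of the link on the trust-times-confidence scale
#'   (default 0.4).
#' @return A list with class `trust_params`.
#' @export
trust_params <- function(steepness = 10, offset = 0.4) {
  if (!is.numeric(steepness) || length(steepness) != 1 || is.na(steepness) ||
      steepness <= 0) {
    abort("`steepness` must be a positive number.")
  }
  if (!is.numeric(offset) || length(offset) != 1 || is.na(offset)) {
    abort("`offset` must be a finite number.")
  }
  structure(list(steepness = steepness, offset = offset), class = "trust_params")
}

#' Specify a decision task
#'
#' A task is `n_trials` independent decisions among `n_options` alternatives
#' whose true labels are i.i.d. uniform over the options (a 50-50 split for
#' two options, an even three-way split for three).
#'
#' @param n_options Number of options k (>= 2).
#' @param n_trials Number of decisions per agent (default 10000).
#' @return A list with class `task_spec`.
#' @export
task_spec <- function(n_options = 2, n_trials = 10000) {
  n_options <- check_count(n_options, "n_options", min = 2)
  n_trials <- check_count(n_trials, "n_trials", min = 1)
  structure(list(n_options = n_options, n_trials = n_trials), class = "task_spec")
}

#' Trust modes
#'
#' `"none"` is the unassisted human baseline; `"fixed"` resolves conflicts with
#' the agent's constant baseline trust; `"conditional"` maps baseline trust and
#' the AI's per-trial confidence through the sigmoid link.
#'
#' @export
trust_modes <- function() c("none", "fixed", "conditional")

check_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1 || !mode %in% trust_modes()) {
    abort(sprintf("`mode` must be one of %s.",
                  paste(dQuote(trust_modes(), q = FALSE), collapse = ", ")))
  }
  mode
}

# ---- canonical grids ---------------------------------------------------------

#' The canonical grid of 27 agent profiles
#'
#' Every combination of competence, certainty and baseline trust over
#' \{0.3, 0.6, 0.9\} in lexicographic order (competence varying slowest,
#' baseline trust fastest), giving the 3 x 3 x 3 = 27 agent types.
#'
#' @param levels Trait levels used for all three traits.
#' @return A tibble with 27 rows: `agent_id`, `competence`, `certainty`,
#'   `baseline_trust`.
#' @examples
#' build_agent_grid()
#' @export
build_agent_grid <- function(levels = c(0.3, 0.6, 0.9)) {
  check_prob(levels, "levels")
  grid <- tidyr::expand_grid(
    competence = levels, certainty = levels, baseline_trust = levels
  )
  dplyr::mutate(
    grid,
    agent_id = agent_id(.data$competence, .data$certainty, .data$baseline_trust),
    .before = 1
  )
}

#' The canonical grid of AI competence values
#'
#' Seven adviser competence levels from 0.3 to 0.9 in steps of 0.1.
#'
#' @return A numeric vector of length 7.
#' @export
build_alpha_grid <- function() round(seq(0.3, 0.9, by = 0.1), 1)
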