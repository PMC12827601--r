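# Per-trial stochastic mechanics. All samplers are vectorised over trials and
# draw from R's current RNG stream; run_agent_trials() owns the substream
# seeding so that identical (seed, config) yields identical trial logs.

# Deterministic substream seed from a key path. The fold is exact in double
# arithmetic (intermediate values stay below 2^53) and lands in [1, 2^31 - 2].
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h) + 1L
}

# uniform pick among the k-1 options other than `current`, driven by u in [0,1)
pick_other <- function(current, k, u) {
  as.integer((current + 1L + as.integer(floor(u * (k - 1)))) %% k)
}

#' Sample true labels for a task
#'
#' Labels are i.i.d. uniform over the `n_options` options, labelled
#' `0 .. n_options - 1`.
#'
#' @param spec A [task_spec()].
#' @return An integer vector of length `spec$n_trials`.
#' @export
sample_labels <- function(spec) {
  as.integer(floor(runif(spec$n_trials) * spec$n_options))
}

#' Sample the agent's primary decision
#'
#' The primary decision equals the true label with probability `competence`;
#' otherwise it is uniform over the remaining wrong options.
#'
#' @param y Integer vector of true labels.
#' @param competence Probability of a correct primary decision.
#' @param n_options Number of options k.
#' @return Integer vector of primary decisions.
#' @export
sample_primary <- function(y, competence, n_options) {
  check_prob(competence, "competence")
  n <- length(y)
  u <- runif(n)
  wrong <- pick_other(y, n_options, runif(n))
  out <- y
  miss <- u >= competence
  out[miss] <- wrong[miss]
  out
}

#' Apply the certainty (self-doubt) stage
#'
#' The agent keeps the primary decision with probability `certainty`;
#' otherwise it reverses, i.e. switches to one of the other `n_options - 1`
#' options uniformly (for two options, the single alternative).
#'
#' @param d1 Integer vector of primary decisions.
#' @param certainty Probability of keeping the primary decision.
#' @param n_options Number of options k.
#' @return Integer vector of post-uncertainty decisions.
#' @export
apply_certainty <- function(d1, certainty, n_options) {
  check_prob(certainty, "certainty")
  n <- length(d1)
  u <- runif(n)
  flipped <- pick_other(d1, n_options, runif(n))
  out <- d1
  rev <- u >= certainty
  out[rev] <- flipped[rev]
  out
}

#' Sample the AI adviser's prediction
#'
#' Correct with probability `alpha`, otherwise uniform over wrong options
#' (the same error model as the human primary decision).
#'
#' @param y Integer vector of true labels.
#' @param alpha AI competence.
#' @param n_options Number of options k.
#' @return Integer vector of AI predictions.
#' @export
sample_ai_prediction <- function(y, alpha, n_options) {
  check_prob(alpha, "alpha")
  sample_primary(y, alpha, n_options)
}

#' Sample state-dependent AI confidence
#'
#' One draw per trial from a normal with mean `conf_mu_correct` where the
#' prediction was correct and `conf_mu_wrong` where it was not, standard
#' deviation `conf_sigma`, then clipped into \[0, 1\] (point masses at the
#' bounds, not truncation-renormalisation).
#'
#' @param ai_correct Logical vector, prediction correct per trial.
#' @param model An [ai_model()].
#' @return Numeric vector of confidence scores in \[0, 1\].
#' @export
sample_confidence <- function(ai_correct, model) {
  mu <- ifelse(ai_correct, model$conf_mu_correct, model$conf_mu_wrong)
  pmin(pmax(rnorm(length(ai_correct), mean = mu, sd = model$conf_sigma), 0), 1)
}

#' Sigmoid effective trust
#'
#' Maps baseline trust and AI confidence to a per-trial adoption probability:
#' `plogis(steepness * (baseline_trust * kappa - offset))`. Deterministic and
#' strictly inside (0, 1).
#'
#' @param baseline_trust Agent baseline trust in \[0, 1\].
#' @param kappa AI confidence in \[0, 1\] (vectorised).
#' @param params A [trust_params()].
#' @return Numeric vector of effective trust values.
#' @examples
#' effective_trust(0.9, 0.8)  # 1 / (1 + exp(-3.2))
#' @export
effective_trust <- function(baseline_trust, kappa, params = trust_params()) {
  check_prob(baseline_trust, "baseline_trust")
  check_prob(kappa, "kappa")
  stats::plogis(params$steepness * (baseline_trust * kappa - params$offset))
}

# shared conflict-resolution core: one Bernoulli(prob) adoption draw per
# conflicting trial; agreement never triggers reconsideration
resolve_conflicts <- function(d2, p, prob) {
  n <- length(d2)
  u <- runif(n)
  adopted <- (p != d2) & (u < prob)
  d_final <- d2
  d_final[adopted] <- p[adopted]
  tibble::tibble(d_final = as.integer(d_final), adopted = adopted)
}

#' Resolve human-AI conflicts under fixed trust
#'
#' Where the AI prediction differs from the post-uncertainty decision, the
#' agent adopts it with constant probability `trust`; agreeing trials pass
#' through unchanged.
#'
#' @param d2 Integer vector of post-uncertainty decisions.
#' @param p Integer vector of AI predictions.
#' @param trust Constant adoption probability.
#' @return A tibble with columns `d_final` and `adopted`.
#' @export
resolve_fixed <- function(d2, p, trust) {
  check_prob(trust, "trust")
  resolve_conflicts(d2, p, trust)
}

#' Resolve human-AI conflicts under conditional trust
#'
#' As [resolve_fixed()], but with a per-trial adoption probability `tau`
#' (typically the [effective_trust()] of that trial's AI confidence).
#'
#' @param d2 Integer vector of post-uncertainty decisions.
#' @param p Integer vector of AI predictions.
#' @param tau Numeric vector of per-trial adoption probabilities.
#' @return A tibble with columns `d_final` and `adopted`.
#' @export
resolve_conditional <- function(d2, p, tau) {
  check_prob(tau, "tau")
  resolve_conflicts(d2, p, tau)
}

#' Run all trials for one agent in one condition
#'
#' Executes the per-trial pipeline label -> primary decision -> certainty
#' reversal -> (AI prediction -> \[confidence -> effective trust\] -> conflict
#' resolution) for `spec$n_trials` trials. Randomness is drawn from named
#' substreams keyed by (seed, agent, replicate, stage) for the human stages
#' and additionally by the AI competence for the AI stages, so a fixed-trust
#' run with zero trust is trial-for-trial identical to the unassisted run and
#' baselines are paired with assisted runs by common random numbers.
#'
#' @param profile One-row tibble from [agent_profile()] or a row of
#'   [build_agent_grid()].
#' @param model An [ai_model()], required unless `mode = "none"`.
#' @param spec A [task_spec()].
#' @param mode One of [trust_modes()].
#' @param seed Base integer seed.
#' @param replicate Replicate index (part of the substream key).
#' @param keep_trials If `TRUE`, attach the full trial log as a list-column.
#' @param params A [trust_params()] (conditional mode only).
#' @return A one-row tibble with `agent_id`, traits, `mode`, `k`, `alpha`,
#'   `replicate`, `n_trials`, `n_correct`, `accuracy`,
#'   `median_effective_trust` (NA outside conditional mode) and, when
#'   requested, a `trials` list-column of per-trial records.
#' @examples
#' run_agent_trials(agent_profile(0.9, 0.9, 0.6), spec = task_spec(2, 1000),
#'                  mode = "none", seed = 1)
#' @export
run_agent_trials <- function(profile, model = NULL, spec = task_spec(),
                             mode = "none", seed = 1, replicate = 1,
                             keep_trials = FALSE, params = trust_params()) {
  check_mode(mode)
  if (mode != "none" && is.null(model)) {
    abort("`model` must be supplied when `mode` is not \"none\".")
  }
  k <- spec$n_options
  n <- spec$n_trials
  alpha <- if (is.null(model)) NA_real_ else model$competence
  hs <- function(stage) {
    substream_seed(seed, profile$agent_id, replicate, stage)
  }
  as <- function(stage) {
    substream_seed(seed, profile$agent_id, sprintf("a%.6f", alpha),
                   replicate, stage)
  }

  y  <- withr::with_seed(hs("labels"), sample_labels(spec))
  d1 <- withr::with_seed(hs("primary"),
                         sample_primary(y, profile$competence, k))
  d2 <- withr::with_seed(hs("certainty"),
                         apply_certainty(d1, profile$certainty, k))

  p <- rep(NA_integer_, n)
  kappa <- rep(NA_real_, n)
  tau <- rep(NA_real_, n)
  if (mode == "none") {
    d_final <- d2
    adopted <- rep(FALSE, n)
  } else {
    p <- withr::with_seed(as("ai"), sample_ai_prediction(y, alpha, k))
    if (mode == "fixed") {
      res <- withr::with_seed(
        as("adoption"), resolve_fixed(d2, p, profile$baseline_trust))
    } else {
      kappa <- withr::with_seed(as("confidence"),
                                sample_confidence(p == y, model))
      tau <- effective_trust(profile$baseline_trust, kappa, params)
      res <- withr::with_seed(as("adoption"), resolve_conditional(d2, p, tau))
    }
    d_final <- res$d_final
    adopted <- res$adopted
  }

  out <- tibble::tibble(
    agent_id = profile$agent_id,
    competence = profile$competence,
    certainty = profile$certainty,
    baseline_trust = profile$baseline_trust,
    mode = mode,
    k = k,
    alpha = alpha,
    replicate = as.integer(replicate),
    n_trials = n,
    n_correct = sum(d_final == y),
    accuracy = mean(d_final == y),
    median_effective_trust = if (mode == "conditional") median(tau) else NA_real_
  )
  if (keep_trials) {
    out$trials <- list(tibble::tibble(
      trial = seq_len(n), y = y, d1 = d1, d2 = d2, p = p,
      kappa = kappa, tau = tau, adopted = adopted, d_final = d_final
    ))
  }
  out
}
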