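# Factorial scenario execution over agents x AI competence x task x mode,
# baseline pairing, relative improvement, and the cross-agent summary tables.

#' Configure a simulation scenario
#'
#' Bundles everything one factorial run needs: the trust mode, the task, the
#' AI competence grid, the agent grid, the seed and the number of replicate
#' runs. Validation happens here so the runners can assume a sound config.
#'
#' @param mode One of [trust_modes()]. With `mode = "none"` no `alphas` may be
#'   supplied (there is no adviser to sweep).
#' @param n_options Number of options k.
#' @param alphas AI competence values to sweep (default [build_alpha_grid()]
#'   for assisted modes, `NULL` for `"none"`).
#' @param n_trials Decisions per agent per run (default 10000).
#' @param seed Base integer seed; all randomness derives from it.
#' @param replicates Number of replicate runs (>= 1).
#' @param agents Agent grid tibble (default [build_agent_grid()]).
#' @param trust_params A [trust_params()].
#' @param conf_mu_correct,conf_mu_wrong,conf_sigma Confidence-distribution
#'   parameters applied to every adviser (conditional mode).
#' @param keep_trials Retain per-trial logs as a list-column.
#' @return A validated list with class `scenario_config`.
#' @examples
#' scenario_config("fixed", n_options = 2, n_trials = 1000, seed = 7)
#' @export
scenario_config <- function(mode, n_options = 2, alphas = NULL,
                            n_trials = 10000, seed = 1, replicates = 1,
                            agents = build_agent_grid(),
                            trust_params = NULL,
                            conf_mu_correct = 0.8, conf_mu_wrong = 0.3,
                            conf_sigma = 0.1, keep_trials = FALSE) {
  check_mode(mode)
  if (mode == "none") {
    if (!is.null(alphas)) {
      abort("`alphas` must not be supplied when `mode` is \"none\".")
    }
  } else {
    alphas <- alphas %||% build_alpha_grid()
    if (length(alphas) == 0) abort("`alphas` must be non-empty.")
    check_prob(alphas, "alphas")
  }
  spec <- task_spec(n_options, n_trials)
  replicates <- check_count(replicates, "replicates", min = 1)
  seed <- check_count(seed, "seed", min = 0)
  if (!is.data.frame(agents) ||
      !all(c("agent_id", "competence", "certainty", "baseline_trust") %in%
           names(agents))) {
    abort("`agents` must be a tibble like build_agent_grid().")
  }
  tp <- trust_params %||% trust_params()
  if (!inherits(tp, "trust_params")) abort("`trust_params` must come from trust_params().")
  check_prob(conf_mu_correct, "conf_mu_correct")
  check_prob(conf_mu_wrong, "conf_mu_wrong")
  if (conf_sigma < 0) abort("`conf_sigma` must be non-negative.")
  structure(list(
    mode = mode, spec = spec, alphas = alphas, seed = seed,
    replicates = replicates, agents = tibble::as_tibble(agents),
    trust_params = tp, conf_mu_correct = conf_mu_correct,
    conf_mu_wrong = conf_mu_wrong, conf_sigma = conf_sigma,
    keep_trials = isTRUE(keep_trials)
  ), class = "scenario_config")
}

#' Read a scenario configuration from JSON or YAML
#'
#' The file mirrors the arguments of [scenario_config()]; unknown keys are
#' rejected so typos fail loudly rather than silently falling back to
#' defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- setdiff(names(formals(scenario_config)), "agents")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$trust_params)) {
    raw$trust_params <- do.call(trust_params, as.list(raw$trust_params))
  }
  do.call(scenario_config, raw)
}

#' Run a factorial scenario
#'
#' For every (agent, replicate) an unassisted baseline run is executed; for
#' assisted modes, every (agent, alpha, replicate) additionally gets an
#' assisted run. Human-stage substreams depend only on (seed, agent,
#' replicate), so each baseline shares its labels and human decisions with the
#' assisted runs it is paired to (common random numbers).
#'
#' @param config A [scenario_config()].
#' @param progress Emit a progress message per replicate (to stderr).
#' @return A tibble with one row per run, columns as in [run_agent_trials()].
#' @examples
#' run_scenario(scenario_config("none", n_options = 2, n_trials = 500, seed = 1))
#' @export
run_scenario <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  agents <- config$agents
  runs <- tidyr::expand_grid(
    replicate = seq_len(config$replicates),
    agent_row = seq_len(nrow(agents)),
    alpha = c(NA_real_, config$alphas)
  )
  out <- purrr::pmap(runs, function(replicate, agent_row, alpha) {
    profile <- agents[agent_row, ]
    if (is.na(alpha)) {
      run_agent_trials(profile, model = NULL, spec = config$spec,
                       mode = "none", seed = config$seed,
                       replicate = replicate, keep_trials = config$keep_trials)
    } else {
      model <- ai_model(alpha, config$conf_mu_correct, config$conf_mu_wrong,
                        config$conf_sigma)
      run_agent_trials(profile, model = model, spec = config$spec,
                       mode = config$mode, seed = config$seed,
                       replicate = replicate, keep_trials = config$keep_trials,
                       params = config$trust_params)
    }
  })
  res <- dplyr::bind_rows(out)
  if (progress) {
    message(sprintf("scenario %s k=%d: %d runs over %d agents x %d replicates",
                    config$mode, config$spec$n_options, nrow(res),
                    nrow(agents), config$replicates))
  }
  res
}

#' Pair assisted runs with their unassisted baselines
#'
#' Joins each assisted row to the same agent's unassisted run in the same
#' replicate and computes the percent relative improvement
#' `(assisted - baseline) / baseline * 100`.
#'
#' @param results Output of [run_scenario()] (baseline and assisted rows).
#' @return A tibble with one row per (agent, alpha, replicate): traits, `k`,
#'   `mode`, `baseline_accuracy`, `assisted_accuracy`, `rel_improvement_pct`,
#'   `improved`, `median_effective_trust`.
#' @export
pair_and_improve <- function(results) {
  baselines <- results |>
    dplyr::filter(.data$mode == "none") |>
    dplyr::select("agent_id", "replicate", baseline_accuracy = "accuracy")
  assisted <- dplyr::filter(results, .data$mode != "none")
  if (nrow(assisted) == 0) abort("no assisted rows to pair.")
  missing <- dplyr::anti_join(assisted, baselines,
                              by = c("agent_id", "replicate"))
  if (nrow(missing) > 0) {
    abort(sprintf("missing baseline run for %d assisted row(s), e.g. %s rep %d.",
                  nrow(missing), missing$agent_id[1], missing$replicate[1]))
  }
  paired <- dplyr::inner_join(assisted, baselines,
                              by = c("agent_id", "replicate"))
  if (any(paired$baseline_accuracy == 0)) {
    abort("baseline accuracy of 0 encountered; relative improvement undefined.")
  }
  paired |>
    dplyr::mutate(
      assisted_accuracy = .data$accuracy,
      rel_improvement_pct =
        (.data$assisted_accuracy - .data$baseline_accuracy) /
        .data$baseline_accuracy * 100,
      improved = .data$rel_improvement_pct > 0
    ) |>
    dplyr::select("agent_id", "competence", "certainty", "baseline_trust",
                  "mode", "k", "alpha", "replicate", "n_trials",
                  "baseline_accuracy", "assisted_accuracy",
                  "rel_improvement_pct", "improved", "median_effective_trust")
}

# replicate-average accuracies per (agent, alpha), then recompute improvement;
# quantiles over agents are taken on these averaged values
average_improvements <- function(improvements) {
  improvements |>
    dplyr::summarise(
      baseline_accuracy = mean(.data$baseline_accuracy),
      assisted_accuracy = mean(.data$assisted_accuracy),
      median_effective_trust = median(.data$median_effective_trust),
      .by = c("agent_id", "competence", "certainty", "baseline_trust",
              "mode", "k", "alpha")
    ) |>
    dplyr::mutate(
      rel_improvement_pct =
        (.data$assisted_accuracy - .data$baseline_accuracy) /
        .data$baseline_accuracy * 100,
      improved = .data$rel_improvement_pct > 0
    )
}

#' Summarise relative improvement across the agent grid
#'
#' Per (alpha, mode, k): the median and quartiles (linear-interpolation
#' convention) of the per-agent percent relative improvements, after
#' replicate-averaging each agent's accuracies, plus the count of improving
#' agents.
#'
#' @param improvements Output of [pair_and_improve()].
#' @param require_full_grid Insist on exactly 27 agents per cell (the
#'   canonical grid); set `FALSE` for ad-hoc subsets.
#' @return A tibble with columns `alpha`, `mode`, `k`, `median_pct`, `q1_pct`,
#'   `q3_pct`, `n_improving`, `n_agents`.
#' @export
summarize_improvements <- function(improvements, require_full_grid = TRUE) {
  avg <- average_improvements(improvements)
  out <- avg |>
    dplyr::summarise(
      median_pct = unname(quantile(.data$rel_improvement_pct, 0.5, type = 7)),
      q1_pct = unname(quantile(.data$rel_improvement_pct, 0.25, type = 7)),
      q3_pct = unname(quantile(.data$rel_improvement_pct, 0.75, type = 7)),
      n_improving = sum(.data$rel_improvement_pct > 0),
      n_agents = dplyr::n(),
      .by = c("alpha", "mode", "k")
    ) |>
    dplyr::arrange(.data$alpha)
  if (require_full_grid && any(out$n_agents != 27)) {
    abort(sprintf("expected 27 agents per (alpha, mode) cell, got %s.",
                  paste(unique(out$n_agents), collapse = ", ")))
  }
  out
}

#' Count improving agents per AI competence level
#'
#' The number of agents whose replicate-averaged relative improvement is
#' strictly positive at each alpha.
#'
#' @param improvements Output of [pair_and_improve()].
#' @param alpha Optional single alpha to count at (default: all).
#' @return A tibble with columns `alpha`, `n_improving`, `n_agents`, or a
#'   single integer when `alpha` is given.
#' @export
count_improving <- function(improvements, alpha = NULL) {
  if (nrow(improvements) == 0) abort("empty improvement set.")
  avg <- average_improvements(improvements)
  counts <- avg |>
    dplyr::summarise(n_improving = sum(.data$rel_improvement_pct > 0),
                     n_agents = dplyr::n(), .by = "alpha") |>
    dplyr::arrange(.data$alpha)
  if (is.null(alpha)) return(counts)
  hit <- counts$n_improving[abs(counts$alpha - alpha) < 1e-9]
  if (length(hit) != 1) abort(sprintf("no improvements at alpha = %s.", alpha))
  hit
}

#' Per-agent median effective trust from trial logs
#'
#' @param results Output of [run_scenario()] with `keep_trials = TRUE` in
#'   conditional mode.
#' @return A tibble with `agent_id`, `baseline_trust`, `alpha`, `replicate`,
#'   `median_effective_trust` computed over the trial-level effective trust.
#' @export
median_effective_trust <- function(results) {
  if (!"trials" %in% names(results)) {
    abort("`results` carries no trial logs; rerun with keep_trials = TRUE.")
  }
  results |>
    dplyr::filter(.data$mode == "conditional") |>
    dplyr::mutate(
      median_effective_trust =
        purrr::map_dbl(.data$trials, ~ median(.x$tau))
    ) |>
    dplyr::select("agent_id", "baseline_trust", "alpha", "replicate",
                  "median_effective_trust")
}

#' Reproduce the three-scenario summary table
#'
#' Runs the three headline scenarios — fixed trust with two options, fixed
#' trust with three options, and conditional trust with two options — over
#' the 27-agent grid and the seven-value AI competence grid, and summarises
#' the percent relative improvements as median (Q1, Q3) across agents plus
#' the count of improving agents.
#'
#' @param seed Base seed.
#' @param replicates Replicate runs averaged per agent (default 10).
#' @param n_trials Decisions per agent per run (default 10000).
#' @param alphas AI competence grid (default [build_alpha_grid()]).
#' @param progress Emit progress messages.
#' @return A tibble of class `trustsim_table1` with columns `alpha`,
#'   `scenario` (`two_options`, `three_options`, `conditional_trust`),
#'   `median_pct`, `q1_pct`, `q3_pct`, `n_improving`.
#' @export
reproduce_table1 <- function(seed = 1, replicates = 10, n_trials = 10000,
                             alphas = build_alpha_grid(), progress = FALSE) {
  cells <- list(
    two_options = list(mode = "fixed", k = 2),
    three_options = list(mode = "fixed", k = 3),
    conditional_trust = list(mode = "conditional", k = 2)
  )
  out <- purrr::imap(cells, function(cell, label) {
    cfg <- scenario_config(cell$mode, n_options = cell$k, alphas = alphas,
                           n_trials = n_trials, seed = seed,
                           replicates = replicates)
    run_scenario(cfg, progress = progress) |>
      pair_and_improve() |>
      summarize_improvements() |>
      dplyr::mutate(scenario = label)
  })
  tbl <- dplyr::bind_rows(out) |>
    dplyr::select("alpha", "scenario", "median_pct", "q1_pct", "q3_pct",
                  "n_improving") |>
    dplyr::arrange(.data$alpha, match(.data$scenario, names(cells)))
  class(tbl) <- c("trustsim_table1", class(tbl))
  attr(tbl, "seed") <- seed
  attr(tbl, "replicates") <- replicates
  tbl
}
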