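# Heavy simulation runs shared across test files, computed once per session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# binary fixed-trust sweep at the alphas the reproduction checks need,
# 10,000 trials x 10 replicates over the canonical 27-agent grid
fixed_k2_run <- function() {
  cached("fixed_k2", {
    cfg <- scenario_config("fixed", n_options = 2,
                           alphas = c(0.3, 0.6, 0.7, 0.8, 0.9),
                           n_trials = 10000, seed = 42, replicates = 10)
    run_scenario(cfg)
  })
}

fixed_k2_improvements <- function() {
  cached("fixed_k2_imp", pair_and_improve(fixed_k2_run()))
}

# ternary unassisted baselines, same scale
none_k3_run <- function() {
  cached("none_k3", {
    cfg <- scenario_config("none", n_options = 3, n_trials = 10000,
                           seed = 42, replicates = 10)
    run_scenario(cfg)
  })
}
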