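# Per-stage sampler checks against binomial/frequency oracles, the sigmoid
# trust link, and the trial-level invariants of the full pipeline.

se_bin <- function(p, n) sqrt(p * (1 - p) / n)

test_that("true labels are uniform over the options", {
  withr::local_seed(101)
  for (k in c(2L, 3L)) {
    y <- sample_labels(task_spec(k, 1e6))
    expect_true(all(y %in% 0:(k - 1)))
    freq <- tabulate(y + 1L, nbins = k) / 1e6
    expect_true(all(abs(freq - 1 / k) < 4 * se_bin(1 / k, 1e6)))
  }
  expect_length(sample_labels(task_spec(3, 1)), 1)
})

test_that("primary decision matches the label with probability competence", {
  withr::local_seed(102)
  y <- sample_labels(task_spec(2, 1e5))
  expect_identical(sample_primary(y, 1, 2), y)
  d1 <- sample_primary(y, 0.9, 2)
  expect_equal(mean(d1 == y), 0.9, tolerance = 4 * se_bin(0.9, 1e5) / 0.9)
  # errors spread uniformly over wrong options: each wrong option gets
  # (1 - o) / (k - 1) = 0.35 under o = 0.3, k = 3
  y3 <- rep(0L, 1e5)
  d13 <- sample_primary(y3, 0.3, 3)
  for (wrong in 1:2) {
    expect_equal(mean(d13 == wrong), 0.35,
                 tolerance = 4 * se_bin(0.35, 1e5) / 0.35)
  }
})

test_that("certainty stage keeps or reverses the primary decision", {
  withr::local_seed(103)
  d1 <- sample_labels(task_spec(2, 1e4))
  expect_identical(apply_certainty(d1, 1, 2), d1)
  expect_identical(apply_certainty(d1, 0, 2), 1L - d1)
  # k = 3, c = 0.4, d1 = 2: reversal splits 0.6 evenly over options 0 and 1
  d2 <- apply_certainty(rep(2L, 1e5), 0.4, 3)
  freq <- tabulate(d2 + 1L, nbins = 3) / 1e5
  expect_equal(freq, c(0.3, 0.3, 0.4), tolerance = 4 * se_bin(0.3, 1e5) / 0.3)
})

test_that("AI predictions follow the same error model as the human", {
  withr::local_seed(104)
  y <- sample_labels(task_spec(2, 1e5))
  expect_identical(sample_ai_prediction(y, 1, 2), y)
  p <- sample_ai_prediction(y, 0.3, 2)
  expect_equal(mean(p == y), 0.3, tolerance = 4 * se_bin(0.3, 1e5) / 0.3)
})

test_that("fixed-trust resolution adopts only on conflict, at rate trust", {
  withr::local_seed(105)
  d2 <- rep(0L, 1e5)
  agree <- resolve_fixed(d2, d2, 0.9)
  expect_identical(agree$d_final, d2)
  expect_false(any(agree$adopted))
  p <- rep(1L, 1e5)
  never <- resolve_fixed(d2, p, 0)
  expect_identical(never$d_final, d2)
  some <- resolve_fixed(d2, p, 0.6)
  expect_equal(mean(some$adopted), 0.6, tolerance = 4 * se_bin(0.6, 1e5) / 0.6)
  expect_identical(some$d_final[some$adopted], p[some$adopted])
})

test_that("confidence draws are state-dependent clipped normals", {
  withr::local_seed(106)
  m0 <- ai_model(0.5, conf_sigma = 0)
  expect_equal(sample_confidence(rep(TRUE, 5), m0), rep(0.8, 5))
  m <- ai_model(0.5)
  kap <- sample_confidence(rep(TRUE, 1e5), m)
  expect_true(all(kap >= 0 & kap <= 1))
  # the clip shifts the mean below mu by ~6e-10 at (0.8, 0.1); the closed-form
  # clipped mean is the oracle, not mu itself
  expect_equal(mean(kap), clipped_normal_mean(0.8, 0.1),
               tolerance = 4 * 0.1 / sqrt(1e5) / 0.8)
  kw <- sample_confidence(rep(FALSE, 1e5), m)
  expect_equal(mean(kw), clipped_normal_mean(0.3, 0.1),
               tolerance = 4 * 0.1 / sqrt(1e5) / 0.3)
})

test_that("the sigmoid trust link hits its midpoint and printed values", {
  # midpoint: whenever trust x confidence = offset, effective trust is 1/2
  for (tk in list(c(0.5, 0.8), c(0.8, 0.5), c(0.4, 1.0))) {
    expect_equal(effective_trust(tk[1], tk[2]), 0.5)
  }
  expect_equal(effective_trust(0.9, 0.8), 1 / (1 + exp(-3.2)))
  expect_equal(effective_trust(0.9, 0.8), 0.9608343, tolerance = 1e-6)
  expect_equal(effective_trust(0.3, 1.0), 0.2689414, tolerance = 1e-6)
  expect_true(all(effective_trust(0.5, c(0, 1)) > 0 &
                    effective_trust(0.5, c(0, 1)) < 1))
})

test_that("conditional resolution adopts at the per-trial effective trust", {
  withr::local_seed(107)
  d2 <- rep(0L, 1e5)
  p <- rep(1L, 1e5)
  tau <- rep(0.9608343, 1e5)
  res <- resolve_conditional(d2, p, tau)
  expect_equal(mean(res$adopted), 0.9608343,
               tolerance = 4 * se_bin(0.9608, 1e5) / 0.9608)
  agree <- resolve_conditional(d2, d2, tau)
  expect_false(any(agree$adopted))
})

test_that("trial records satisfy their invariants in conditional mode", {
  res <- run_agent_trials(agent_profile(0.6, 0.6, 0.3), model = ai_model(0.6),
                          spec = task_spec(2, 5000), mode = "conditional",
                          seed = 9, keep_trials = TRUE)
  tr <- res$trials[[1]]
  expect_true(all(tr$d_final %in% 0:1 & tr$d1 %in% 0:1 & tr$d2 %in% 0:1))
  expect_true(all(tr$kappa >= 0 & tr$kappa <= 1))
  # adopted => conflict and final taken from the AI; else final = own decision
  expect_true(all(tr$p[tr$adopted] != tr$d2[tr$adopted]))
  expect_identical(tr$d_final[tr$adopted], tr$p[tr$adopted])
  expect_identical(tr$d_final[!tr$adopted], tr$d2[!tr$adopted])
  # low baseline trust bounds effective trust: t*kappa <= 0.3 => tau < 0.27
  expect_true(all(tr$tau <= 1 / (1 + exp(1))))
})

test_that("identical seed and config give identical trial logs", {
  args <- list(agent_profile(0.9, 0.3, 0.9), model = ai_model(0.7),
               spec = task_spec(3, 2000), mode = "conditional", seed = 31,
               keep_trials = TRUE)
  a <- do.call(run_agent_trials, args)
  b <- do.call(run_agent_trials, args)
  expect_identical(a$trials[[1]], b$trials[[1]])
  expect_identical(a$accuracy, b$accuracy)
})

test_that("zero trust reproduces the unassisted run trial for trial", {
  prof <- agent_profile(0.6, 0.9, 0)
  none <- run_agent_trials(prof, spec = task_spec(2, 5000), mode = "none",
                           seed = 17, keep_trials = TRUE)
  fixed <- run_agent_trials(prof, model = ai_model(0.9),
                            spec = task_spec(2, 5000), mode = "fixed",
                            seed = 17, keep_trials = TRUE)
  expect_identical(fixed$trials[[1]]$d_final, none$trials[[1]]$d_final)
  expect_identical(fixed$n_correct, none$n_correct)
})

test_that("a perfect, fully trusted AI yields perfect accuracy", {
  res <- run_agent_trials(agent_profile(0.3, 0.3, 1), model = ai_model(1),
                          spec = task_spec(2, 5000), mode = "fixed", seed = 3)
  expect_equal(res$accuracy, 1)
})

test_that("degenerate confidence makes conditional mode identical to fixed
           mode at the sigmoid-mapped trust", {
  # same agent_id on both sides so every substream is shared; the conditional
  # run's constant tau equals the fixed run's adoption probability exactly
  t0 <- 0.6; mu <- 0.7
  tau_star <- effective_trust(t0, mu)
  base <- tibble::tibble(agent_id = "shared", competence = 0.6,
                         certainty = 0.3, baseline_trust = t0)
  fixed_prof <- dplyr::mutate(base, baseline_trust = tau_star)
  cond <- run_agent_trials(base, ai_model(0.7, mu, mu, conf_sigma = 0),
                           spec = task_spec(2, 4000), mode = "conditional",
                           seed = 23, keep_trials = TRUE)
  fix <- run_agent_trials(fixed_prof, ai_model(0.7),
                          spec = task_spec(2, 4000), mode = "fixed",
                          seed = 23, keep_trials = TRUE)
  expect_identical(cond$trials[[1]]$d_final, fix$trials[[1]]$d_final)
  expect_equal(cond$trials[[1]]$tau, rep(tau_star, 4000))
})
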