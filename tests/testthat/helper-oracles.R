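# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (path enumeration, sample()-based simulators, manual
# quantile interpolation) and share no code with the package internals.

# expected unassisted accuracy by exhaustive enumeration of the four
# (primary right/wrong x kept/reversed) outcome paths
enum_baseline <- function(o, c, k) {
  p <- 0
  for (right in c(TRUE, FALSE)) {
    p_path <- if (right) o else 1 - o
    for (keep in c(TRUE, FALSE)) {
      p_branch <- p_path * (if (keep) c else 1 - c)
      p_correct <- if (keep) {
        as.numeric(right)
      } else {
        # reversal moves uniformly to one of the other k - 1 options
        if (right) 0 else 1 / (k - 1)
      }
      p <- p + p_branch * p_correct
    }
  }
  p
}

# naive trial-loop simulator of the assisted fixed-trust pipeline
mc_assisted_fixed <- function(o, c, t, alpha, k, n, seed) {
  set.seed(seed)
  correct <- logical(n)
  opts <- seq_len(k) - 1L
  for (i in seq_len(n)) {
    y <- sample(opts, 1)
    d1 <- if (runif(1) < o) y else sample(setdiff(opts, y), 1)
    d2 <- if (runif(1) < c) d1 else sample(setdiff(opts, d1), 1)
    p <- if (runif(1) < alpha) y else sample(setdiff(opts, y), 1)
    d_final <- if (p != d2 && runif(1) < t) p else d2
    correct[i] <- d_final == y
  }
  mean(correct)
}

# mean of a normal clipped (not truncated) to [0, 1], in closed form
clipped_normal_mean <- function(mu, sigma) {
  a <- (0 - mu) / sigma
  b <- (1 - mu) / sigma
  pnorm(b, lower.tail = FALSE) * 1 +
    mu * (pnorm(b) - pnorm(a)) - sigma * (dnorm(b) - dnorm(a))
}

# linear-interpolation quantile, written out by hand
brute_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
}

# build a pair_and_improve()-shaped tibble from given improvement values,
# for exercising the summarisers without a simulation run
fake_improvements <- function(rel, alpha = 0.5, mode = "fixed", k = 2L) {
  n <- length(rel)
  baseline <- rep(0.5, n)
  assisted <- baseline * (1 + rel / 100)
  tibble::tibble(
    agent_id = sprintf("agent%02d", seq_len(n)),
    competence = 0.5, certainty = 0.5, baseline_trust = 0.5,
    mode = mode, k = k, alpha = alpha, replicate = 1L, n_trials = 1000L,
    baseline_accuracy = baseline, assisted_accuracy = assisted,
    rel_improvement_pct = rel, improved = rel > 0,
    median_effective_trust = NA_real_
  )
}
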