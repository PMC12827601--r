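---
title: "Modelling trust-mediated human-AI decision making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trust-mediated human-AI decision making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustsim)
library(dplyr)
```

## The model

`trustsim` simulates a population of synthetic decision-makers ("agents")
solving repeated choice tasks with `k` options, alone or with an AI adviser.
Each trial is a two-stage probabilistic choice followed, when an adviser is
present, by a trust-gated conflict resolution:

1. **True label.** `y ~ Uniform{0, ..., k-1}`. Labels are i.i.d. uniform
   draws, not an exactly balanced sequence; every accuracy expectation in the
   package is label-symmetric, so the distinction is outcome-neutral.
2. **Primary decision.** The agent picks the true label with probability
   `o` (competence), otherwise one of the `k - 1` wrong options uniformly.
3. **Certainty stage.** With probability `c` (certainty) the primary decision
   is kept; otherwise the agent reverses, i.e. switches to one of the other
   `k - 1` options uniformly (for `k = 2`, the single alternative). The
   result is the post-uncertainty decision.
4. **AI prediction.** The adviser is correct with probability `alpha`, with
   errors uniform over wrong options — the same error model as the human.
5. **Conflict resolution.** Only when the AI's prediction differs from the
   post-uncertainty decision does the agent consider it, adopting it with a
   trust probability; agreement never triggers reconsideration or a second
   certainty pass, and at most one adoption draw happens per trial.

The adoption probability defines the three modes: `"none"` (no adviser),
`"fixed"` (the agent's constant baseline trust `t`), and `"conditional"`,
where the adviser also reports a confidence score
`kappa ~ N(mu, sigma)` clipped to `[0, 1]` — `mu = 0.8` when the prediction
is correct, `mu = 0.3` when it is wrong, `sigma = 0.1` — and effective trust
is the sigmoid

```
tau = plogis(steepness * (t * kappa - offset)),  steepness = 10, offset = 0.4.
```

The multiplicative-then-sigmoid form means a low-trust agent can never be
pushed far: with `t = 0.3`, `t * kappa <= 0.3 < offset`, so
`tau <= plogis(-1) ≈ 0.269` on every trial. Clipping is realised as
draw-then-clip (point masses at 0 and 1), not truncation with
renormalisation.

The canonical study population crosses the three traits — competence,
certainty, baseline trust — over `{0.3, 0.6, 0.9}`, giving 27 agent types
(`build_agent_grid()`, lexicographic, competence varying slowest), and the
adviser competence grid is `{0.3, ..., 0.9}` in steps of 0.1
(`build_alpha_grid()`). Defaults everywhere are 10,000 decisions per agent
per run.

## Closed-form expectations

Every simulated quantity has an analytic counterpart in the package, used
both as a verification oracle and as a fast calculator of who benefits from
an adviser.

* Unassisted accuracy: a kept correct primary decision stays correct and a
  reversed wrong one recovers the truth with probability `1 / (k - 1)`, so

  ```
  h = o * c + (1 - o) * (1 - c) / (k - 1).
  ```

  This reversal semantics (switch away from the current choice, uniform over
  the others) is the only reading consistent with the intended baselines: it
  gives `h(0.9, 0.9, 2) = 0.82` and `h(0.9, 0.3, 2) = 0.34`, whereas a
  uniform re-draw over all `k` options would give 0.86 and 0.62.
* Fixed trust: adopting on conflict repairs a wrong decision when the AI is
  right and spoils a right one when it is wrong, collapsing to
  `h + t * (alpha - h)`. Assistance helps exactly when `alpha > h`
  ("complementarity"), whatever the trust level.
* Conditional trust: with `Ec`/`Ew` the expected effective trust given a
  correct/wrong prediction,
  `h + alpha * (1 - h) * Ec - (1 - alpha) * h * Ew`. `Ec` and `Ew` are
  computed by adaptive quadrature of the sigmoid against the clipped normal —
  continuous density on `(0, 1)` plus the two boundary atoms, absolute error
  below `1e-6`; naive quadrature that ignores the atoms is wrong whenever
  `mu ± 4 sigma` crosses a bound.
* Relative improvement: `(assisted - h) / h * 100`, per agent, against the
  same agent's unassisted expectation. The denominator convention matters
  for mid-range summary cells and is fixed here once; `h = 0` (possible only
  off-grid, e.g. `o = 1, c = 0, k = 2`) is rejected as undefined.

`verify_oracle()` runs the full canonical design — 27 agents x {2, 3}
options unassisted, x 7 adviser levels fixed, x 7 levels conditional — and
reports each cell's discrepancy in binomial standard-error units; the test
suite asserts every cell within 4 SE at 10,000 trials.

## Randomness, pairing and determinism

All randomness flows from a single integer seed. Each sampling stage draws
from its own substream, seeded by hashing the key path
`(seed, agent, [adviser competence], replicate, stage)` into `[1, 2^31 - 2]`.
Two consequences are deliberate:

* Human stages (labels, primary, certainty) do not key on the mode or the
  adviser, so an agent faces the same task and makes the same unassisted
  decisions whether or not an adviser is present. A fixed-trust run with
  `t = 0` is therefore *trial-for-trial identical* to the unassisted run,
  and every baseline is paired with its assisted runs by common random
  numbers, which removes most of the Monte Carlo noise from the
  improvement ratio. We adopt common-random-number pairing as the only
  pairing scheme — an independently seeded baseline would break the `t = 0`
  identity that anchors the verification suite.
* Stage substreams consume a fixed number of draws per trial regardless of
  outcomes, so trial logs are byte-stable across runs and platforms with
  the same seed.

## Summaries

`run_scenario()` executes the factorial design and returns one tidy row per
(agent, adviser, replicate); `pair_and_improve()` joins each assisted run to
its replicate-matched baseline; `summarize_improvements()` reduces the 27
per-agent improvements to median (Q1, Q3) and the count of improving agents.
Two conventions are fixed here:

* Per-agent accuracies are averaged across replicates *before* the percent
  improvement and the cross-agent quantiles are computed, which keeps the
  27-value quantiles from being dominated by replicate noise.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), the most common default; e.g. the values
  `{1, 2, 3, 4}` give Q1 = 1.75, median = 2.5, Q3 = 3.25. Quartiles are more
  sensitive than medians to this choice, so it is worth stating.

`reproduce_table1()` assembles the three headline scenarios — fixed trust
with two options, fixed trust with three options, conditional trust with two
options — across the full adviser grid:

```{r table1, eval = FALSE}
tbl <- reproduce_table1(seed = 1, replicates = 10)
autoplot(tbl)
```

Expected qualitative behaviour, all of which the test suite asserts: under
fixed trust the binary median improvement is negative at adviser competence
0.3 (about -21% in expectation) and rises to about +49% at 0.9; in the
three-option task even mediocre advisers help (random guessing is weaker, so
`alpha > h` more often); under conditional trust the median at adviser
competence 0.3 is *positive* — confidence-conditioned reliance filters out
most wrong advice — and exceeds its fixed-trust counterpart.

## Problem sizes

The canonical run is 10,000 decisions per agent per condition; summary
reproductions average 10 replicate runs, so each of the 27 x 7 cells rests
on 100,000 decisions plus paired baselines. The verification suite covers
621 cells at 10,000 trials each. At these sizes the whole test suite and a
full acceptance recomputation each run in about a minute on a single core;
per-trial logs (`keep_trials = TRUE`) are kept optional because they raise
memory by three orders of magnitude.

## What the generator does and does not emulate

The simulation isolates trait-level interactions in a deliberately abstract
task: i.i.d. trials, fixed traits, a well-calibrated adviser whose
confidence distribution depends only on correctness. Passing tests show the
engine matches its own stated mechanics, not that real clinicians behave
like the agents. Known departures from real decision-making, intentionally
out of scope: trust does not update across trials (no learning, decay or
asymmetric updating); adviser confidence is never miscalibrated beyond the
two fixed normals; decisions are single events, not sequential chains;
traits do not drift with context or fatigue. Extensions would slot into
`resolve_*`/`sample_confidence` without touching the oracles' structure, but
the closed forms above would no longer apply unchanged.
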