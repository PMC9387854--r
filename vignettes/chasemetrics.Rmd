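---
title: "Measuring within-session chasing in round-level gambling logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring within-session chasing in round-level gambling logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasemetrics)
library(data.table)
```

## The problem

Loss-chasing — continuing or intensifying gambling to recoup losses — is a
core marker of problem gambling, but within a single session it can show up
in at least three distinct behaviors: *when a player stops*, *how the stake
changes*, and *how fast the next action is initiated* after a win versus a
loss. `chasemetrics` implements the full analysis chain for round-level
player-tracking logs of a fast online dice game (a Mystery-Arena-style
product): each round the player stakes one of ten ladder amounts, places 12
dealt columns of 3 dice into 4 slots, and wins when matched lines bring the
round to at least 100 points.

Because operators do not release round-level data, the package pairs the
analysis chain with a generative simulator: a game engine that reproduces
the round mechanics, and a cohort simulator whose latent per-player
parameters (stop hazards, stake policy, response-time model) leave exactly
the footprints the three indicators are designed to detect. Every stage of
the pipeline can therefore be tested against known ground truth.

## The three indicators

For one player, with a round classified as a **win** iff its recorded win
amount is positive, and a round counting as a **stop** iff it is the last
round of its session:

* **Stopping.** $p(\mathrm{stop}\mid\mathrm{win})$ and
  $p(\mathrm{stop}\mid\mathrm{loss})$ are each divided by the player's
  overall stop probability $p(\mathrm{stop})$, giving *relative
  likelihoods* $rl_{\mathrm{win}}, rl_{\mathrm{loss}}$ that control for
  session length. The identity
  $(n_w\,rl_w + n_l\,rl_l)/(n_w+n_l) = 1$ is the algebraic fingerprint of
  this normalization and is enforced in the test suite to $10^{-12}$.
  Players need at least 5 wins and 5 losses to be included.
* **Staking.** For every round with a predecessor in the same session, the
  signed stake change in euro cents (stored exactly as integers) is
  attributed to the previous round's outcome; the probability of any
  change and the mean signed change are summarized per prior outcome.
  First rounds of sessions are excluded; inclusion needs at least 5
  retained rounds per prior outcome.
* **Speed.** The first-column response time (from starting a round to
  placing its first column — the only latency not confounded by win/loss
  feedback) is filtered (first round of session; RT strictly above
  5000 ms), z-standardized within the player over all retained rounds, and
  averaged by prior outcome. $rt_{\mathrm{diff}} = \bar z_{\mathrm{loss}} -
  \bar z_{\mathrm{win}} < 0$ is post-loss speeding. Zero-variance players
  are excluded with a warning (their z-scores are undefined).

The overall stop probability is computed over *all* rounds, before any
facet-specific exclusion; the source analyses do not state the order and
this choice is the simpler one.

## The statistical battery

Each facet table (per-player after-loss and after-win values, with the
involvement group) is analyzed exactly the way operator cohorts are
reported:

* a 2×2 mixed ANOVA (prior outcome within-subjects × involvement group
  between-subjects) with **Type III** sums of squares — the groups are
  heavily unbalanced in real cohorts — and generalized eta squared with
  *both* error strata (subjects and residual) in the denominator;
* five pairwise comparisons: paired t within each group, Welch t between
  groups on each condition and on the loss-minus-win difference scores;
* Holm–Bonferroni adjustment over each facet's 5-comparison family (the
  family boundary is not stated in the source analyses; per-facet is the
  natural reading of per-table correction);
* JZS Bayes factors (Cauchy prior on the standardized effect, scale
  0.707), reported as natural logs. The marginal likelihood is evaluated
  by adaptive quadrature on the log scale, split at the peak
  $\delta = t/\sqrt{n}$, so $t$-values in the tens do not underflow. For
  two-sample rows the Bayes factor uses the classical pooled-variance $t$
  on $n_1+n_2-2$ df with effective sample size $n_1 n_2/(n_1+n_2)$, the
  standard JZS form (the frequentist columns still report Welch).
* Hedges' *g* with the exact gamma-function small-sample correction:
  pooled-sd standardization between subjects, and the "average g"
  (mean difference over the average of the two condition sds) within
  subjects;
* within-subject 95% CIs: subject-centered values with the $J/(J-1)$
  variance inflation ($J = 2$). For two conditions the half-width equals
  $t_{.975,n-1}\,\mathrm{sd}(d)/\sqrt{2n}$, which the tests assert.

With a single two-level between factor, Type III and sequential sums of
squares coincide for the group effect; they differ for the within-subject
main effect under unbalance, where Type III tests the unweighted mean of
the two groups' loss−win differences (some toolchains use the weighted
mean instead — the choice is visible only in unbalanced cohorts and is
documented here deliberately).

## The simulated world

`sim_config()` fixes a "stated world" whose defaults mirror the
qualitative contrasts of real involvement groups at desk scale (hundreds,
not millions, of rounds):

| parameter | low group | high group | what it encodes |
|---|---|---|---|
| sessions per player | 1 + Pois(5) | 1 + Pois(7) | more sessions when highly involved |
| stop hazard after win / loss | .010 / .030 | .008 / .022 | win-chasing in stopping; longer sessions in the high group |
| stake-change prob. after win / loss | .03 / .06 | same | lose-shift in change probability |
| P(step up given change) after win / loss | .85 / .30 | same | net stake increase after wins |
| baseline log RT | log 900 ms ± .15 | log 700 ms ± .15 | high group plays faster |
| post-loss RT shift δ (log scale) | −.25 ± .05 | −.10 ± .05 | post-loss speeding, attenuated in the high group |
| in-session break prob. | .01 | .01 | breaks that the 10-minute resegmentation should find |

Stopping is modeled as outcome-conditional Bernoulli hazards rather than
bankroll depletion, because account balances are unobservable in tracking
data; an optional finite per-session bankroll (`bankroll_eur`) forces
stops when funds cannot cover the next stake, so the forced-stop
hypothesis can be probed even though observational data cannot arbitrate
it. RTs are lognormal with an additive log-scale post-loss shift — the
z-scoring pipeline is scale-free, so this distributional choice is not
load-bearing. Sessions are truncated at 1000 rounds as a runtime guard.

The group contrast in δ is deliberately clearer than the small effects
published for real cohorts: the recovery criterion demands the full
qualitative pattern (win-chasing in stopping and staking, post-loss
speeding attenuated in the high group) in ≥90% of replicates at 300
players per group, which a g ≈ 0.15 group difference could not deliver at
that size. The simulator is a power tool for validating the pipeline, not
a calibrated model of any operator's population.

### The invented game economy

The published rules fix the structure (10 equiprobable faces, one of them
a bonus face; line scoring on 3 rows and 2 diagonals; ×1.5 with 3 winning
slots, ×2 with 4; +200 points for nine identical dice; stakes on a
10-level ladder from €0.25 to €20; wins at ≥100 points) but not the
numbers. The defaults — face values {5, 10, 15, 20, 25, 30, 40, 50, 100},
ladder {0.25, 0.50, 0.75, 1, 1.50, 2, 3, 5, 10, 20} €, prize = points/100
× stake, a fixed 150 points from the bonus mini-game, the 200-point bonus
added *after* the multiplier — are invented and configurable
(`point_table()`, `stake_schedule()`, JSON via `read_game_config()`).
Under these defaults and random column placement the engine yields
P(win) ≈ 3.9% and a bonus-trigger rate ≈ 1.9% per round (the real product
logged 1.47%; the rate is documented, not calibrated, since the real
placement-policy mix is unknown). Points per matching line equal the
repeated face's value — the simplest reading of "corresponding points".

A consequence of i.i.d. uniform faces worth noting: any placement policy
that never *reads* future columns leaves the score distribution unchanged,
and the immediate-gain greedy policy (ties to the lowest slot index)
degenerates to filling slots left to right when starting from an empty
board — lines can only complete on a slot's third column. The greedy
policy therefore only matters from non-empty partial states
(`place_column()`), and the skill component of the real game is *not*
reproduced; this is a documented non-goal.

## Numerical choices and edge cases

* Money is held as integer euro cents end to end; CSVs carry euros with
  two decimals and amounts that are not whole cents are rejected at
  parse time (naming row and column).
* The prize conversion itself is exact (linear in the stake at fixed
  points); the simulator rounds only the *recorded* win amount to whole
  cents.
* The 10-minute break rule splits a session strictly above 600,000 ms of
  start latency, never merges operator sessions, recomputes 1-based round
  indices, and is idempotent. Rounds with missing latency are flagged and
  left unsplit.
* The 5000 ms RT rule is strict (`> 5000` excluded) and applied *before*
  z-standardization. Bonus-game rounds are retained in all facets.
* Paired comparisons require at least 3 players per group (the Hedges
  correction needs df > 1); smaller analysis sets return a structured
  "no result" rather than an error.
* Whether the operator's latency clock pauses during connection loss is
  unknowable from the logs; treat extreme start latencies as a data
  caveat, not a measurement.

## What a green test establishes — and what it does not

The simulator emulates outcome-dependent stopping, staking and speed with
independent rounds and stationary per-player parameters. Real play has
features the generator deliberately omits: learning and drift within
sessions, autocorrelated response times, bankroll dynamics coupled across
sessions, device and input-method effects, and whatever the operator's
proprietary involvement algorithm actually conditions on (group labels
here are generating-model truth, not re-derived behavior). A green
recovery criterion therefore establishes that *the pipeline detects the
effects it claims to measure when they are present and calibrates
correctly when they are absent* — it does not establish that any real
cohort shows those effects, and between-session chasing is out of scope
entirely.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(mode = "full", out_dir = "run1",
                  sim = sim_config(n_players = c(high = 50, low = 50),
                                   seed = 42))
res <- run_full(cfg)
res$batteries$speed$comparisons[, .(comparison, diff, t, p_holm, ln_bf, g)]
plot(res$batteries$speed, main = "speed of play (RT z)")
```

The `run1/` directory then holds the tracking and ground-truth CSVs, the
per-facet metric tables, `battery_comparisons.csv` and a markdown report
mirroring the table layout used for operator cohorts, each stamped with
the seed and a hash of the effective configuration.
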