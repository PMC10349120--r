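---
title: "Beta-belief learning and hidden-state inference: models, simulation and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-belief learning and hidden-state inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betastate)
```

## The scientific problem

In Pavlovian aversive reversal learning, a cue predicts a painful outcome
with a probability that occasionally flips between a high and a low level.
A participant who rates the shock probability on every trial can track such
an environment in two qualitatively different ways: by *gradually* updating
a single running estimate, or by *inferring hidden states* — internal
contexts such as "high threat" and "low threat" — and switching between
them when the evidence demands it. The second strategy produces abrupt
jumps in ratings after contingency reversals and discounts surprising
outcomes during stable stretches (oddballs). `betastate` implements both
strategies as generative models over beta-distributed beliefs, fits them to
trial-wise rating data by maximum likelihood, and provides everything
needed to study the question end-to-end on synthetic cohorts: a constrained
task-schedule generator, model-free behavioural markers, a rating-producing
agent simulator with a trait-anxiety covariate, and model/parameter
recovery tooling.

## The one-state learner

A belief about the shock probability is a beta distribution with shape
parameters $\alpha$ (shock pseudo-counts) and $\beta$ (no-shock
pseudo-counts). The reported probability is the mode,

$$\hat P = \frac{\alpha - 1}{\alpha + \beta - 2},$$

and the state uncertainty is the distribution's standard deviation
$\sigma$. After a shock, $\alpha$ grows by the step size $\tau^{+}$; after
an omission, $\beta$ grows by $\tau^{-}$; on every trial both parameters
decay multiplicatively by $\lambda$, which implements forgetting and keeps
uncertainty from vanishing. Both parameters are floored at 1 — below 1 the
density becomes bimodal and the mode stops being meaningful — and their sum
is capped at 30 by proportional rescaling, which bounds how certain the
learner can ever become. The flat belief $\alpha=\beta=1$ reports 0.5 by
convention.

Two numerical details are worth stating explicitly. First, the floor is
applied before the cap; if the rescaling pushes the un-incremented
parameter below 1 (possible when one parameter sits at the floor while the
other is near the cap), the pair is projected to the nearest point
satisfying both constraints ($1$ and $\mathrm{cap}-1$). Second, the
reported $\hat P$ in traces is clipped into $[\epsilon, 1-\epsilon]$ with
$\epsilon = 0.005$, the same constant used to clip observed ratings before
likelihood evaluation.

Free parameters and their ranges: $\tau^{+}, \tau^{-} \in [0,2]$,
$\lambda \in (0,1)$ (estimated in log space), starting values
$\alpha_0, \beta_0 \in [1,10]$.

## The n-state learner

The n-state model runs the same belief updates but maintains a *set* of
states, exactly one of which is active; inactive states only decay. Each
state carries a running surprise

$$S_t = (1-\pi)\,S_{t-1} + \pi\,\lvert O_t - \hat P_t \rvert,$$

an exponentially smoothed absolute prediction error, bounded in $[0,1]$.
The smoothing weight is fixed at $\pi = 0.3$: mid-range smoothing (roughly
a three-trial memory), and fixing it keeps the n-state model at a single
extra free parameter, the threshold $\eta$, so that model comparison
penalises exactly one degree of freedom.

After each update the active state's surprise is compared against two
thresholds built from its pre-update uncertainty:

* **basic threshold** $\sigma\eta$ — crossing it triggers *polling*: the
  model forms an expected value
  $E = \mathrm{clip}(\hat P + \mathrm{sign}(O - \hat P)\,S)$, looks for
  existing states whose mode lies within $E \pm \sigma\eta$, and activates
  the one with maximal beta density at $E$ (ties broken by recency). If no
  candidate exists the current state is kept.
* **compound threshold** $\sigma\eta\,q$ — crossing it additionally
  licenses *creation*: if polling finds no candidate, a new state is
  created with mode $E$ and the starting uncertainty
  $\sigma(\alpha_0,\beta_0)$ (solved for $(\alpha,\beta)$ by bisection on
  the mode-parameterised concentration), and its surprise starts at 0.

Design choices where the construction was genuinely open, and why:

* *Direction of the expected value.* $E$ moves from $\hat P$ toward the
  surprising outcome, i.e. by $\mathrm{sign}(O_t - \hat P_t)\,S$; surprise
  should shift expectation toward what was just observed.
* *Surprise bookkeeping is per state* (each state keeps its own
  accumulator, frozen while inactive; new states start at 0), matching the
  per-state subscripting of the smoothing recursion.
* *The eligibility window uses the current state's* $\sigma$, not the
  candidate's: the question "is this value compatible with an existing
  state?" is asked at the resolution of the state currently doing the
  predicting.
* *New states match the mode, not the mean, to* $E$: beliefs are reported
  via the mode throughout, so initialising the mean would make a freshly
  created state report a value different from the one that triggered its
  creation.
* *Decay is applied after the step-size increment* for the active state,
  following the order in which the update equations compose.

### The difficulty of creating additional states

Creating each further state should be progressively harder, so the
compound threshold carries a multiplier $q$ derived from a Chinese
restaurant process. A two-parameter seating rule with $\theta = 0.25$ and
discount $\alpha = 1$ degenerates: every occupied table has weight
$n_s - \alpha = 0$ for singletons, so every customer opens a new table and
the "difficulty" never grows. The package therefore builds the mapping by
Monte-Carlo simulation of the one-parameter CRP with concentration
$\theta = 0.25$: seating sequences of
the session length are simulated 10,000 times, the per-step probability of
opening a new table is averaged conditional on the current table count
$K$, and

$$q(K) = \bar P_{\mathrm{new}}(1) / \bar P_{\mathrm{new}}(K),$$

clipped below at 1 and made non-decreasing. Because later customers face
lower new-table probabilities, $q$ grows with $K$ (typically
$q(2) \approx 2$, $q(3) \approx 3$ at session lengths around 150). The
multiplier is indexed by the *prospective* state count — creating the
$(K{+}1)$-th state uses $q(K{+}1)$ — so $q(1) = 1$ is the normalisation
anchor and difficulty accrues from the first creation onward. The mapping
is pluggable (`q_map` in `crp_difficulty()`, `q_table` in the simulation
and fitting entry points) and the table is computed once per model run.
$\alpha$ is retained in `model_constants()` as a record of the
two-parameter form but is unused by the default mapping.

With $\eta \ge 10^6$ the thresholds are never crossed and the n-state
model reproduces the one-state trace to machine precision; the one-state
model is in fact implemented as the n-state step with thresholds disabled,
so the nesting is structural, not approximate.

### How threshold magnitude translates into behaviour

On 90/10-style schedules with $\lambda \approx 0.95$, uncertainty at the
evidence cap is $\sigma \approx 0.09$, post-reversal surprise climbs to
0.4–0.6 within a few trials, and oddball-driven surprise stays near the
long-run mean absolute error. In that regime $\eta \in [1, 3]$ yields
prompt state creation after the first reversal and switching (not
re-creation) at later reversals; $\eta \lesssim 1$ fragments the
environment into many states; and $\eta \gtrsim 3$–5 never crosses the
thresholds, so the learner behaves gradually. Note that a stable 90%
stream will occasionally produce clustered omissions whose surprise spike
crosses moderate thresholds — spurious-looking creations on long
single-contingency runs are a property of the surprise formulation, not a
bug; only conservative thresholds ($\eta \approx 5$ at these settings)
never fragment.

## Likelihood and fitting

Ratings live on $[0,1]$ (serialised on the task's 0–100 scale) and are
clipped to $[0.005, 0.995]$. The likelihood of a rating on trial $t$ is
the beta density of the active state's belief *before* that trial's
outcome; the negative log-likelihood sums over rated trials, skipping
missing ones. BIC is $k\ln n + 2\,\mathrm{nll}$ with $n$ the number of
rated trials and $k = 5$ (one-state) or $6$ (n-state);
$\Delta\mathrm{BIC} = \mathrm{BIC}_{1} - \mathrm{BIC}_{n} > 0$ favours
state inference, and exact ties go to the simpler model.

`fit_beta_learner()` maximises the likelihood with multi-start
Nelder-Mead on a logistic reparameterisation of the box bounds
($\lambda$ and $\eta$ squashed on the log scale), followed by a fresh
simplex restart from each solution — Nelder-Mead simplices collapse easily
on this surface. The n-state likelihood is *rugged*: switch and creation
times are discrete functions of the parameters, so the basin around a
switching solution can be narrow, and a fully uniform multistart may never
land in it. Every other restart therefore draws the decay from
$[0.88, 0.9995]$ and the threshold log-uniformly from $[0.4, 5]$ — the
ranges in which the learners express distinct dynamics — while the
remaining restarts cover the full bounds. The default protocol is 45
restarts; the recovery studies scale this to 15, which the model-recovery
results below show is sufficient at their problem sizes.
`fit_both_models()` additionally seeds one n-state restart at the
one-state optimum with $\eta$ at its upper bound, which guarantees that
the nested model's likelihood is attainable and makes the likelihood
dominance of the larger model structural.

The fitted object is a standard S3 model: `print`, `summary`, `coef`,
`logLik` (hence `stats::BIC`), `predict` (optionally on new outcome
sequences), `fitted`, `residuals`, `simulate` (mode-parameterised beta
response noise) and `plot`.

```{r example-fit}
sched <- assemble_schedule(session_spec("90/10", "III"), seed = 11)
agent <- agent_spec("demo", "switching",
                    learner_params(1.13, 0.73, 0.95, 2, 2, eta = 2),
                    noise_kappa = 200, seed = 12)
trials <- simulate_agent(agent, sched, cues = "reversal")
rev <- trials[trials$cue == "reversal", ]
fits <- fit_both_models(rev$outcome, rev$rating, n_restarts = 10, seed = 13)
fits$comparison
```

## The task-schedule generator

A session consists of 6–10 phases; within a phase the reversal cue's shock
probability is constant and the two stable cues keep their fixed
probabilities. Phase length is drawn as a mean with uniform integer jitter
(styles I/II/III use 30±2, 30±5, 35±10 total trials with cue proportions
30/30/40, 25/25/50, 20/20/60); trials are apportioned to cues by
largest-remainder rounding, which preserves the proportions without bias.
Constraint satisfaction is by rejection sampling with a retry budget,
matching a generate-and-check design: cue order is reshuffled until no cue
occupies more than three consecutive trials, and outcomes are redrawn until
each cue's realised shock rate falls within ±5 percentage points of its
target and — after a contingency flip — at least three of the first five
reversal-cue outcomes point in the new direction. Phase boundaries flip the
reversal contingency with probability 0.75 (styles I/II) or always (style
III); a boundary that does not flip redraws a phase with the same
contingency. A second ±5-point check runs across the whole session per
cue, with the reversal cue's target mixing the high- and low-phase targets
by exposure.

One tolerance detail: for small per-cue trial counts the ±5-point window
can contain *no* integer shock count (five stable-cue trials at a 0.9
target admit only rates 0.8 or 1.0). The generator and the validator both
use the window "±5 points, widened to the nearest integer-achievable
rate", so the constraint degrades gracefully instead of deadlocking; with
the 14–16-of-20 style counts of larger phases the literal window applies
unchanged. `validate_schedule()` reports each named check (per-phase rate,
session rate, run length, first-five rule, phase count) and never raises,
so constructed violations can be examined.

## Synthetic agents and cohorts

`simulate_agent()` runs the agent's forward model separately per cue (each
cue's contingency is learned with its own state system) and draws each
rating from a beta distribution with mode at the model's prediction and
concentration $\kappa$ (`a = 1 + m\kappa`, `b = 1 + (1-m)\kappa`), clipped
like all probabilities; an option rounds to the task's 1% slider grid
(off by default so that fitting tests are not quantised). The default
$\kappa = 200$ corresponds to a rating SD of roughly 0.02–0.035 —
deliberate, low-noise reporting.

`simulate_cohort()` adds the population layer: trait anxiety drawn from a
truncated normal (mean 39, SD 10, bounds [20, 71], matching the reported
questionnaire median and range), strategy assigned by a logistic effect
map in TA, and generating parameters drawn per strategy from
`default_param_summary()`: step-size means 1.17/0.86 (gradual) and
1.13/0.73 (switching) follow the magnitudes reported for fitted human
data; $\lambda \sim N(0.95, 0.03)$, $\alpha_0, \beta_0 \sim N(2, 1)$
truncated to bounds, and $\eta \sim N(2, 0.5)$ truncated to $[1, 3]$ are
package choices — the $\eta$ truncation confines "switching" agents to the
regime where the label describes their behaviour (see above). Ground truth
is stored alongside the trials, and all randomness descends from the
cohort seed, so tables reproduce exactly.

What the generator deliberately does **not** emulate: human rating noise
of unknown shape (the beta noise model is an assumption, and real
rating-to-belief mappings may be miscalibrated), slider anchoring and
motor effects, missing responses, attention lapses, physiological
channels, and any within-subject session-order or habituation effects.
Passing recovery tests on these agents therefore demonstrates that the
*pipeline* is correct and the models identifiable under their own
assumptions — not that human data will be as well-behaved.

## Model-free markers

All markers operate on the reversal cue and on *behavioural phases*:
consecutive schedule phases with the same contingency (possible when the
flip probability is below 1) are merged, because an unflipped boundary is
invisible to the participant. Positions within a phase count reversal-cue
presentations, consistent with fitting being cue-specific.

* **Trial-wise learning rates** invert the delta rule,
  $\alpha_t = (P_{t+1} - P_t)/(O_t - P_t)$; values outside $[0,1]$ are
  excluded (e.g. lowering the expectation after a shock), and
  zero-denominator cases are flagged separately. The first five
  presentations after a reversal are *meaningful*, later ones *oddball*
  (cutoffs 7, 10, 13 support the sensitivity analysis); the first phase is
  unlabeled. Log transforms use the natural log of rates clipped below at
  $10^{-3}$.
* **Post-reversal slopes** are ordinary least-squares slopes of ratings
  (0–100 scale) on presentations 1–10 of each post-reversal phase,
  aggregated per switch direction; at least three rated points are
  required. Per-subject slopes are the unit of analysis here — the mixed
  model machinery used for group inference on real cohorts is out of scope
  by design.
* **Stable-window means** average ratings from presentation 10 until the
  next reversal, split by phase type.
* **Reinforcement error** subtracts the running mean of delivered outcomes
  (the best estimate of the true rate available to an agent that knows its
  state) from the rating; positive errors are overestimation.

## Recovery, correlations and power

`model_recovery()` simulates agents from each generating model with
parameters drawn from the documented summary, fits both candidates with
the identical protocol, and tabulates BIC winners in a confusion matrix;
with 30 agents per generator, 15 restarts and $\kappa = 200$ on 90/10
schedules, the generating model wins in 100% (gradual) and roughly 85–95%
(switching) of agents. Misclassified switching agents are almost always
those whose drawn threshold sits near the top of its range, where the
strategies genuinely converge.

`parameter_recovery()` sweeps one-state truths uniformly over the
estimable interior ($\tau \in [0.2, 1.9]$, $\lambda \in [0.9, 0.99]$,
$\alpha_0, \beta_0 \in [1, 4]$) and refits; with 40 agents and ~300 rated
trials the step-size truth-estimate correlations land around 0.7–0.8. Two
properties of this estimator deserve honest emphasis. First, because the
likelihood is the *belief* density (SD $\geq$ ~0.05 at the evidence cap)
while $\kappa = 200$ ratings are much tighter, the model is misspecified
as a noise model for its own simulations; maximum likelihood responds by
inflating step sizes toward the upper bound to sharpen the belief, so raw
$\tau$ estimates are biased upward and correlations, not intercepts, are
the meaningful recovery metric. Second, that same bias compresses
estimates when truths cluster tightly (restriction of range): recovery
correlations measured on cohort-default truths are substantially lower
than on the full sweep. The sweep is the conventional design for a
parameter-recovery study and is what the package reports.

`correlate()` provides Pearson and Spearman estimates with percentile
bootstrap CIs (2000 case resamples by default) and an optional permutation
p-value; session-wise p-values in `run_full_analysis()` are
Bonferroni-corrected across the three sessions.
`required_n_correlation()` implements the Fisher-z sample-size formula
$n = \lceil ((z_{1-\alpha/2} + z_{\mathrm{power}})/\operatorname{atanh} r)^2 + 3 \rceil$;
detecting $r = 0.5$ at 0.8 power under the three-session-corrected
$\alpha = 0.0167$ requires 38 participants. `split_half_check()` fits on
the first half of each session, computes markers on the second half, and
correlates the out-of-sample quantities, flagging sessions whose halves do
not both contain two behavioural phases.

`run_full_analysis()` chains the stages (simulate or ingest → fit →
markers → correlations → optional recovery), derives every stage seed from
the config seed, and writes CSV/JSON artifacts that reproduce
byte-for-byte under a fixed config.

## Problem sizes and numerical choices, in one place

Test-suite problem sizes (the package's own choices for routine
verification): nesting checked on 50 parameter sets × 50 sequences of 100
trials at $10^{-12}$; brute-force oracles on 100 random fixtures at
$10^{-9}$; 1000 schedules per contingency condition through the validator
and 2000 boundaries for the flip rate; recovery at 30 agents per generator
with 15 restarts; the parameter sweep at 40 agents with the 45-restart
protocol; marker contrasts over 20 replicate cohorts of 6 matched pairs.
Fixed numerical constants: probability clip $\epsilon = 0.005$; evidence
cap 30; learning-rate log floor $10^{-3}$; CRP table from 10,000
iterations, 12 tabulated counts; bisection with 100 fixed iterations;
Nelder-Mead with `maxit = 400`, `reltol = 1e-8`, one simplex restart.

## Known limitations

The difficulty construction resolves a degenerate two-parameter seating
rule by one defensible reading; others (e.g. Pitman–Yor with a valid discount)
would change how steeply creation difficulty grows. Switching and creation
share a single threshold scaled by $q$; environments that dissociate
switching from creation would need separate thresholds. The beta response
noise and the logistic trait-anxiety effect map are artifact assumptions.
Raw step-size estimates are boundary-biased under low-noise ratings, as
discussed above. Group-level inference (mixed models, post-hoc contrasts,
effect sizes) on real cohorts is intentionally out of scope; the package
exposes per-subject summaries and simple correlation machinery instead.
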