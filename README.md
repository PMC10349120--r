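# betastate

Computational modelling of Pavlovian aversive reversal learning: do people
track a changing shock probability by **gradual updating**, or by
**inferring hidden states** (contexts of high vs low threat) and switching
between them? `betastate` is an R package for researchers in computational
psychiatry and learning who want to simulate, fit and compare the two
accounts on trial-wise probability-rating data — including fully synthetic
cohorts with a trait-anxiety covariate, so every stage of the analysis is
testable without any participant data.

## The models

A belief about the shock probability is a beta distribution
Beta(&alpha;, &beta;). The reported probability is its mode and the state
uncertainty its standard deviation:

```
P̂ = (α − 1) / (α + β − 2),      σ = sqrt(αβ / ((α + β)² (α + β + 1)))
```

**One-state learner** (gradual): after a shock, α ← λ(α + τ⁺); after an
omission, β ← λ(β + τ⁻); otherwise both parameters decay by λ
(forgetting). Parameters are floored at 1 (unimodality) and α + β is
capped at 30. Free parameters: τ⁺, τ⁻ ∈ [0,2]; λ ∈ (0,1) (log space);
α₀, β₀ ∈ [1,10].

**n-state learner** (hidden-state inference): the same updates run on a
set of states, one active at a time, each tracking a smoothed surprise
S ← (1−π)S + π|O − P̂| with π = 0.3 fixed. If S exceeds the basic
threshold σ·η the model polls existing states around the expected value
E = P̂ ± S and switches to the most likely candidate; if S also exceeds
the compound threshold σ·η·q and no candidate exists, a new state is
created at E. The difficulty q grows with the number of states via a
Chinese-restaurant-process construction, so each additional state is
harder to create. One extra free parameter: the threshold η.

Fitting is maximum likelihood under the beta likelihood of the belief,
with multi-start Nelder–Mead (45 restarts by default) and BIC comparison;
ΔBIC = BIC₁ − BICₙ > 0 favours state inference.

## Worked example

Generate a 90/10 session, simulate a state-inferring agent, fit both
models and compute the behavioural markers:

```r
library(betastate)

sched <- assemble_schedule(session_spec("90/10", "III"), seed = 11)
sched
#> Reversal schedule (90/10, style III): 253 trials, 7 phases, 6 flips
#> realized shock rates: reversal 0.54, stable_high 0.88, stable_low 0.12

agent  <- agent_spec("demo", "switching",
                     learner_params(1.13, 0.73, 0.95, 2, 2, eta = 2),
                     noise_kappa = 200, seed = 12)
trials <- simulate_agent(agent, sched, cues = "reversal")
rev    <- trials[trials$cue == "reversal", ]

fits <- fit_both_models(rev$outcome, rev$rating, n_restarts = 10, seed = 13)
fits$comparison
#> BIC one-state -254.27 vs n-state -341.76: delta = +87.49 -> n_state

compute_markers(trials)[, c("slope_lh", "slope_hl", "lr_meaningful",
                            "lr_oddball")]
#>   slope_lh slope_hl lr_meaningful lr_oddball
#> 1        9   -6.314         0.322       0.27
```

The ΔBIC of +87 says the rating sequence is far better explained by state
switching than by gradual updating, as it should be for this agent. The
markers tell the same story model-free: ratings climb ~9 points per trial
after low→high reversals (and fall ~6 after high→low), and learning is
faster on the five post-reversal trials (meaningful, α ≈ 0.32) than during
stable periods (oddball, α ≈ 0.27). `plot(fits$n_state)` overlays the
fitted prediction and switch events on the ratings.

Cohort-level analysis, recovery and power:

```r
res <- run_full_analysis(list(
  cohort = list(n_agents = 20, sessions = c("60/40", "90/10"),
                effect_map = list(ta_weight = 0.15)),
  fit = list(n_restarts = 15), seed = 1), out_dir = "out")

model_recovery(n_agents = 30, n_restarts = 15, seed = 1)
parameter_recovery(n_agents = 40, seed = 1)
required_n_correlation(0.5, 0.8, 0.0167)
#> [1] 38
```

The last line is the study-design power calculation: detecting a
correlation of 0.5 at 0.8 power under the session-corrected two-tailed
alpha requires 38 participants.

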