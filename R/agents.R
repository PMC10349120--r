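#' Agent specification
#'
#' A synthetic rating-producing agent: its learning strategy (`"gradual"` =
#' one-state forward model, `"switching"` = n-state), its learner
#' parameters, a trait-anxiety score emulating the STAI-trait range, and the
#' concentration of its beta response noise.
#'
#' @param agent_id Identifier.
#' @param strategy `"gradual"` or `"switching"`.
#' @param params A [learner_params()] set (must carry `eta` for switching
#'   agents).
#' @param ta_score Trait-anxiety scalar in \[20, 80\].
#' @param noise_kappa Response-noise concentration (> 0); ratings are drawn
#'   from a beta distribution with mode at the model prediction and
#'   concentration `noise_kappa`.
#' @param seed Optional per-agent seed.
#' @return A list of class `"agent_spec"`.
#' @export
agent_spec <- function(agent_id, strategy = c("gradual", "switching"),
                       params = learner_params(), ta_score = 39,
                       noise_kappa = 200, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(ta_score >= 20, ta_score <= 80, noise_kappa > 0)
  if (strategy == "switching" && is.null(params$eta))
    stop("switching agents need params$eta")
  structure(list(agent_id = agent_id, strategy = strategy, params = params,
                 ta_score = ta_score, noise_kappa = noise_kappa,
                 seed = seed),
            class = "agent_spec")
}

#' Simulate an agent's ratings on a schedule
#'
#' Runs the agent's forward model separately for each cue (the agent learns
#' each cue's contingency with its own state system) and draws a rating for
#' every trial from a beta distribution with mode at the model's trial-wise
#' prediction and concentration `noise_kappa`, clipped to
#' \[0.005, 0.995\]. Deterministic under the agent's seed.
#'
#' @param agent An [agent_spec()].
#' @param sched A `"reversal_schedule"`.
#' @param cues Which cues receive ratings (default: all three).
#' @param round_to_grid Round ratings to the task's 1% response grid?
#' @param constants Fixed constants.
#' @return The schedule's trial table with added `rating` (in \[0, 1\];
#'   `NA` on unrated cues), `agent_id`, `session`, `ta_score`.
#' @export
simulate_agent <- function(agent, sched,
                           cues = c("stable_low", "stable_high", "reversal"),
                           round_to_grid = FALSE,
                           constants = model_constants()) {
  tt <- sched$trials
  model <- if (agent$strategy == "switching") "n_state" else "one_state"
  eps <- constants$prob_clip
  with_seed(agent$seed, {
    rating <- rep(NA_real_, nrow(tt))
    for (cue in cues) {
      sel <- which(tt$cue == cue)
      if (!length(sel)) next
      trace <- simulate_learner(tt$outcome[sel], agent$params, model,
                                constants)
      m <- trace$p_hat
      k <- agent$noise_kappa
      rating[sel] <- clip01(stats::rbeta(length(m), 1 + m * k,
                                         1 + (1 - m) * k), eps)
    }
    if (round_to_grid) rating <- round(rating * 100) / 100
    out <- cbind(agent_id = agent$agent_id, session = sched$spec$label,
                 tt, rating = rating, ta_score = agent$ta_score,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Cohort specification
#'
#' Describes a synthetic cohort: the number of agents, the sessions each
#' agent completes, the trait-anxiety distribution (truncated normal
#' emulating the STAI-trait median of 39 and range 20-71), the effect map
#' linking trait anxiety to the probability of being a switching agent, and
#' the generating parameter distributions.
#'
#' The effect map is a list with `base_logit` (log-odds of switching at the
#' TA mean), `ta_weight` (log-odds change per TA point) and optional
#' `sessions` (labels in which the TA effect applies; elsewhere only
#' `base_logit` acts). Strategy is drawn once per agent using the TA effect
#' of its strongest session.
#'
#' @param n_agents Number of agents (`>= 2`).
#' @param sessions List of [session_spec()]s (or a character vector of
#'   labels, built with the given `style`).
#' @param style Experiment style used when `sessions` is a label vector.
#' @param ta Trait-anxiety distribution: list with `mean`, `sd`, `min`,
#'   `max`.
#' @param effect_map See Details.
#' @param param_summary Generating parameter means/SDs per strategy, see
#'   [default_param_summary()].
#' @param noise_kappa Response-noise concentration for all agents.
#' @param seed Cohort seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_agents = 20, sessions = "90/10", style = "III",
                        ta = list(mean = 39, sd = 10, min = 20, max = 71),
                        effect_map = list(base_logit = 0, ta_weight = 0,
                                          sessions = NULL),
                        param_summary = default_param_summary(),
                        noise_kappa = 200, seed = NULL) {
  stopifnot(n_agents >= 2)
  if (is.character(sessions))
    sessions <- lapply(sessions, function(l) session_spec(l, style))
  em <- utils::modifyList(list(base_logit = 0, ta_weight = 0,
                               sessions = NULL), effect_map)
  stopifnot(is.finite(em$base_logit), is.finite(em$ta_weight))
  structure(list(n_agents = n_agents, sessions = sessions, ta = ta,
                 effect_map = em, param_summary = param_summary,
                 noise_kappa = noise_kappa, seed = seed),
            class = "cohort_spec")
}

#' Default generating parameter summary
#'
#' Means, SDs and truncation ranges used to draw agent parameters. Step
#' sizes centre on the magnitudes typical of fitted human data (shocks
#' updating more than omissions); decay and starting counts are package
#' defaults. The switching threshold is drawn inside \[1, 3\], the range in
#' which the n-state model actually expresses state switching on these
#' schedules — below it the model fragments into many states, above it the
#' thresholds are never crossed and the "switching" label would be
#' meaningless (see the methods vignette).
#'
#' @return A list with elements `gradual` and `switching`, each holding
#'   `mean`, `sd` and optional `lower`/`upper` named vectors.
#' @export
default_param_summary <- function() {
  list(
    gradual = list(
      mean = c(tau_plus = 1.17, tau_minus = 0.86, lam = 0.95, a0 = 2, b0 = 2),
      sd   = c(tau_plus = 0.35, tau_minus = 0.30, lam = 0.03, a0 = 1, b0 = 1)),
    switching = list(
      mean = c(tau_plus = 1.13, tau_minus = 0.73, lam = 0.95, a0 = 2, b0 = 2,
               eta = 2),
      sd   = c(tau_plus = 0.35, tau_minus = 0.30, lam = 0.03, a0 = 1, b0 = 1,
               eta = 0.5),
      lower = c(eta = 1), upper = c(eta = 3)))
}

# truncated-normal draw by rejection
rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  (lo + hi) / 2
}

draw_agent_params <- function(summary, strategy) {
  s <- summary[[strategy]]
  bounds <- default_bounds(if (strategy == "switching") "n_state"
                           else "one_state")
  p <- vapply(names(s$mean), function(nm) {
    i <- match(nm, bounds$param)
    lo <- max(bounds$lower[i], if (nm %in% names(s$lower)) s$lower[[nm]] else -Inf)
    hi <- min(bounds$upper[i], if (nm %in% names(s$upper)) s$upper[[nm]] else Inf)
    rtruncnorm1(s$mean[[nm]], s$sd[[nm]], lo, hi)
  }, 1)
  par_to_learner(p, if (strategy == "switching") "n_state" else "one_state")
}

#' Simulate a cohort of agents
#'
#' Draws each agent's trait anxiety from the truncated normal, assigns the
#' strategy via the effect map (logistic in TA), draws learner parameters
#' from the generating summary, generates one fresh schedule per agent and
#' session, and simulates ratings. All randomness derives from the cohort
#' seed, so re-simulating from the stored spec reproduces the tables.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `trials` (agents x sessions x trials data frame) and
#'   `ground_truth` (one row per agent: strategy, TA, generating
#'   parameters, per-agent seed).
#' @export
simulate_cohort <- function(spec) {
  seeds <- derive_seeds(spec$seed, 1 + spec$n_agents)
  labels <- vapply(spec$sessions, function(s) s$label, "")
  em <- spec$effect_map
  with_seed(seeds[1], {
    ta <- vapply(seq_len(spec$n_agents), function(i)
      rtruncnorm1(spec$ta$mean, spec$ta$sd, spec$ta$min, spec$ta$max), 1)
    effect_on <- if (is.null(em$sessions)) TRUE else any(labels %in% em$sessions)
    w <- if (effect_on) em$ta_weight else 0
    p_sw <- stats::plogis(em$base_logit + w * (ta - spec$ta$mean))
    strategy <- ifelse(stats::runif(spec$n_agents) < p_sw,
                       "switching", "gradual")
    params <- lapply(strategy, function(s)
      draw_agent_params(spec$param_summary, s))
  })
  rows <- vector("list", spec$n_agents)
  gt <- vector("list", spec$n_agents)
  for (i in seq_len(spec$n_agents)) {
    sub <- derive_seeds(seeds[1 + i], 2 * length(spec$sessions))
    per_session <- vector("list", length(spec$sessions))
    for (j in seq_along(spec$sessions)) {
      sched <- assemble_schedule(spec$sessions[[j]], seed = sub[2 * j - 1])
      ag <- agent_spec(sprintf("agent_%03d", i), strategy[i], params[[i]],
                       ta_score = ta[i], noise_kappa = spec$noise_kappa,
                       seed = sub[2 * j])
      per_session[[j]] <- simulate_agent(ag, sched)
    }
    rows[[i]] <- do.call(rbind, per_session)
    p <- params[[i]]
    gt[[i]] <- data.frame(agent_id = sprintf("agent_%03d", i),
                          strategy = strategy[i], ta_score = ta[i],
                          tau_plus = p$tau_plus, tau_minus = p$tau_minus,
                          lam = p$lam, a0 = p$a0, b0 = p$b0,
                          eta = if (is.null(p$eta)) NA_real_ else p$eta,
                          seed = seeds[1 + i],
                          stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, rows), ground_truth = do.call(rbind, gt))
}

#' Write / read cohort trial tables
#'
#' The CSV serialises ratings on the task's 0-100 scale; reading converts
#' back to \[0, 1\].
#'
#' @param cohort A cohort list from [simulate_cohort()] or its `trials`
#'   data frame.
#' @param path File path (ground truth goes to `gt_path` if given).
#' @param gt_path Optional path for the ground-truth table.
#' @return `write_cohort` the path(s) invisibly; `read_cohort` a trial data
#'   frame with ratings in \[0, 1\].
#' @export
write_cohort <- function(cohort, path, gt_path = NULL) {
  tt <- if (is.data.frame(cohort)) cohort else cohort$trials
  tt$rating <- tt$rating * 100
  utils::write.csv(tt, path, row.names = FALSE)
  if (!is.null(gt_path) && !is.data.frame(cohort))
    utils::write.csv(cohort$ground_truth, gt_path, row.names = FALSE)
  invisible(c(path, gt_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  tt$rating <- tt$rating / 100
  tt
}
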