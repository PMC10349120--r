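#' Initialise a learner state collection
#'
#' A session starts with a single state built from the starting pseudo-counts
#' `a0`, `b0`, zero surprise, and that state active.
#'
#' @param params A [learner_params()] set.
#' @return A list with vectors `a`, `b`, `S` (per-state surprise), `last`
#'   (trial each state was last active, -1 for never) and scalar `active`.
#' @export
init_learner <- function(params) {
  list(a = params$a0, b = params$b0, S = 0, last = -1L, active = 1L)
}

#' One trial of the n-state learner (reference implementation)
#'
#' Advances the state collection by one outcome: records the active state's
#' prediction (mode, clipped) and uncertainty, updates its running surprise,
#' applies the belief update to the active state and decay to the others,
#' and then — if the surprise exceeds the basic threshold `sigma * eta` —
#' polls the existing states around the expected value
#' `E = clip(p_hat + sign(O - p_hat) * S)`; a state whose mode lies within
#' `E +/- sigma * eta` and has maximal beta density at `E` (ties broken by
#' recency) is switched to. If the surprise also exceeds the compound
#' threshold `sigma * eta * q` (with `q` the CRP difficulty of the
#' prospective state) and no candidate exists, a new state is created with
#' mode `E` and the starting uncertainty, its surprise reset to 0.
#'
#' This pure-R implementation defines the step semantics; the fast compiled
#' forward pass used by [simulate_learner()] and fitting is checked against
#' it in the package tests.
#'
#' @param states A state collection from [init_learner()].
#' @param outcome 0 or 1.
#' @param params A [learner_params()] set; `eta = NULL` disables the
#'   thresholds (one-state behaviour).
#' @param t Trial index (0-based), used for recency bookkeeping.
#' @param q_table Difficulty table from `crp_difficulty`/internal tabulation;
#'   indexed by the prospective state count.
#' @param constants Fixed constants.
#' @return A list: updated `states`, and the trial's `p_hat`, `sigma`,
#'   `surprise`, `a_pre`, `b_pre`, `active_state` (state generating the
#'   prediction), `n_states`, `event` (one of `"update"`, `"switch"`,
#'   `"create"`).
#' @export
step_nstate <- function(states, outcome, params, t = 0L,
                        q_table = rep(1, 12),
                        constants = model_constants()) {
  eps <- constants$prob_clip
  s <- states$active
  a_pre <- states$a[s]; b_pre <- states$b[s]
  p_hat <- clip01(beta_mode(a_pre, b_pre), eps)
  sigma <- beta_sd(a_pre, b_pre)

  states$S[s] <- update_surprise(states$S[s], outcome, p_hat, constants$pi_s)
  S_act <- states$S[s]
  states$last[s] <- as.integer(t)

  K <- length(states$a)
  for (j in seq_len(K)) {
    up <- update_state(list(a = states$a[j], b = states$b[j]), outcome,
                       params, active = (j == s), constants)
    states$a[j] <- up$a; states$b[j] <- up$b
  }

  event <- "update"
  nstate <- !is.null(params$eta)
  if (nstate) {
    thr <- sigma * params$eta
    if (S_act > thr) {
      q <- q_table[min(K + 1, length(q_table))]
      E <- clip01(p_hat + sign(outcome - p_hat) * S_act, eps)
      best <- -1L; bestd <- -1
      for (j in seq_len(K)) {
        if (abs(beta_mode(states$a[j], states$b[j]) - E) <= thr) {
          d <- stats::dbeta(E, states$a[j], states$b[j])
          if (d > bestd ||
              (d == bestd && best > 0 && states$last[j] > states$last[best])) {
            bestd <- d; best <- j
          }
        }
      }
      if (S_act <= thr * q) {
        if (best > 0 && best != s) { states$active <- best; event <- "switch" }
      } else if (best > 0) {
        if (best != s) { states$active <- best; event <- "switch" }
      } else {
        sd0 <- beta_sd(params$a0, params$b0)
        ab <- beta_from_mode_sd(E, sd0, constants$evidence_cap)
        states$a <- c(states$a, ab$a)
        states$b <- c(states$b, ab$b)
        states$S <- c(states$S, 0)
        states$last <- c(states$last, -1L)
        states$active <- length(states$a)
        event <- "create"
      }
    }
  }

  list(states = states, p_hat = p_hat, sigma = sigma, surprise = S_act,
       a_pre = a_pre, b_pre = b_pre, active_state = s,
       n_states = length(states$a), event = event)
}

#' Forward-simulate a beta-belief learner over an outcome sequence
#'
#' Runs the one-state or n-state learner over a sequence of binary outcomes
#' and returns the per-trial model trace. Predictions (`p_hat`, `sigma`) are
#' computed *before* each trial's outcome is seen. The one-state model is the
#' n-state step with the thresholds disabled, so the two models share every
#' arithmetic detail.
#'
#' @param outcomes Integer vector of 0/1 outcomes (1 = shock).
#' @param params A [learner_params()] set; supply `eta` for the n-state
#'   model.
#' @param model `"one_state"` or `"n_state"`. Defaults to n-state when `eta`
#'   is present in `params`.
#' @param constants Fixed constants.
#' @param q_table Optional precomputed CRP difficulty table (indexed by the
#'   prospective state count); by default it is tabulated once per call with
#'   horizon equal to the sequence length. Supplying a stub table (e.g.
#'   `seq_len(12)`) is useful for threshold-composition checks.
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference loop built
#'   on [step_nstate()]).
#' @return A data frame of class `"learner_trace"` with columns `trial`
#'   (0-based), `outcome`, `p_hat`, `sigma`, `surprise`, `a_pre`, `b_pre`,
#'   `active_state`, `n_states`, `event`.
#' @export
#' @examples
#' p <- learner_params(tau_plus = 1, tau_minus = 1, lam = 1)
#' simulate_learner(c(1, 1, 0, 1), p, model = "one_state")
simulate_learner <- function(outcomes, params,
                             model = if (is.null(params$eta)) "one_state" else "n_state",
                             constants = model_constants(), q_table = NULL,
                             engine = c("cpp", "r")) {
  model <- match.arg(model, c("one_state", "n_state"))
  engine <- match.arg(engine)
  stopifnot(all(outcomes %in% c(0L, 1L)))
  outcomes <- as.integer(outcomes)
  nstate <- model == "n_state"
  if (nstate && is.null(params$eta))
    stop("n_state model requires params$eta")
  if (is.null(q_table)) {
    q_table <- if (nstate)
      crp_q_table(horizon = max(length(outcomes), 10L),
                  n_mc = constants$crp_n_mc, theta = constants$crp_theta,
                  k_max = constants$crp_k_max)
    else rep(1, constants$crp_k_max)
  }
  eta <- if (nstate) params$eta else 0

  if (engine == "cpp") {
    res <- forward_pass_cpp(outcomes, params$tau_plus, params$tau_minus,
                            params$lam, params$a0, params$b0, eta, nstate,
                            constants$pi_s, constants$evidence_cap,
                            constants$prob_clip, q_table)
    ev <- c("update", "switch", "create")[res$event + 1L]
    out <- data.frame(trial = seq_along(outcomes) - 1L, outcome = outcomes,
                      p_hat = res$p_hat, sigma = res$sigma,
                      surprise = res$surprise, a_pre = res$a_pre,
                      b_pre = res$b_pre, active_state = res$active_state,
                      n_states = res$n_states, event = ev)
  } else {
    st <- init_learner(params)
    pp <- if (nstate) params else learner_params(params$tau_plus,
                                                 params$tau_minus, params$lam,
                                                 params$a0, params$b0,
                                                 eta = NULL)
    rows <- vector("list", length(outcomes))
    for (t in seq_along(outcomes)) {
      stp <- step_nstate(st, outcomes[t], pp, t - 1L, q_table, constants)
      st <- stp$states
      rows[[t]] <- data.frame(trial = t - 1L, outcome = outcomes[t],
                              p_hat = stp$p_hat, sigma = stp$sigma,
                              surprise = stp$surprise, a_pre = stp$a_pre,
                              b_pre = stp$b_pre,
                              active_state = stp$active_state,
                              n_states = stp$n_states, event = stp$event)
    }
    out <- do.call(rbind, rows)
  }
  class(out) <- c("learner_trace", "data.frame")
  out
}

#' @export
print.learner_trace <- function(x, ...) {
  cat("Learner trace:", nrow(x), "trials,", max(x$n_states), "state(s),",
      sum(x$event == "switch"), "switch /", sum(x$event == "create"),
      "create events\n")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more trials\n")
  invisible(x)
}

#' Serialize a model trace to CSV
#'
#' Columns: `trial,p_hat,sigma,active_state,n_states,surprise,event`.
#'
#' @param trace A `"learner_trace"` data frame.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("trial", "p_hat", "sigma", "active_state",
                             "n_states", "surprise", "event")],
                   path, row.names = FALSE)
  invisible(path)
}
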