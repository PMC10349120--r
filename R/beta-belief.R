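#' Mode of a beta belief
#'
#' The learner reports the mode of its beta-distributed belief as the
#' subjective shock probability. For shape parameters `a, b >= 1` the mode is
#' `(a - 1) / (a + b - 2)`; the flat belief `a = b = 1` has no unique mode and
#' returns 0.5 by convention.
#'
#' @param a,b Beta shape parameters (shock / no-shock pseudo-counts), both
#'   `>= 1`. Vectorised.
#' @return The mode(s), in \[0, 1\].
#' @seealso [beta_sd()], [update_state()]
#' @export
#' @examples
#' beta_mode(2, 2)  # 0.5
#' beta_mode(3, 2)  # 2/3
beta_mode <- function(a, b) {
  stopifnot(all(a >= 1), all(b >= 1))
  ifelse(a + b == 2, 0.5, (a - 1) / (a + b - 2))
}

#' Standard deviation of a beta belief
#'
#' State uncertainty is the standard deviation of the beta belief,
#' `sqrt(a b / ((a + b)^2 (a + b + 1)))`. It shrinks as evidence (`a + b`)
#' accumulates and grows again under decay.
#'
#' @inheritParams beta_mode
#' @return The standard deviation(s), positive.
#' @export
#' @examples
#' beta_sd(2, 2)
beta_sd <- function(a, b) {
  s <- a + b
  sqrt(a * b / (s^2 * (s + 1)))
}

#' Update a beta state with one outcome
#'
#' Applies one trial's update to a state's pseudo-counts. The active state
#' adds `tau_plus` to `a` after a shock or `tau_minus` to `b` after a shock
#' omission, then both parameters decay by `lam`; inactive states only decay.
#' Afterwards each parameter is floored at 1 (unimodality) and, if the sum
#' exceeds the evidence cap, the pair is rescaled proportionally onto the cap
#' (re-floored at 1 so both invariants hold).
#'
#' @param state A list or named vector with elements `a` and `b`.
#' @param outcome 0 (no shock) or 1 (shock).
#' @param params A [learner_params()] set.
#' @param active Is this the currently active state?
#' @param constants Fixed constants, see [model_constants()].
#' @return A list with updated `a` and `b`.
#' @export
#' @examples
#' update_state(list(a = 2, b = 2), 1, learner_params(tau_plus = 1, lam = 1))
update_state <- function(state, outcome, params, active = TRUE,
                         constants = model_constants()) {
  stopifnot(outcome %in% c(0, 1))
  a <- state$a; b <- state$b
  lam <- params$lam
  if (active) {
    if (outcome == 1) {
      a <- lam * (a + params$tau_plus); b <- lam * b
    } else {
      b <- lam * (b + params$tau_minus); a <- lam * a
    }
  } else {
    a <- lam * a; b <- lam * b
  }
  a <- max(a, 1); b <- max(b, 1)
  cap <- constants$evidence_cap
  if (a + b > cap) {
    f <- cap / (a + b)
    a <- a * f; b <- b * f
    if (a < 1) { a <- 1; b <- cap - 1 } else if (b < 1) { b <- 1; a <- cap - 1 }
  }
  list(a = a, b = b)
}

#' Update the running surprise
#'
#' Surprise is an exponentially smoothed absolute prediction error,
#' `S' = (1 - pi_s) S + pi_s |O - p_hat|`, bounded in \[0, 1\] whenever
#' `pi_s` is in (0, 1). Each state carries its own accumulator.
#'
#' @param s_prev Previous surprise value in \[0, 1\].
#' @param outcome 0 or 1.
#' @param p_hat Predicted shock probability before the outcome.
#' @param pi_s Smoothing weight in (0, 1).
#' @return Updated surprise in \[0, 1\].
#' @export
#' @examples
#' update_surprise(0, 1, 0.5, 0.3)  # 0.15
update_surprise <- function(s_prev, outcome, p_hat, pi_s) {
  stopifnot(s_prev >= 0, s_prev <= 1, pi_s > 0, pi_s < 1)
  (1 - pi_s) * s_prev + pi_s * abs(outcome - p_hat)
}

#' Beta shapes from a mode and standard deviation
#'
#' Solves for the shape pair with the requested mode and standard deviation
#' using the mode parameterisation `a = 1 + m c`, `b = 1 + (1 - m) c`, whose
#' SD decreases monotonically in the concentration `c` from the Beta(1,1)
#' value; the solve is a fixed-iteration bisection on `c`. Used to initialise
#' newly created states (all new states share the starting uncertainty
#' implied by `a0`, `b0`).
#'
#' @param mode Target mode in \[0, 1\].
#' @param sd Target standard deviation (at most the Beta(1,1) SD).
#' @param cap Evidence cap bounding `a + b`.
#' @return A list with `a` and `b`.
#' @export
beta_from_mode_sd <- function(mode, sd, cap = model_constants()$evidence_cap) {
  stopifnot(mode >= 0, mode <= 1, sd > 0)
  lo <- 0; hi <- cap - 2
  sd_at <- function(c) beta_sd(1 + mode * c, 1 + (1 - mode) * c)
  if (sd_at(hi) >= sd) {
    c <- hi
  } else {
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (sd_at(mid) > sd) lo <- mid else hi <- mid
    }
    c <- (lo + hi) / 2
  }
  list(a = 1 + mode * c, b = 1 + (1 - mode) * c)
}

#' State-creation difficulty from a Chinese restaurant process
#'
#' Each additional hidden state is progressively harder to create. The
#' difficulty multiplier `q(K)` applied to the surprise threshold when the
#' K-th state would be created is derived from a Chinese restaurant process
#' with concentration `theta`: seating sequences of length `horizon` are
#' simulated `n_mc` times, the per-step probability of opening a new table is
#' averaged conditional on the current table count, and the default mapping
#' is `q(K) = Pbar_new(1) / Pbar_new(K)`, clipped below at 1 and made
#' non-decreasing. Counts never visited in the simulation inherit the last
#' tabulated value. `q(1) = 1` by construction.
#'
#' @param K State count(s) at which to evaluate the multiplier; `K >= 1`.
#' @param horizon Number of trials over which the process is simulated.
#' @param n_mc Monte-Carlo iterations.
#' @param theta CRP concentration.
#' @param q_map Optional mapping from the vector of averaged new-state
#'   probabilities to a difficulty vector; the default implements the ratio
#'   mapping described above.
#' @param k_max Largest count tabulated.
#' @return Difficulty multiplier(s) `>= 1`, non-decreasing in `K`.
#' @export
#' @examples
#' set.seed(1)
#' crp_difficulty(1:4, horizon = 100, n_mc = 2000)
crp_difficulty <- function(K, horizon = 150,
                           n_mc = model_constants()$crp_n_mc,
                           theta = model_constants()$crp_theta,
                           q_map = NULL, k_max = model_constants()$crp_k_max) {
  if (any(K < 1)) stop("K must be >= 1")
  tab <- crp_q_table(horizon, n_mc, theta, q_map, k_max)
  tab[pmin(as.integer(K), length(tab))]
}

# build the full difficulty table q(1..k_max)
crp_q_table <- function(horizon = 150, n_mc = model_constants()$crp_n_mc,
                        theta = model_constants()$crp_theta, q_map = NULL,
                        k_max = model_constants()$crp_k_max) {
  pbar <- crp_new_prob_cpp(as.integer(horizon), as.integer(n_mc), theta,
                           as.integer(k_max))
  if (is.null(q_map)) {
    q <- pbar[1] / pbar
    q[is.na(q)] <- NA
  } else {
    q <- q_map(pbar)
  }
  # carry the last defined value forward, clip at 1, enforce monotonicity
  for (k in seq_along(q)) if (is.na(q[k])) q[k] <- q[max(which(!is.na(q[seq_len(k)])))]
  q <- pmax(q, 1)
  cummax(q)
}
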