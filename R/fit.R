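#' Default fitting bounds
#'
#' Box bounds and transforms for the free parameters. Step sizes lie in
#' \[0, 2\] and starting pseudo-counts in \[1, 10\] (fitted on the natural
#' scale); the decay `lam` is estimated in log space inside (0, 1); the
#' n-state threshold `eta` is estimated in log space on \[0.05, 20\], a range
#' spanning hair-trigger switching to effectively never switching.
#'
#' @param model `"one_state"` or `"n_state"`.
#' @return A data frame with columns `param`, `lower`, `upper`, `transform`.
#' @export
default_bounds <- function(model = c("one_state", "n_state")) {
  model <- match.arg(model)
  b <- data.frame(
    param = c("tau_plus", "tau_minus", "lam", "a0", "b0"),
    lower = c(0, 0, 1e-3, 1, 1),
    upper = c(2, 2, 1 - 1e-4, 10, 10),
    transform = c("identity", "identity", "log", "identity", "identity"),
    stringsAsFactors = FALSE)
  if (model == "n_state")
    b <- rbind(b, data.frame(param = "eta", lower = 0.05, upper = 20,
                             transform = "log"))
  b
}

# map unconstrained z to the bounded parameter scale and back; log-transform
# parameters are squashed logistically on the log scale
z_to_par <- function(z, bounds) {
  p <- numeric(nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    lo <- bounds$lower[i]; hi <- bounds$upper[i]
    if (bounds$transform[i] == "log") {
      p[i] <- exp(log(lo) + (log(hi) - log(lo)) * stats::plogis(z[i]))
    } else {
      p[i] <- lo + (hi - lo) * stats::plogis(z[i])
    }
  }
  names(p) <- bounds$param
  p
}

par_to_z <- function(p, bounds) {
  z <- numeric(nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    lo <- bounds$lower[i]; hi <- bounds$upper[i]
    x <- p[[bounds$param[i]]]
    x <- min(max(x, lo), hi)
    u <- if (bounds$transform[i] == "log")
      (log(x) - log(lo)) / (log(hi) - log(lo))
    else (x - lo) / (hi - lo)
    u <- min(max(u, 1e-9), 1 - 1e-9)
    z[i] <- stats::qlogis(u)
  }
  z
}

# one uniform (log-uniform for log-transform) start on the parameter scale;
# `informed` draws the decay and threshold from the ranges in which the
# learners express distinct dynamics (lam: plausible forgetting; eta: the
# regime where states are actually switched/created), which puts part of the
# multistart budget where the rugged region of the n-state likelihood lives
draw_start <- function(bounds, informed = FALSE) {
  p <- numeric(nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    lo <- bounds$lower[i]; hi <- bounds$upper[i]
    p[i] <- if (bounds$transform[i] == "log")
      exp(stats::runif(1, log(lo), log(hi)))
    else stats::runif(1, lo, hi)
  }
  names(p) <- bounds$param
  if (informed) {
    if ("lam" %in% names(p))
      p[["lam"]] <- stats::runif(1, max(bounds$lower[bounds$param == "lam"],
                                        0.88),
                                 min(bounds$upper[bounds$param == "lam"],
                                     0.9995))
    if ("eta" %in% names(p))
      p[["eta"]] <- exp(stats::runif(1, log(max(0.4, bounds$lower[
        bounds$param == "eta"])), log(min(5, bounds$upper[
        bounds$param == "eta"]))))
  }
  p
}

par_to_learner <- function(p, model) {
  learner_params(tau_plus = p[["tau_plus"]], tau_minus = p[["tau_minus"]],
                 lam = p[["lam"]], a0 = p[["a0"]], b0 = p[["b0"]],
                 eta = if (model == "n_state") p[["eta"]] else NULL)
}

#' Beta negative log-likelihood of a rating sequence
#'
#' The learner's belief before each outcome is a beta distribution; the
#' likelihood of the observed rating on that trial is its density. Returns
#' `-sum(log BetaPDF(rating_t; a_t, b_t))` over rated trials, where
#' `(a_t, b_t)` is the active state's belief before outcome `t`. Missing
#' ratings are skipped; ratings at or beyond the \[0.005, 0.995\] clipping
#' range are clipped with a warning.
#'
#' @param params A [learner_params()] set.
#' @param outcomes 0/1 outcome vector.
#' @param ratings Ratings in \[0, 1\], `NA` for unrated trials, aligned with
#'   `outcomes`.
#' @param model `"one_state"` or `"n_state"`.
#' @param constants Fixed constants.
#' @param q_table Optional precomputed CRP difficulty table.
#' @return The negative log-likelihood (0 for an empty rating vector).
#' @export
negloglik <- function(params, outcomes, ratings,
                      model = if (is.null(params$eta)) "one_state" else "n_state",
                      constants = model_constants(), q_table = NULL) {
  model <- match.arg(model, c("one_state", "n_state"))
  stopifnot(length(outcomes) == length(ratings))
  if (length(outcomes) == 0) return(0)
  eps <- constants$prob_clip
  r <- ratings
  out_of_range <- !is.na(r) & (r < eps | r > 1 - eps)
  if (any(out_of_range)) {
    warning("ratings clipped to [", eps, ", ", 1 - eps, "]")
    r <- ifelse(is.na(r), r, clip01(r, eps))
  }
  nstate <- model == "n_state"
  if (is.null(q_table)) {
    q_table <- if (nstate)
      crp_q_table(horizon = max(length(outcomes), 10L),
                  n_mc = constants$crp_n_mc, theta = constants$crp_theta,
                  k_max = constants$crp_k_max)
    else rep(1, constants$crp_k_max)
  }
  negloglik_cpp(as.integer(outcomes), as.numeric(r), params$tau_plus,
                params$tau_minus, params$lam, params$a0, params$b0,
                if (nstate) params$eta else 0, nstate, constants$pi_s,
                constants$evidence_cap, eps, q_table)
}

#' Fit a beta-belief learner to probability ratings
#'
#' Maximum-likelihood fit of the one-state or n-state learner to a sequence
#' of trial-wise shock-probability ratings under the beta likelihood (see
#' [negloglik()]). Optimisation is multi-start Nelder-Mead on an
#' unconstrained reparameterisation of the box bounds (a bounded
#' derivative-free local search), with a simplex restart from each solution.
#' Starting points are drawn uniformly within the bounds (log-uniformly for
#' log-transformed parameters); every other restart stratifies the decay and
#' threshold starts into the ranges where the learners express distinct
#' dynamics, because the n-state likelihood is rugged there. The restart
#' with the lowest negative log-likelihood wins.
#'
#' @param outcomes 0/1 outcome vector (typically the reversal cue's outcome
#'   stream for one session).
#' @param ratings Ratings in \[0, 1\] aligned with `outcomes`; `NA` allowed.
#' @param model `"one_state"` or `"n_state"`.
#' @param bounds Bounds/transform table, see [default_bounds()].
#' @param n_restarts Number of random restarts (the study protocol uses 45).
#' @param seed Optional seed making the fit reproducible.
#' @param extra_starts Optional list of named parameter vectors appended to
#'   the random starts (e.g. a one-state optimum with `eta` at its upper
#'   bound, which guarantees the nested model's likelihood is attainable).
#' @param constants Fixed constants.
#' @param control Passed to [stats::optim()] (method `"Nelder-Mead"`).
#' @return An object of class `"beta_fit"`: a list with `model`, `params`
#'   (a [learner_params()] set), `par` (named vector), `nll`, `bic`,
#'   `n_trials` (rated trials), `n_params`, `n_restarts`,
#'   `best_restart_idx`, `restarts` (data frame of per-restart results),
#'   `trace` (the model trace at the optimum) and the data.
#' @export
#' @examples
#' set.seed(1)
#' o <- rbinom(60, 1, 0.8)
#' tr <- simulate_learner(o, learner_params(1, 1, 0.97, 2, 2))
#' f <- fit_beta_learner(o, tr$p_hat, "one_state", n_restarts = 5, seed = 2)
#' f
fit_beta_learner <- function(outcomes, ratings,
                             model = c("one_state", "n_state"),
                             bounds = default_bounds(model), n_restarts = 45,
                             seed = NULL, extra_starts = NULL,
                             constants = model_constants(),
                             control = list(maxit = 400, reltol = 1e-8)) {
  model <- match.arg(model)
  stopifnot(length(outcomes) == length(ratings), n_restarts >= 1)
  rated <- sum(!is.na(ratings))
  if (rated < 1) stop("no rated trials to fit")
  eps <- constants$prob_clip
  ratings <- ifelse(is.na(ratings), NA_real_, clip01(ratings, eps))
  outcomes <- as.integer(outcomes)

  with_seed(seed, {
    nstate <- model == "n_state"
    q_table <- if (nstate)
      crp_q_table(horizon = max(length(outcomes), 10L),
                  n_mc = constants$crp_n_mc, theta = constants$crp_theta,
                  k_max = constants$crp_k_max)
    else rep(1, constants$crp_k_max)

    obj <- function(z) {
      p <- z_to_par(z, bounds)
      negloglik_cpp(outcomes, ratings, p[["tau_plus"]], p[["tau_minus"]],
                    p[["lam"]], p[["a0"]], p[["b0"]],
                    if (nstate) p[["eta"]] else 0, nstate, constants$pi_s,
                    constants$evidence_cap, eps, q_table)
    }

    starts <- lapply(seq_len(n_restarts), function(i)
      draw_start(bounds, informed = (i %% 2 == 1)))
    if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
    res <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      z0 <- par_to_z(as.list(starts[[i]]), bounds)
      opt <- tryCatch({
        o <- stats::optim(z0, obj, method = "Nelder-Mead", control = control)
        # simplex restart from the solution: Nelder-Mead collapses easily on
        # this piecewise surface, a fresh simplex often improves the optimum
        stats::optim(o$par, obj, method = "Nelder-Mead", control = control)
      }, error = function(e) NULL)
      res[[i]] <- opt
    }
    ok <- !vapply(res, is.null, TRUE)
    if (!any(ok)) stop("all restarts failed")
    nlls <- vapply(res, function(r) if (is.null(r)) Inf else r$value, 1)
    best <- which.min(nlls)
    par <- z_to_par(res[[best]]$par, bounds)
    params <- par_to_learner(par, model)
    nll <- nlls[best]
    k <- nrow(bounds)
    bic_val <- bic(nll, k, rated)
    trace <- simulate_learner(outcomes, params, model, constants,
                              q_table = q_table)
    structure(list(model = model, params = params, par = par, nll = nll,
                   bic = bic_val, n_trials = rated, n_params = k,
                   n_restarts = length(starts), best_restart_idx = best,
                   restarts = data.frame(restart = seq_along(starts),
                                         nll = nlls,
                                         converged = ok),
                   trace = trace, bounds = bounds,
                   outcomes = outcomes, ratings = ratings,
                   constants = constants, q_table = q_table),
              class = "beta_fit")
  })
}

#' Bayesian information criterion
#'
#' `BIC = k log(n) + 2 nll` with `k` free parameters and `n` rated trials.
#'
#' @param nll Negative log-likelihood.
#' @param n_params Number of free parameters (5 one-state, 6 n-state).
#' @param n_trials Number of rated trials (`>= 1`).
#' @return The BIC value.
#' @export
bic <- function(nll, n_params, n_trials) {
  stopifnot(n_trials >= 1)
  n_params * log(n_trials) + 2 * nll
}

#' Compare one-state and n-state fits by BIC
#'
#' `delta_bic = BIC(one-state) - BIC(n-state)`; positive values favour the
#' state-inference model. Ties go to the simpler one-state model
#' (parsimony).
#'
#' @param fit1 A `"beta_fit"` for the one-state model.
#' @param fitn A `"beta_fit"` for the n-state model, fitted to the same
#'   data.
#' @return A list of class `"beta_fit_comparison"` with `delta_bic`,
#'   `winner` (`"one_state"` or `"n_state"`) and both BICs.
#' @export
compare_models <- function(fit1, fitn) {
  if (fit1$n_trials != fitn$n_trials)
    stop("fits are not on the same data (n_trials differ)")
  delta <- fit1$bic - fitn$bic
  structure(list(delta_bic = delta,
                 winner = if (delta > 0) "n_state" else "one_state",
                 bic_one_state = fit1$bic, bic_n_state = fitn$bic,
                 n_trials = fit1$n_trials),
            class = "beta_fit_comparison")
}

#' @export
print.beta_fit_comparison <- function(x, ...) {
  cat(sprintf("BIC one-state %.2f vs n-state %.2f: delta = %+.2f -> %s\n",
              x$bic_one_state, x$bic_n_state, x$delta_bic, x$winner))
  invisible(x)
}

#' Fit both models to one rating sequence
#'
#' Convenience wrapper: fits the one-state model, then the n-state model
#' with the one-state optimum (threshold at its upper bound) added as an
#' extra start so that the nested likelihood is always attainable, and
#' returns both fits plus their comparison.
#'
#' @inheritParams fit_beta_learner
#' @return A list with elements `one_state`, `n_state` (both `"beta_fit"`)
#'   and `comparison`.
#' @export
fit_both_models <- function(outcomes, ratings, n_restarts = 45, seed = NULL,
                            constants = model_constants(),
                            control = list(maxit = 400, reltol = 1e-8)) {
  seeds <- derive_seeds(seed, 2)
  f1 <- fit_beta_learner(outcomes, ratings, "one_state",
                         n_restarts = n_restarts, seed = seeds[1],
                         constants = constants, control = control)
  bn <- default_bounds("n_state")
  nested <- c(f1$par, eta = bn$upper[bn$param == "eta"])
  fn <- fit_beta_learner(outcomes, ratings, "n_state",
                         n_restarts = n_restarts, seed = seeds[2],
                         extra_starts = list(nested), constants = constants,
                         control = control)
  list(one_state = f1, n_state = fn, comparison = compare_models(f1, fn))
}
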