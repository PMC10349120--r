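#' Fixed model constants
#'
#' Constants shared by the one-state and n-state learners that are *not*
#' estimated from data: the surprise-smoothing weight, the
#' Chinese-restaurant-process parameters governing the difficulty of creating
#' additional states, the evidence cap on the beta pseudo-counts, and the
#' clipping constant applied to probabilities and ratings.
#'
#' @param pi_s Surprise smoothing weight in (0,1). The running surprise is an
#'   exponentially weighted average of absolute prediction errors; `pi_s` is
#'   the weight on the current trial. Fixed at 0.3 (mid-range smoothing) so
#'   that the n-state model keeps a single extra free parameter (the
#'   threshold) relative to the one-state model.
#' @param crp_theta Concentration of the Chinese restaurant process used to
#'   derive the state-creation difficulty multiplier.
#' @param crp_alpha Second CRP parameter as printed in the source model
#'   description; recorded for completeness but unused by the default
#'   difficulty mapping (see [crp_difficulty()]).
#' @param evidence_cap Upper bound on `a + b` of any state's beta belief;
#'   keeps state uncertainty within realistic bounds and the updates
#'   numerically stable.
#' @param prob_clip Clipping constant `eps`: predicted probabilities, polling
#'   targets and observed ratings are clipped into `[eps, 1 - eps]`.
#' @param crp_n_mc Monte-Carlo iterations used to build the CRP difficulty
#'   table.
#' @param crp_k_max Largest state count tabulated for the difficulty
#'   multiplier; larger counts reuse the last entry.
#'
#' @return A named list of constants.
#' @export
model_constants <- function(pi_s = 0.3, crp_theta = 0.25, crp_alpha = 1,
                            evidence_cap = 30, prob_clip = 0.005,
                            crp_n_mc = 10000, crp_k_max = 12) {
  stopifnot(pi_s > 0, pi_s < 1, crp_theta > 0, evidence_cap > 2,
            prob_clip > 0, prob_clip < 0.5, crp_n_mc >= 1, crp_k_max >= 2)
  list(pi_s = pi_s, crp_theta = crp_theta, crp_alpha = crp_alpha,
       evidence_cap = evidence_cap, prob_clip = prob_clip,
       crp_n_mc = crp_n_mc, crp_k_max = crp_k_max)
}

#' Learner parameter set
#'
#' Free parameters of the beta-belief learners. `tau_plus` and `tau_minus`
#' are the attention weights added to the shock (`a`) and no-shock (`b`)
#' pseudo-counts, `lam` is the multiplicative decay applied to every state on
#' every trial (forgetting), `a0`/`b0` are the starting pseudo-counts, and
#' `eta` is the surprise threshold of the n-state model (`NULL` for the
#' one-state learner).
#'
#' @param tau_plus Shock step size, in \[0, 2\].
#' @param tau_minus No-shock step size, in \[0, 2\].
#' @param lam Decay in (0, 1\].  `lam = 1` disables forgetting (useful for
#'   closed-form checks); fitting constrains it inside (0, 1).
#' @param a0,b0 Starting pseudo-counts, in \[1, 10\] (values below 1 would
#'   make the belief bimodal).
#' @param eta Surprise threshold (> 0), or `NULL` for the one-state model.
#'
#' @return A named list with class `"learner_params"`.
#' @export
learner_params <- function(tau_plus = 1, tau_minus = 1, lam = 0.95,
                           a0 = 1, b0 = 1, eta = NULL) {
  stopifnot(tau_plus >= 0, tau_plus <= 2, tau_minus >= 0, tau_minus <= 2,
            lam > 0, lam <= 1, a0 >= 1, a0 <= 10, b0 >= 1, b0 <= 10,
            is.null(eta) || eta > 0)
  structure(list(tau_plus = tau_plus, tau_minus = tau_minus, lam = lam,
                 a0 = a0, b0 = b0, eta = eta),
            class = "learner_params")
}

# run `code` under a temporary RNG state seeded with `seed`; NULL = use the
# ambient RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# derive k reproducible sub-seeds (< 2^31) from one seed
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)
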