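#' Fit both models to every agent x session in a cohort
#'
#' Fits the one-state and n-state learners to each agent's reversal-cue
#' ratings in each session and tabulates fits and the BIC comparison.
#'
#' @param trials Cohort trial data frame.
#' @param n_restarts Restarts per fit.
#' @param seed Seed; per-fit seeds are derived from it.
#' @param cue Cue fitted (default the reversal cue, matching the study
#'   protocol).
#' @return A data frame with one row per agent x session x model: fitted
#'   parameters, `nll`, `bic`, plus `delta_bic` and `winner` repeated on
#'   both rows.
#' @export
fit_cohort <- function(trials, n_restarts = 45, seed = NULL,
                       cue = "reversal") {
  groups <- unique(trials[, c("agent_id", "session")])
  seeds <- derive_seeds(seed, nrow(groups))
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    tt <- trials[trials$agent_id == groups$agent_id[i] &
                 trials$session == groups$session[i] &
                 trials$cue == cue, , drop = FALSE]
    tt <- tt[order(tt$trial), ]
    fb <- fit_both_models(tt$outcome, tt$rating, n_restarts = n_restarts,
                          seed = seeds[i])
    fmt <- function(f) data.frame(
      agent_id = groups$agent_id[i], session = groups$session[i],
      model = f$model, nll = f$nll, bic = f$bic,
      tau_plus = f$par[["tau_plus"]], tau_minus = f$par[["tau_minus"]],
      lam = f$par[["lam"]], a0 = f$par[["a0"]], b0 = f$par[["b0"]],
      eta = if (f$model == "n_state") f$par[["eta"]] else NA_real_,
      n_restarts = f$n_restarts, n_trials = f$n_trials,
      delta_bic = fb$comparison$delta_bic, winner = fb$comparison$winner,
      stringsAsFactors = FALSE)
    rows[[i]] <- rbind(fmt(fb$one_state), fmt(fb$n_state))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model and parameter recovery
#'
#' Simulates agents from each generating model (parameters drawn from the
#' supplied means/SDs, truncated to the fitting bounds), fits both candidate
#' models to each synthetic data set with the identical procedure, and
#' tabulates the BIC winners in a confusion matrix plus truth-vs-estimate
#' correlations for the generating model's parameters.
#'
#' @param param_summary Generating means/SDs per model, see
#'   [default_param_summary()].
#' @param session A [session_spec()] used for every agent (default: the
#'   90/10 session, where strategies are most identifiable).
#' @param n_agents Agents per generating model.
#' @param n_restarts Restarts per fit.
#' @param noise_kappa Response-noise concentration.
#' @param seed Seed.
#' @return A list of class `"recovery_report"`: `confusion` (2x2 counts,
#'   generator x winner), `accuracy` (per generator), `param_recovery`
#'   (data frame of truth/estimate correlations), `n_agents`, `fits`.
#' @export
model_recovery <- function(param_summary = default_param_summary(),
                           session = session_spec("90/10", "III"),
                           n_agents = 30, n_restarts = 15,
                           noise_kappa = 200, seed = NULL) {
  generators <- c("gradual", "switching")
  seeds <- derive_seeds(seed, 1)
  sub <- derive_seeds(seeds[1], 2 * length(generators) * n_agents + 1)
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(generator = c("one_state", "n_state"),
                                      winner = c("one_state", "n_state")))
  truth <- list(); est <- list(); fits <- list()
  idx <- 0L
  for (g in seq_along(generators)) {
    gen <- generators[g]
    gen_model <- if (gen == "switching") "n_state" else "one_state"
    for (i in seq_len(n_agents)) {
      idx <- idx + 1L
      s1 <- sub[2 * idx - 1]; s2 <- sub[2 * idx]
      p <- with_seed(s1, draw_agent_params(param_summary, gen))
      sched <- assemble_schedule(session, seed = s1)
      ag <- agent_spec(sprintf("%s_%02d", gen, i), gen, p,
                       noise_kappa = noise_kappa, seed = s2)
      tab <- simulate_agent(ag, sched, cues = "reversal")
      rev <- tab[tab$cue == "reversal", ]
      fb <- tryCatch(
        fit_both_models(rev$outcome, rev$rating, n_restarts = n_restarts,
                        seed = s2),
        error = function(e) NULL)
      if (is.null(fb)) next
      win <- fb$comparison$winner
      confusion[gen_model, win] <- confusion[gen_model, win] + 1L
      own <- if (gen_model == "one_state") fb$one_state else fb$n_state
      truth[[idx]] <- c(unlist(p[c("tau_plus", "tau_minus", "lam",
                                   "a0", "b0")]),
                        eta = if (is.null(p$eta)) NA_real_ else p$eta,
                        gen = g)
      est[[idx]] <- c(own$par[c("tau_plus", "tau_minus", "lam", "a0", "b0")],
                      eta = if (gen_model == "n_state")
                        own$par[["eta"]] else NA_real_, gen = g)
      fits[[idx]] <- data.frame(generator = gen_model, agent = i,
                                winner = win,
                                delta_bic = fb$comparison$delta_bic,
                                stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, truth); es <- do.call(rbind, est)
  pr <- do.call(rbind, lapply(c("tau_plus", "tau_minus", "lam", "a0", "b0",
                                "eta"), function(nm) {
    ok <- !is.na(tr[, nm]) & !is.na(es[, nm])
    r <- if (sum(ok) >= 4 && stats::sd(tr[ok, nm]) > 0 &&
             stats::sd(es[ok, nm]) > 0)
      stats::cor(tr[ok, nm], es[ok, nm]) else NA_real_
    data.frame(param = nm, r = r, n = sum(ok), stringsAsFactors = FALSE)
  }))
  structure(list(confusion = confusion,
                 accuracy = diag(confusion) / rowSums(confusion),
                 param_recovery = pr, n_agents = n_agents,
                 fits = do.call(rbind, fits), seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Model recovery (", x$n_agents, "agents per generator )\n")
  print(x$confusion)
  cat("accuracy:", paste(names(x$accuracy),
                         sprintf("%.2f", x$accuracy), collapse = ", "), "\n")
  cat("parameter recovery (truth vs estimate):\n")
  print(x$param_recovery, row.names = FALSE)
  invisible(x)
}

#' Parameter recovery sweep for the one-state learner
#'
#' Simulates low-noise gradual agents with true parameters drawn uniformly
#' over the estimable interior of the parameter space, refits the one-state
#' model, and reports truth-vs-estimate correlations. Sweeping the range —
#' rather than clustering truths at the cohort means — is the standard
#' design for a parameter-recovery study: it probes whether the estimator
#' orders agents correctly across the space in which the parameters are
#' interpreted. Note that the raw step sizes are estimated with an upward
#' bias when the response noise is much narrower than the beta-belief
#' likelihood (see the methods vignette); correlations, not intercepts, are
#' the meaningful recovery metric here.
#'
#' @param n_agents Number of simulated agents.
#' @param n_restarts Restarts per fit.
#' @param noise_kappa Response-noise concentration.
#' @param session A [session_spec()]; the default long session yields about
#'   300 rated reversal-cue trials per agent.
#' @param ranges Uniform truth ranges per parameter.
#' @param seed Seed.
#' @return A list: `table` (truth and estimate per agent) and `r` (named
#'   Pearson correlations for `tau_plus`, `tau_minus`, `lam`).
#' @export
parameter_recovery <- function(n_agents = 40, n_restarts = 45,
                               noise_kappa = 200,
                               session = session_spec("90/10", "III",
                                                      phase_len_mean = 50,
                                                      phase_len_jitter = 10,
                                                      n_phases = 10),
                               ranges = list(tau_plus = c(0.2, 1.9),
                                             tau_minus = c(0.2, 1.9),
                                             lam = c(0.9, 0.99),
                                             a0 = c(1, 4), b0 = c(1, 4)),
                               seed = NULL) {
  seeds <- derive_seeds(seed, 2 * n_agents)
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    p <- with_seed(seeds[2 * i - 1], {
      d <- lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
      learner_params(d$tau_plus, d$tau_minus, d$lam, d$a0, d$b0)
    })
    sch <- assemble_schedule(session, seed = seeds[2 * i - 1])
    ag <- agent_spec("a", "gradual", p, noise_kappa = noise_kappa,
                     seed = seeds[2 * i])
    rev <- simulate_agent(ag, sch, cues = "reversal")
    rev <- rev[rev$cue == "reversal", ]
    f <- fit_beta_learner(rev$outcome, rev$rating, "one_state",
                          n_restarts = n_restarts, seed = seeds[2 * i])
    rows[[i]] <- data.frame(agent = i, n_rated = nrow(rev),
                            tau_plus = p$tau_plus, tau_minus = p$tau_minus,
                            lam = p$lam,
                            tau_plus_hat = f$par[["tau_plus"]],
                            tau_minus_hat = f$par[["tau_minus"]],
                            lam_hat = f$par[["lam"]])
  }
  tab <- do.call(rbind, rows)
  r <- c(tau_plus = stats::cor(tab$tau_plus, tab$tau_plus_hat),
         tau_minus = stats::cor(tab$tau_minus, tab$tau_minus_hat),
         lam = stats::cor(tab$lam, tab$lam_hat))
  list(table = tab, r = r)
}

#' Correlation with bootstrap CI and optional permutation test
#'
#' Pearson or Spearman correlation with a percentile bootstrap confidence
#' interval over case resampling and, optionally, a permutation p-value
#' from label shuffles.
#'
#' @param x,y Paired numeric vectors (pairs with missing values are
#'   dropped; at least 4 complete pairs required).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param n_perm Permutation shuffles (0 = no permutation test).
#' @param conf Confidence level.
#' @param seed Seed.
#' @return A list: `estimate`, `ci` (length 2), `p_perm` (`NA` if not
#'   requested), `method`, `n`, `degenerate` (zero-variance flag).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      n_boot = 2000, n_perm = 0, conf = 0.95, seed = NULL) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                p_perm = NA_real_, method = method, n = n,
                degenerate = TRUE))
  est <- stats::cor(x, y, method = method)
  with_seed(seed, {
    bs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
      stats::cor(x[idx], y[idx], method = method)
    }, 1)
    ci <- unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
    p_perm <- NA_real_
    if (n_perm > 0) {
      perm <- vapply(seq_len(n_perm), function(i)
        stats::cor(x, sample(y), method = method), 1)
      p_perm <- (1 + sum(abs(perm) >= abs(est))) / (n_perm + 1)
    }
  })
  list(estimate = est, ci = ci, p_perm = p_perm, method = method, n = n,
       degenerate = FALSE)
}

#' Sample size for detecting a correlation
#'
#' Smallest sample size achieving the target power for a two-sided test of
#' a correlation of magnitude `r`, under the Fisher z approximation:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3)`.
#'
#' @param r Hypothesised correlation magnitude, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param alpha Two-tailed significance level, in (0, 1).
#' @return Required sample size (integer).
#' @export
#' @examples
#' required_n_correlation(0.5, 0.8, 0.0167)  # 38
required_n_correlation <- function(r, power, alpha) {
  stopifnot(r > 0, r < 1, power > 0, power < 1, alpha > 0, alpha < 1)
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(r)
  as.integer(ceiling(z^2 + 3))
}

#' Split-half out-of-sample marker check
#'
#' Fits both models to the first half of each agent's session, computes the
#' behavioural markers on the second half, and correlates the first-half
#' relative model fit (delta BIC) with the second-half markers. Sessions
#' whose halves do not both contain at least two behavioural phases of the
#' reversal cue are flagged missing.
#'
#' @param trials Cohort trial data frame.
#' @param n_restarts Restarts per fit.
#' @param seed Seed.
#' @param swap_halves Fit on the second half and mark on the first instead
#'   (symmetry check).
#' @return A list: `table` (per agent x session delta_bic + markers, with
#'   `excluded` flag), `cor_abs_slope`, `cor_lr_diff` (each a
#'   [correlate()] result or `NA` if fewer than 4 usable rows).
#' @export
split_half_check <- function(trials, n_restarts = 15, seed = NULL,
                             swap_halves = FALSE) {
  groups <- unique(trials[, c("agent_id", "session")])
  seeds <- derive_seeds(seed, nrow(groups))
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    tt <- trials[trials$agent_id == groups$agent_id[i] &
                 trials$session == groups$session[i], , drop = FALSE]
    tt <- tt[order(tt$trial), ]
    half <- floor(nrow(tt) / 2)
    first <- tt[seq_len(half), ]; second <- tt[(half + 1):nrow(tt), ]
    if (swap_halves) { tmp <- first; first <- second; second <- tmp }
    nph <- function(d) {
      p <- d$phase_type[d$cue == "reversal"]
      if (!length(p)) 0L else length(rle(p)$lengths)
    }
    if (nph(first) < 2 || nph(second) < 2) {
      rows[[i]] <- data.frame(agent_id = groups$agent_id[i],
                              session = groups$session[i],
                              delta_bic = NA_real_, abs_slope = NA_real_,
                              lr_diff = NA_real_, excluded = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    rev <- first[first$cue == "reversal", ]
    fb <- fit_both_models(rev$outcome, rev$rating, n_restarts = n_restarts,
                          seed = seeds[i])
    mk <- compute_markers(second)
    rows[[i]] <- data.frame(agent_id = groups$agent_id[i],
                            session = groups$session[i],
                            delta_bic = fb$comparison$delta_bic,
                            abs_slope = mk$abs_slope, lr_diff = mk$lr_diff,
                            excluded = FALSE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  cors <- lapply(c("abs_slope", "lr_diff"), function(v) {
    ok <- stats::complete.cases(tab$delta_bic, tab[[v]])
    if (sum(ok) >= 4)
      correlate(tab$delta_bic[ok], tab[[v]][ok], "spearman", n_boot = 500,
                seed = seeds[1])
    else NA
  })
  list(table = tab, cor_abs_slope = cors[[1]], cor_lr_diff = cors[[2]])
}
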