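test_that("negloglik matches the closed form on a frozen belief", {
  # zero step sizes and no decay pin the belief at Beta(2,2); constant 0.5
  # ratings then contribute -log dbeta(0.5; 2, 2) = -log(1.5) per trial
  p <- learner_params(tau_plus = 0, tau_minus = 0, lam = 1, a0 = 2, b0 = 2)
  o <- rep(c(1L, 0L), 10)
  nll <- negloglik(p, o, rep(0.5, 20), model = "one_state")
  expect_equal(nll, -20 * log(1.5), tolerance = 1e-10)
})

test_that("negloglik equals the per-trial loop oracle on random traces", {
  set.seed(16)
  for (i in 1:5) {
    p <- random_params(nstate = TRUE)
    o <- rbinom(60, 1, 0.75)
    r <- pmin(pmax(rbeta(60, 2, 2), 0.005), 0.995)
    r[sample(60, 5)] <- NA  # missing ratings are skipped
    q <- crp_difficulty(1:12, horizon = 60, n_mc = 500)
    expect_equal(negloglik(p, o, r, q_table = q),
                 oracle_nll(o, r, p, q), tolerance = 1e-9)
  }
})

test_that("negloglik of an empty sequence is zero and bounds are clipped", {
  p <- learner_params()
  expect_equal(negloglik(p, integer(0), numeric(0)), 0)
  expect_warning(nll <- negloglik(p, c(1L, 0L), c(1, 0), "one_state"),
                 "clipped")
  expect_true(is.finite(nll))
})

test_that("bic follows its definition and agrees with stats::BIC", {
  expect_equal(bic(0, 5, exp(1)), 5)
  expect_equal(bic(10, 6, 100) - bic(10, 5, 100), log(100))
  set.seed(17)
  o <- rbinom(40, 1, 0.8)
  tr <- simulate_learner(o, learner_params(1, 1, 0.95, 2, 2), "one_state")
  f <- fit_beta_learner(o, tr$p_hat, "one_state", n_restarts = 4, seed = 1)
  expect_equal(stats::BIC(f), f$bic, tolerance = 1e-6)
  expect_equal(f$bic, bic(f$nll, f$n_params, f$n_trials))
})

test_that("refitting with the same seed is deterministic", {
  set.seed(18)
  o <- rbinom(50, 1, 0.7)
  r <- pmin(pmax(rbeta(50, 3, 2), 0.005), 0.995)
  f1 <- fit_beta_learner(o, r, "one_state", n_restarts = 5, seed = 42)
  f2 <- fit_beta_learner(o, r, "one_state", n_restarts = 5, seed = 42)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$restarts, f2$restarts)
})

test_that("the winning restart attains the minimal nll", {
  set.seed(19)
  o <- rbinom(60, 1, 0.8)
  r <- pmin(pmax(rbeta(60, 4, 2), 0.005), 0.995)
  f <- fit_beta_learner(o, r, "one_state", n_restarts = 8, seed = 3)
  expect_true(all(f$nll <= f$restarts$nll + 1e-12))
  expect_equal(f$nll, min(f$restarts$nll))
})

test_that("fit recovers the prediction trace of a low-noise agent", {
  set.seed(20)
  truth <- learner_params(1.2, 0.8, 0.96, 2, 2)
  sch <- assemble_schedule(session_spec("90/10", "III"), seed = 31)
  ag <- agent_spec("a1", "gradual", truth, noise_kappa = 500, seed = 32)
  tab <- simulate_agent(ag, sch, cues = "reversal")
  rev <- tab[tab$cue == "reversal", ]
  f <- fit_beta_learner(rev$outcome, rev$rating, "one_state",
                        n_restarts = 8, seed = 33)
  truth_trace <- simulate_learner(rev$outcome, truth, "one_state")
  expect_lt(mean(abs(fitted(f) - truth_trace$p_hat)), 0.05)
})

test_that("model comparison signs, ties and guards behave as documented", {
  fake <- function(bic, n) structure(list(bic = bic, n_trials = n),
                                     class = "beta_fit")
  cmp <- compare_models(fake(-118, 100), fake(-123, 100))
  expect_equal(cmp$delta_bic, 5)
  expect_equal(cmp$winner, "n_state")
  expect_equal(compare_models(fake(-10, 50), fake(-10, 50))$winner,
               "one_state")  # tie goes to the simpler model
  expect_error(compare_models(fake(-10, 50), fake(-12, 60)), "same data")
})

test_that("the nested start makes the n-state likelihood dominate", {
  set.seed(21)
  o <- rbinom(80, 1, 0.75)
  r <- pmin(pmax(rbeta(80, 3, 2), 0.005), 0.995)
  fb <- fit_both_models(o, r, n_restarts = 5, seed = 9)
  expect_lte(fb$n_state$nll, fb$one_state$nll + 1e-6)
})

test_that("fit methods expose the standard modelling interface", {
  set.seed(22)
  o <- rbinom(50, 1, 0.8)
  tr <- simulate_learner(o, learner_params(1, 1, 0.95, 2, 2), "one_state")
  f <- fit_beta_learner(o, tr$p_hat, "one_state", n_restarts = 4, seed = 2)
  expect_named(coef(f), c("tau_plus", "tau_minus", "lam", "a0", "b0"))
  expect_equal(nobs(f), 50)
  expect_equal(as.numeric(logLik(f)), -f$nll)
  expect_length(predict(f), 50)
  expect_length(predict(f, newdata = rep(1L, 10)), 10)
  expect_equal(residuals(f), f$ratings - fitted(f))
  sims <- simulate(f, nsim = 3, seed = 1, kappa = 1e6)
  expect_equal(dim(sims), c(50, 3))
  expect_lt(max(abs(sims[, 1] - fitted(f))), 0.01)
  out <- capture.output({print(f); print(summary(f))})
  expect_true(any(grepl("BIC", out)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
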