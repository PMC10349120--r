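test_that("one-state trace follows pseudo-counting when decay is off", {
  p <- learner_params(tau_plus = 1, tau_minus = 1, lam = 1, a0 = 1, b0 = 1)
  set.seed(3)
  o <- rbinom(25, 1, 0.6)
  tr <- simulate_learner(o, p, "one_state")
  for (t in 3:25) {
    n1 <- sum(o[seq_len(t - 1)]); n0 <- (t - 1) - n1
    expect_equal(tr$p_hat[t], n1 / (n1 + n0), tolerance = 1e-12)
  }
})

test_that("all-shock sequences give non-decreasing predictions", {
  p <- learner_params(tau_plus = 1.3, tau_minus = 0.7, lam = 1, a0 = 2,
                      b0 = 2)
  tr <- simulate_learner(rep(1L, 40), p, "one_state")
  expect_true(all(diff(tr$p_hat) >= -1e-12))
})

test_that("trace invariants hold on alternating outcomes", {
  set.seed(5)
  for (i in 1:5) {
    p <- random_params(nstate = TRUE)
    tr <- simulate_learner(rep(c(1L, 0L), 30), p, "n_state",
                           q_table = rep(1, 12))
    expect_true(all(tr$p_hat > 0 & tr$p_hat < 1))
    expect_true(all(tr$sigma > 0))
    expect_true(all(tr$surprise >= 0 & tr$surprise <= 1))
    expect_true(all(diff(tr$n_states) >= 0))
    expect_true(all(tr$a_pre + tr$b_pre <= 30 + 1e-9))
  }
})

test_that("compiled and reference engines produce identical traces", {
  set.seed(11)
  for (i in 1:8) {
    nst <- i > 2
    p <- random_params(nstate = nst)
    o <- rbinom(60, 1, runif(1, 0.2, 0.9))
    q <- crp_difficulty(1:12, horizon = 60, n_mc = 500)
    t_cpp <- simulate_learner(o, p, q_table = q, engine = "cpp")
    t_r <- simulate_learner(o, p, q_table = q, engine = "r")
    expect_equal(t_cpp$p_hat, t_r$p_hat, tolerance = 1e-12)
    expect_equal(t_cpp$a_pre, t_r$a_pre, tolerance = 1e-12)
    expect_identical(t_cpp$event, t_r$event)
    expect_identical(t_cpp$n_states, t_r$n_states)
  }
})

test_that("compiled trace matches the plain-loop oracle", {
  set.seed(12)
  for (i in 1:8) {
    p <- random_params(nstate = TRUE)
    o <- rbinom(50, 1, 0.7)
    q <- crp_difficulty(1:12, horizon = 50, n_mc = 500)
    fw <- oracle_forward(o, p, q)
    tr <- simulate_learner(o, p, q_table = q)
    expect_equal(tr$p_hat, fw$p_hat, tolerance = 1e-9)
    expect_identical(tr$event, fw$event)
  }
})

test_that("a huge threshold reproduces the one-state trace exactly", {
  set.seed(6)
  for (i in 1:5) {
    p1 <- random_params(nstate = FALSE)
    pn <- learner_params(p1$tau_plus, p1$tau_minus, p1$lam, p1$a0, p1$b0,
                         eta = 1e6)
    o <- rbinom(100, 1, runif(1, 0.1, 0.9))
    t1 <- simulate_learner(o, p1, "one_state")
    tn <- simulate_learner(o, pn, "n_state")
    expect_equal(tn$p_hat, t1$p_hat, tolerance = 1e-12)
    expect_true(all(tn$n_states == 1))
  }
})

test_that("a contingency change creates exactly one new state promptly", {
  # deterministic 90/10-like toy stream: 30 shocks then 10 omissions
  p <- learner_params(1, 1, 0.95, 2, 2, eta = 2)
  tr <- simulate_learner(c(rep(1L, 30), rep(0L, 10)), p)
  expect_equal(max(tr$n_states), 2)
  creates <- tr$trial[tr$event == "create"]
  expect_length(creates, 1)
  expect_lte(creates - 30, 10)  # within 10 trials of the change
})

test_that("a second change switches back to the earlier state", {
  p <- learner_params(1, 1, 0.95, 2, 2, eta = 2)
  tr <- simulate_learner(c(rep(1L, 30), rep(0L, 15), rep(1L, 15)), p)
  expect_equal(max(tr$n_states), 2)  # polling precedes creation
  after <- tr[tr$trial >= 45, ]
  expect_gte(sum(after$event == "switch"), 1)
  expect_equal(sum(tr$event == "create"), 1)
})

test_that("single-contingency streams keep one state under a conservative
           threshold", {
  # with no contingency change, a threshold above the oddball-surprise range
  # never fragments the belief (clustered omissions in a 90% stream are the
  # binding case; see the methods vignette on choosing eta)
  set.seed(7)
  p <- learner_params(1.1, 0.8, 0.95, 2, 2, eta = 5)
  for (i in 1:10)
    expect_equal(max(simulate_learner(rbinom(120, 1, 0.9), p)$n_states), 1)
})

test_that("decayed idle states drift toward the flat-belief uncertainty", {
  p <- learner_params(1, 1, lam = 0.9, a0 = 8, b0 = 4)
  s <- list(a = 8, b = 4)
  sds <- numeric(40)
  for (i in 1:40) {
    s <- update_state(s, 0, p, active = FALSE)
    sds[i] <- beta_sd(s$a, s$b)
  }
  expect_true(all(diff(sds) >= -1e-12))
  expect_equal(sds[40], beta_sd(1, 1), tolerance = 1e-3)
})

test_that("stub difficulty composes the creation threshold multiplicatively", {
  # engineered single-state step: surprise lands between the basic threshold
  # and the stubbed compound threshold, so creation must be suppressed
  p <- learner_params(1, 1, 0.95, 2, 2, eta = 2.5)
  states <- list(a = 8, b = 1, S = 0.2, last = -1L, active = 1L)
  sg <- beta_sd(8, 1)
  S_next <- update_surprise(0.2, 0, betastate:::clip01(beta_mode(8, 1),
                                                       0.005), 0.3)
  expect_gt(S_next, sg * 2.5)          # basic threshold crossed
  expect_lt(S_next, sg * 2.5 * 2)      # stubbed q(2) = 2 not crossed
  stub <- step_nstate(states, 0, p, t = 5L, q_table = 1:12)
  expect_equal(stub$event, "update")   # polling zone, no candidate -> keep
  flat <- step_nstate(states, 0, p, t = 5L, q_table = rep(1, 12))
  expect_equal(flat$event, "create")   # without difficulty it would create
})

test_that("trace serialization writes the documented columns", {
  tr <- simulate_learner(rep(1L, 5), learner_params(), "one_state")
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  got <- read.csv(f)
  expect_named(got, c("trial", "p_hat", "sigma", "active_state", "n_states",
                      "surprise", "event"))
  expect_equal(nrow(got), 5)
})
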