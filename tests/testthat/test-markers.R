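test_that("trial-wise learning rates follow the rearranged delta rule", {
  expect_equal(trialwise_learning_rate(0.3, 0.5, 1)$alpha, 0.2 / 0.7)
  # lowering the expectation after a shock is excluded
  ex <- trialwise_learning_rate(0.3, 0.2, 1)
  expect_true(is.na(ex$alpha))
  expect_equal(ex$status, "out_of_range")
  # a full update gives alpha = 1
  expect_equal(trialwise_learning_rate(0.3, 1, 1)$alpha, 1)
  # zero denominator is flagged distinctly
  zd <- trialwise_learning_rate(0.5, 0.7, 0.5)
  expect_true(is.na(zd$alpha))
  expect_equal(zd$status, "zero_denominator")
})

test_that("learning-rate exclusion never removes values inside [0,1]", {
  set.seed(23)
  p <- runif(200); p1 <- runif(200); o <- rbinom(200, 1, 0.5)
  res <- trialwise_learning_rate(p, p1, o)
  raw <- (p1 - p) / (o - p)
  keep <- res$status == "ok"
  expect_true(all(raw[keep] >= 0 & raw[keep] <= 1))
  expect_true(all(is.na(res$alpha[!keep])))
  dropped <- raw[res$status == "out_of_range"]
  expect_true(all(dropped < 0 | dropped > 1))
})

test_that("classification counts meaningful and oddball trials", {
  tt <- data.frame(trial = 0:39, cue = "reversal",
                   phase_idx = rep(1:2, each = 20),
                   phase_type = rep(c("low", "high"), each = 20),
                   p_true = rep(c(0.1, 0.9), each = 20),
                   outcome = rbinom(40, 1, 0.5), stringsAsFactors = FALSE)
  lab <- classify_trials(tt, cutoff = 5)
  expect_equal(sum(lab$label == "unlabeled"), 20)  # first phase
  expect_equal(sum(lab$label == "meaningful"), 5)
  expect_equal(sum(lab$label == "oddball"), 15)
  # cutoff equal to the phase length leaves no oddball trials
  lab20 <- classify_trials(tt, cutoff = 20)
  expect_equal(sum(lab20$label == "oddball"), 0)
})

test_that("classification matches a brute-force loop on random schedules", {
  set.seed(24)
  for (i in 1:20) {
    tt <- random_trial_table()
    for (ct in c(5, 7, 10, 13)) {
      lab <- classify_trials(tt, cutoff = ct)
      rev <- tt[tt$cue == "reversal", ]
      # brute force: walk the reversal stream, reset position on type change
      expected <- character(nrow(rev))
      pos <- 0; cur <- ""; phase_no <- 0
      for (j in seq_len(nrow(rev))) {
        if (rev$phase_type[j] != cur) {
          cur <- rev$phase_type[j]; pos <- 0; phase_no <- phase_no + 1
        }
        pos <- pos + 1
        expected[j] <- if (phase_no == 1) "unlabeled"
          else if (pos <= ct) "meaningful" else "oddball"
      }
      expect_identical(lab$label, expected)
      post <- lab$label[lab$bphase > 1]
      expect_true(all(post %in% c("meaningful", "oddball")))
    }
  }
})

test_that("post-reversal slopes recover exact lines and constants", {
  tt <- data.frame(trial = 0:19, cue = "reversal",
                   phase_idx = rep(1:2, each = 10),
                   phase_type = rep(c("low", "high"), each = 10),
                   p_true = rep(c(0.1, 0.9), each = 10),
                   outcome = 1, stringsAsFactors = FALSE)
  ratings <- c(rep(0.5, 10), seq(0.1, 1, by = 0.1))
  sl <- post_reversal_slope(ratings, tt)
  expect_equal(nrow(sl), 1)
  expect_equal(sl$slope, 10, tolerance = 1e-9)  # %/trial on 0-100 scale
  expect_equal(sl$direction, "low_to_high")
  flat <- post_reversal_slope(c(rep(0.5, 10), rep(0.7, 10)), tt)
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  # fewer than 3 rated trials -> missing
  few <- post_reversal_slope(c(rep(0.5, 10), 0.2, 0.3, rep(NA, 8)), tt)
  expect_true(is.na(few$slope))
})

test_that("stable-window means use only trials at position 10 or later", {
  set.seed(25)
  tt <- random_trial_table(n_phases = 4, len_range = c(20, 30))
  const <- rep(0.7, nrow(tt))
  sw <- stable_window_mean(const, tt)
  expect_equal(unname(sw), c(0.7, 0.7))
  # altering the first 9 post-reversal presentations changes nothing
  r <- tt$rating
  bp <- betastate:::behavioral_phases(tt)
  sw1 <- stable_window_mean(r, tt)
  r2 <- r
  r2[match(bp$trial[bp$pos <= 9], tt$trial)] <- 0.999
  expect_equal(stable_window_mean(r2, tt), sw1)
  # brute-force oracle
  for (i in 1:10) {
    tt <- random_trial_table()
    r <- tt$rating
    bp <- betastate:::behavioral_phases(tt)
    got <- stable_window_mean(r, tt)
    for (ty in c("high", "low")) {
      sel <- bp$pos >= 10 & bp$phase_type == ty
      exp_mean <- if (any(sel))
        mean(r[match(bp$trial[sel], tt$trial)]) else NA_real_
      expect_equal(unname(got[ty]), exp_mean)
    }
  }
})

test_that("reinforcement error subtracts the running mean per group", {
  expect_equal(reinforcement_error(c(1, 1, 1), c(1, 1, 0)), c(0, 0, 1 / 3))
  o <- c(1, 0, 1, 1)
  cm <- cumsum(o) / seq_along(o)
  expect_equal(reinforcement_error(cm, o), rep(0, 4))
  # grouped brute force
  set.seed(26)
  for (i in 1:10) {
    n <- 50
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    o <- rbinom(n, 1, 0.6); r <- runif(n)
    got <- reinforcement_error(r, o, g)
    for (j in seq_len(n)) {
      prior <- which(g == g[j] & seq_len(n) <= j)
      expect_equal(got[j], r[j] - mean(o[prior]))
    }
  }
})

test_that("learning rates match the model's update on noiseless traces", {
  # on a noiseless one-state simulation the marker alpha_t must equal the
  # model's own implied per-trial update fraction
  p <- learner_params(1, 1, lam = 1, a0 = 2, b0 = 2)
  set.seed(27)
  o <- rbinom(40, 1, 0.7)
  tr <- simulate_learner(o, p, "one_state")
  lr <- trialwise_learning_rate(tr$p_hat[-40], tr$p_hat[-1], o[-40])
  implied <- (tr$p_hat[-1] - tr$p_hat[-40]) / (o[-40] - tr$p_hat[-40])
  ok <- lr$status == "ok"
  expect_true(any(ok))
  expect_equal(lr$alpha[ok], implied[ok], tolerance = 1e-12)
})

test_that("marker table is complete and labels by merged behavioral phase", {
  set.seed(28)
  sch <- assemble_schedule(session_spec("90/10", "III"), seed = 41)
  ag <- agent_spec("a1", "switching",
                   learner_params(1, 1, 0.95, 2, 2, eta = 2),
                   noise_kappa = 300, seed = 42)
  tab <- simulate_agent(ag, sch)
  mk <- compute_markers(tab)
  expect_equal(nrow(mk), 1)
  expect_gt(mk$slope_lh, 0)
  expect_lt(mk$slope_hl, 0)
  expect_true(mk$lr_meaningful >= 0 && mk$lr_meaningful <= 1)
  expect_true(mk$lr_oddball >= 0 && mk$lr_oddball <= 1)
  expect_gt(mk$stable_mean_high, mk$stable_mean_low)
  # cutoff sensitivity: means vary smoothly across the documented cutoffs
  ms <- sapply(c(5, 7, 10, 13), function(ct)
    compute_markers(tab, cutoff = ct)$lr_meaningful)
  expect_true(all(is.finite(ms)))
  expect_lt(max(abs(diff(ms))), 0.2)
})
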