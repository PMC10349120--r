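test_that("largest-remainder rounding preserves totals and proportions", {
  for (i in 1:20) {
    n <- sample(10:60, 1)
    p <- c(0.2, 0.2, 0.6)
    counts <- betastate:::largest_remainder(n, p)
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * p) < 1))
  }
})

test_that("a 75/25 high phase realizes 14-16 reversal shocks out of 20", {
  # 40-trial phase with 50% reversal trials at target 0.75
  sp <- session_spec("75/25", "II", phase_len_mean = 40, phase_len_jitter = 0)
  set.seed(8)
  for (i in 1:20) {
    ph <- generate_phase(sp, "high", phase_idx = 1)
    shocks <- sum(ph$outcome[ph$cue == "reversal"])
    expect_equal(sum(ph$cue == "reversal"), 20)
    expect_gte(shocks, 14)
    expect_lte(shocks, 16)
  }
})

test_that("degenerate proportions give an all-reversal, all-shock phase", {
  sp <- session_spec("90/10", "III", p_high = 1, cue_props = c(0, 0, 1),
                     phase_len_mean = 20, phase_len_jitter = 0)
  set.seed(9)
  ph <- generate_phase(sp, "high", 1)
  expect_true(all(ph$cue == "reversal"))
  expect_true(all(ph$outcome == 1))
})

test_that("generated phases always satisfy the per-phase constraints", {
  set.seed(10)
  sp <- session_spec("60/40", "III")
  for (i in 1:200) {
    type <- sample(c("low", "high"), 1)
    ph <- generate_phase(sp, type, phase_idx = 2, flipped = TRUE)
    # rate window per cue
    for (cue in unique(ph$cue)) {
      o <- ph$outcome[ph$cue == cue]
      p <- ph$p_true[ph$cue == cue][1]
      expect_lte(abs(mean(o) - p),
                 betastate:::effective_tol(length(o), p, 0.05) + 1e-9)
    }
    expect_lte(max(rle(ph$cue)$lengths), 3)
    first5 <- ph$outcome[ph$cue == "reversal"][1:5]
    hits <- if (type == "high") sum(first5 == 1) else sum(first5 == 0)
    expect_gte(hits, 3)
  }
})

test_that("style III schedules alternate contingencies strictly", {
  sp <- session_spec("90/10", "III", n_phases = 7, start_high = FALSE)
  s <- assemble_schedule(sp, seed = 2)
  types <- unique(s$trials[, c("phase_idx", "phase_type")])$phase_type
  expect_equal(types, rep(c("low", "high"), length.out = 7))
  expect_true(all(s$flips))
})

test_that("boundary flips occur at the stated probability", {
  sp <- session_spec("75/25", "I", n_phases = 8)
  set.seed(13)
  flips <- unlist(lapply(1:60, function(i)
    assemble_schedule(sp, seed = sample.int(1e6, 1))$flips))
  expect_gt(length(flips), 300)
  expect_lt(abs(mean(flips) - 0.75), 0.08)  # ~3 sigma at this n
})

test_that("assembled schedules pass their own validator", {
  set.seed(14)
  for (lab in c("60/40", "75/25", "90/10")) {
    s <- assemble_schedule(session_spec(lab, "III"),
                           seed = sample.int(1e6, 1))
    expect_true(all(validate_schedule(s)))
  }
})

test_that("identical spec and seed give byte-identical schedules", {
  sp <- session_spec("90/10", "III")
  s1 <- assemble_schedule(sp, seed = 77)
  s2 <- assemble_schedule(sp, seed = 77)
  expect_identical(s1$trials, s2$trials)
  f1 <- tempfile(); f2 <- tempfile()
  write_schedule(s1, f1); write_schedule(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("style III reversal phases average ~21 trials with minimum 15", {
  set.seed(15)
  lens <- unlist(lapply(1:40, function(i) {
    s <- assemble_schedule(session_spec("90/10", "III"),
                           seed = sample.int(1e6, 1))
    tab <- table(s$trials$phase_idx[s$trials$cue == "reversal"])
    as.numeric(tab)
  }))
  expect_gte(min(lens), 15)
  expect_lt(abs(mean(lens) - 21), 1.5)
})

test_that("the validator reports constructed violations", {
  s <- assemble_schedule(session_spec("75/25", "III", n_phases = 6),
                         seed = 21)
  # four consecutive stable_low trials break the run-length check
  bad <- s$trials
  bad$cue[1:4] <- "stable_low"
  bad$p_true[1:4] <- 0.25
  expect_false(validate_schedule(bad)[["max_run_length"]])

  # hand-built two-phase toy schedule: only 2 of the first 5 post-reversal
  # outcomes go in the new direction -> first-five check fails
  toy <- data.frame(
    trial = 0:19, cue = "reversal",
    phase_idx = rep(1:2, each = 10),
    phase_type = rep(c("low", "high"), each = 10),
    p_true = rep(c(0.25, 0.75), each = 10),
    outcome = c(0, 0, 1, 0, 0, 1, 0, 0, 1, 0,
                1, 0, 0, 1, 0, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  v <- validate_schedule(toy)
  expect_false(v[["first_five"]])
  expect_false(v[["n_phases"]])  # 2 phases outside [6, 10]
})

test_that("schedule CSV round-trips", {
  s <- assemble_schedule(session_spec("60/40", "III", n_phases = 6),
                         seed = 5)
  f <- tempfile(fileext = ".csv")
  write_schedule(s, f)
  got <- read_schedule(f)
  expect_equal(got$outcome, s$trials$outcome)
  expect_equal(got$trial[1], 0)
  expect_true(all(validate_schedule(got)[c("per_phase_rate", "first_five")]))
})
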