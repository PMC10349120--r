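#' Session specification for the reversal-learning task
#'
#' Describes one session of the three-cue Pavlovian task: the contingency
#' condition (how far apart the high and low shock probabilities are), the
#' phase-length distribution, the cue proportions, and how phase boundaries
#' behave. The built-in experiment styles reproduce the three study designs:
#' style I (phases of 30 +/- 2 trials, cue proportions 30/30/40, boundaries
#' flip with probability 0.75), style II (30 +/- 5, 25/25/50, 0.75) and
#' style III (35 +/- 10, 20/20/60, boundaries always flip).
#'
#' @param label Session label: `"60/40"`, `"75/25"` or `"90/10"`. Determines
#'   `p_high` unless overridden.
#' @param style Experiment style, `"I"`, `"II"` or `"III"`; sets the phase
#'   length, jitter, cue proportions and switch probability.
#' @param n_phases Number of phases, in \[6, 10\]; `NULL` draws one uniformly
#'   at assembly time.
#' @param start_high Does the reversal cue start in its high-probability
#'   phase? `NULL` draws at random.
#' @param p_high Optional override of the high shock probability (in
#'   (0.5, 1\]).
#' @param phase_len_mean,phase_len_jitter Optional overrides of the phase
#'   length (total trials across cues) and its +/- uniform integer jitter.
#' @param cue_props Optional override of the proportions
#'   (stable-low, stable-high, reversal); must sum to 1.
#' @param switch_prob Optional override of the probability that a phase
#'   boundary flips the reversal cue's contingency.
#' @param retry_budget Rejection-sampling budget per constraint.
#' @return A list of class `"session_spec"`.
#' @export
#' @examples
#' session_spec("90/10", style = "III", n_phases = 7)
session_spec <- function(label = c("75/25", "60/40", "90/10"),
                         style = c("III", "I", "II"), n_phases = NULL,
                         start_high = NULL, p_high = NULL,
                         phase_len_mean = NULL, phase_len_jitter = NULL,
                         cue_props = NULL, switch_prob = NULL,
                         retry_budget = 10000) {
  label <- match.arg(label)
  style <- match.arg(style)
  defaults <- list(
    I   = list(len = 30, jit = 2,  props = c(0.30, 0.30, 0.40), sw = 0.75),
    II  = list(len = 30, jit = 5,  props = c(0.25, 0.25, 0.50), sw = 0.75),
    III = list(len = 35, jit = 10, props = c(0.20, 0.20, 0.60), sw = 1.00)
  )[[style]]
  if (is.null(p_high))
    p_high <- c("60/40" = 0.6, "75/25" = 0.75, "90/10" = 0.9)[[label]]
  if (is.null(phase_len_mean)) phase_len_mean <- defaults$len
  if (is.null(phase_len_jitter)) phase_len_jitter <- defaults$jit
  if (is.null(cue_props)) cue_props <- defaults$props
  if (is.null(switch_prob)) switch_prob <- defaults$sw
  stopifnot(p_high > 0.5, p_high <= 1,
            abs(sum(cue_props) - 1) < 1e-9, length(cue_props) == 3,
            is.null(n_phases) || (n_phases >= 6 && n_phases <= 10),
            switch_prob >= 0, switch_prob <= 1)
  structure(list(label = label, style = style, p_high = p_high,
                 p_low = 1 - p_high, phase_len_mean = phase_len_mean,
                 phase_len_jitter = phase_len_jitter, cue_props = cue_props,
                 switch_prob = switch_prob, n_phases = n_phases,
                 start_high = start_high, retry_budget = retry_budget),
            class = "session_spec")
}

# largest-remainder apportionment of n among proportions p
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

CUES <- c("stable_low", "stable_high", "reversal")

# per-cue target shock probability given the reversal cue's phase type
cue_targets <- function(spec, phase_type) {
  c(stable_low = spec$p_low, stable_high = spec$p_high,
    reversal = if (phase_type == "high") spec$p_high else spec$p_low)
}

# smallest rate deviation an integer shock count can achieve over n trials
min_achievable_dev <- function(n, p) abs(round(n * p) - n * p) / n

# effective tolerance: the +/-5 point window, widened to the nearest
# achievable rate when no integer count falls inside it (tiny phase counts
# in the 90/10 condition make the literal window empty)
effective_tol <- function(n, p, tol) max(tol, min_achievable_dev(n, p))

# draw a 0/1 outcome vector of length n whose realized rate is within the
# effective tolerance of p and (optionally) whose first five entries contain
# >= 3 values equal to `dir`; rejection-sampled
draw_outcomes <- function(n, p, tol, first_five_dir = NULL, budget = 10000) {
  if (n == 0) return(integer(0))
  tol <- effective_tol(n, p, tol)
  lo <- ceiling(n * (p - tol) - 1e-9); hi <- floor(n * (p + tol) + 1e-9)
  if (lo > hi || hi < 0 || lo > n)
    stop(sprintf(paste0("constraint-unsatisfiable: no shock count in ",
                        "[%d, %d] can realize rate %.2f +/- %.2f over %d ",
                        "trials"), lo, hi, p, tol, n))
  for (i in seq_len(budget)) {
    o <- as.integer(stats::runif(n) < p)
    k <- sum(o)
    if (k < lo || k > hi) next
    if (!is.null(first_five_dir)) {
      w <- o[seq_len(min(5, n))]
      hits <- if (first_five_dir == "high") sum(w == 1) else sum(w == 0)
      if (hits < 3) next
    }
    return(o)
  }
  stop("constraint-unsatisfiable: outcome rejection budget exhausted ",
       "(rate window / first-five rule)")
}

# cue order with no cue on > 3 consecutive trials, by shuffle-and-check
draw_cue_sequence <- function(counts, budget = 10000) {
  pool <- rep(CUES, times = counts)
  if (length(unique(pool)) <= 1) return(pool)  # degenerate proportions
  for (i in seq_len(budget)) {
    s <- sample(pool)
    if (max(rle(s)$lengths) <= 3) return(s)
  }
  stop("constraint-unsatisfiable: cue run-length budget exhausted")
}

#' Generate one phase (mini-block) of trials
#'
#' Draws the phase length (`phase_len_mean` +/- uniform integer jitter),
#' apportions trials to the three cues by largest-remainder rounding, and
#' rejection-samples cue order and outcomes until the constraints hold: each
#' cue's realized shock rate within +/- 5 percentage points of its target, no
#' cue on more than three consecutive trials and — for phases following a
#' contingency flip — at least three of the first five reversal-cue outcomes
#' in the new direction.
#'
#' @param spec A [session_spec()].
#' @param phase_type `"low"` or `"high"` — the reversal cue's contingency in
#'   this phase.
#' @param phase_idx 1-based phase index (phase 1 has no first-five
#'   constraint).
#' @param flipped Did the contingency change at the boundary entering this
#'   phase? The first-five rule applies only then.
#' @param tol Rate tolerance in probability points (0.05).
#' @return A data frame of trials: `cue`, `phase_idx`, `phase_type`,
#'   `p_true`, `outcome`.
#' @export
generate_phase <- function(spec, phase_type = c("low", "high"),
                           phase_idx = 1L, flipped = (phase_idx > 1),
                           tol = 0.05) {
  phase_type <- match.arg(phase_type)
  jit <- spec$phase_len_jitter
  len <- spec$phase_len_mean + sample.int(2L * jit + 1L, 1L) - jit - 1L
  counts <- largest_remainder(len, spec$cue_props)
  targets <- cue_targets(spec, phase_type)
  cue_seq <- draw_cue_sequence(counts, spec$retry_budget)
  outcome <- integer(len)
  for (ci in seq_along(CUES)) {
    cue <- CUES[ci]
    ff <- if (cue == "reversal" && phase_idx > 1 && flipped) phase_type else NULL
    outcome[cue_seq == cue] <- draw_outcomes(counts[ci], targets[[cue]], tol,
                                             ff, spec$retry_budget)
  }
  data.frame(cue = cue_seq, phase_idx = as.integer(phase_idx),
             phase_type = phase_type, p_true = unname(targets[cue_seq]),
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Assemble a full session schedule
#'
#' Generates `n_phases` phases and concatenates them. At each boundary the
#' reversal cue's contingency flips with probability `switch_prob` (style III
#' always flips). A second +/- 5 point contingency check is then performed
#' across the whole schedule separately for each cue (the reversal cue's
#' whole-session target mixes the high- and low-phase targets by exposure);
#' the schedule is re-drawn if it fails, within the retry budget.
#'
#' @param spec A [session_spec()].
#' @param seed Optional integer seed; identical `(spec, seed)` yield an
#'   identical schedule.
#' @param tol Rate tolerance (0.05).
#' @return An object of class `"reversal_schedule"`: a list with `spec`,
#'   `trials` (data frame with 0-based `trial` plus the phase columns),
#'   `phase_boundaries` (0-based indices of the first trial of each phase
#'   after the first) and `flips` (logical, per boundary).
#' @export
#' @examples
#' s <- assemble_schedule(session_spec("90/10", "III", n_phases = 6), seed = 1)
#' s
assemble_schedule <- function(spec, seed = NULL, tol = 0.05) {
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      n_phases <- if (is.null(spec$n_phases))
        sample(6:10, 1L) else as.integer(spec$n_phases)
      start_high <- if (is.null(spec$start_high))
        stats::runif(1) < 0.5 else isTRUE(spec$start_high)
      types <- character(n_phases)
      flips <- logical(n_phases - 1L)
      types[1] <- if (start_high) "high" else "low"
      for (k in 2:n_phases) {
        flips[k - 1L] <- stats::runif(1) < spec$switch_prob
        types[k] <- if (flips[k - 1L])
          setdiff(c("low", "high"), types[k - 1L]) else types[k - 1L]
      }
      phases <- lapply(seq_len(n_phases), function(k)
        generate_phase(spec, types[k], k,
                       flipped = (k > 1 && flips[k - 1L]), tol = tol))
      trials <- do.call(rbind, phases)
      trials <- cbind(trial = seq_len(nrow(trials)) - 1L, trials)
      # whole-session check per cue
      ok <- TRUE
      for (cue in CUES) {
        sel <- trials$cue == cue
        if (!any(sel)) next
        p <- mean(trials$p_true[sel])
        if (abs(mean(trials$outcome[sel]) - p) >
            effective_tol(sum(sel), p, tol) + 1e-9) { ok <- FALSE; break }
      }
      if (ok) {
        bounds <- cumsum(vapply(phases, nrow, 1L))
        return(structure(list(spec = spec, trials = trials,
                              phase_boundaries = bounds[-length(bounds)],
                              flips = flips),
                         class = "reversal_schedule"))
      }
    }
    stop("constraint-unsatisfiable: whole-session retry budget exhausted")
  })
}

#' @export
print.reversal_schedule <- function(x, ...) {
  tt <- x$trials
  cat(sprintf("Reversal schedule (%s, style %s): %d trials, %d phases, %d flips\n",
              x$spec$label, x$spec$style, nrow(tt), max(tt$phase_idx),
              sum(x$flips)))
  rates <- tapply(tt$outcome, tt$cue, mean)
  cat("realized shock rates:",
      paste(names(rates), sprintf("%.2f", rates), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a schedule against the task constraints
#'
#' Reports named pass/fail checks; it never raises. Checks: per-phase
#' realized shock rate within +/- 5 points of target for every cue,
#' whole-session rate within +/- 5 points per cue, no cue on more than three
#' consecutive trials, the first-five rule after every contingency flip, and
#' a phase count in \[6, 10\].
#'
#' @param s A `"reversal_schedule"` or a trial data frame with columns
#'   `cue`, `phase_idx`, `phase_type`, `p_true`, `outcome`.
#' @param tol Rate tolerance (0.05).
#' @return A named logical vector: `per_phase_rate`, `session_rate`,
#'   `max_run_length`, `first_five`, `n_phases`.
#' @export
validate_schedule <- function(s, tol = 0.05) {
  tt <- if (inherits(s, "reversal_schedule")) s$trials else s
  checks <- c(per_phase_rate = TRUE, session_rate = TRUE,
              max_run_length = TRUE, first_five = TRUE, n_phases = TRUE)
  for (ph in unique(tt$phase_idx)) {
    sub <- tt[tt$phase_idx == ph, ]
    for (cue in unique(sub$cue)) {
      o <- sub$outcome[sub$cue == cue]
      p <- sub$p_true[sub$cue == cue][1]
      if (abs(mean(o) - p) > effective_tol(length(o), p, tol) + 1e-9)
        checks["per_phase_rate"] <- FALSE
    }
    if (max(rle(sub$cue)$lengths) > 3) checks["max_run_length"] <- FALSE
  }
  for (cue in unique(tt$cue)) {
    sel <- tt$cue == cue
    p <- mean(tt$p_true[sel])
    if (abs(mean(tt$outcome[sel]) - p) >
        effective_tol(sum(sel), p, tol) + 1e-9)
      checks["session_rate"] <- FALSE
  }
  # first-five rule at every boundary where the contingency flipped
  phases <- unique(tt[, c("phase_idx", "phase_type")])
  phases <- phases[order(phases$phase_idx), ]
  if (nrow(phases) >= 2) {
    for (k in 2:nrow(phases)) {
      if (phases$phase_type[k] == phases$phase_type[k - 1]) next
      o <- tt$outcome[tt$cue == "reversal" &
                      tt$phase_idx == phases$phase_idx[k]]
      w <- o[seq_len(min(5, length(o)))]
      hits <- if (phases$phase_type[k] == "high") sum(w == 1) else sum(w == 0)
      if (hits < 3) checks["first_five"] <- FALSE
    }
  }
  np <- length(unique(tt$phase_idx))
  checks["n_phases"] <- np >= 6 && np <= 10
  checks
}

#' Write / read a schedule as CSV
#'
#' Columns `trial,cue,phase_idx,phase_type,p_true,outcome` (0-based trial
#' index, UTF-8, comma-delimited).
#'
#' @param s A `"reversal_schedule"`.
#' @param path File path.
#' @return `write_schedule` returns the path invisibly; `read_schedule`
#'   returns the trial data frame.
#' @export
write_schedule <- function(s, path) {
  utils::write.csv(s$trials[, c("trial", "cue", "phase_idx", "phase_type",
                                "p_true", "outcome")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
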