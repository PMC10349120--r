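#' Trial-wise model-free learning rate
#'
#' Rearranges the delta rule: `alpha_t = (P_{t+1} - P_t) / (O_t - P_t)`.
#' Values outside \[0, 1\] (e.g. lowering the expectation after a shock) are
#' excluded, as are zero-denominator cases (`O_t == P_t`), each with a
#' distinct flag. Vectorised over trials.
#'
#' @param p_t Rating before the outcome, in \[0, 1\].
#' @param p_t1 Rating on the next trial of the same cue.
#' @param o_t Outcome 0/1.
#' @return A data frame with `alpha` (`NA` when excluded) and `status`
#'   (`"ok"`, `"out_of_range"`, `"zero_denominator"`).
#' @export
#' @examples
#' trialwise_learning_rate(0.3, 0.5, 1)   # 0.2857...
#' trialwise_learning_rate(0.3, 0.2, 1)   # excluded (negative)
trialwise_learning_rate <- function(p_t, p_t1, o_t) {
  denom <- o_t - p_t
  alpha <- ifelse(denom == 0, NA_real_, (p_t1 - p_t) / denom)
  status <- ifelse(denom == 0, "zero_denominator",
                   ifelse(is.na(alpha) | alpha < 0 | alpha > 1,
                          "out_of_range", "ok"))
  alpha[status != "ok"] <- NA_real_
  data.frame(alpha = alpha, status = status, stringsAsFactors = FALSE)
}

# Behavioral phases of the reversal cue: consecutive schedule phases with the
# same contingency are merged (a boundary that does not flip is invisible to
# the participant). Returns, per reversal-cue trial (in trial order):
# bphase (1-based), pos (1-based position within bphase) and the phase type.
behavioral_phases <- function(trials) {
  rev <- trials[trials$cue == "reversal", , drop = FALSE]
  rev <- rev[order(rev$trial), , drop = FALSE]
  if (!nrow(rev))
    return(data.frame(trial = integer(0), bphase = integer(0),
                      pos = integer(0), phase_type = character(0)))
  r <- rle(rev$phase_type)
  bphase <- rep(seq_along(r$lengths), r$lengths)
  pos <- unlist(lapply(r$lengths, seq_len), use.names = FALSE)
  data.frame(trial = rev$trial, bphase = bphase, pos = pos,
             phase_type = rev$phase_type, stringsAsFactors = FALSE)
}

#' Classify reversal-cue trials as meaningful or oddball
#'
#' Within each post-reversal phase, the first `cutoff` reversal-cue
#' presentations are `"meaningful"` (updating is adaptive there) and later
#' presentations are `"oddball"` (surprising outcomes should be
#' discounted). The first phase is `"unlabeled"` — no reversal precedes it.
#' Cutoffs 5 (default), 7, 10 and 13 support the sensitivity analysis.
#'
#' @param sched A `"reversal_schedule"` or trial data frame.
#' @param cutoff Post-reversal cutoff in reversal-cue presentations.
#' @return A data frame with `trial`, `bphase`, `pos`, `phase_type`,
#'   `label` for every reversal-cue trial.
#' @export
classify_trials <- function(sched, cutoff = 5) {
  tt <- if (inherits(sched, "reversal_schedule")) sched$trials else sched
  bp <- behavioral_phases(tt)
  bp$label <- ifelse(bp$bphase == 1, "unlabeled",
                     ifelse(bp$pos <= cutoff, "meaningful", "oddball"))
  bp
}

#' Post-reversal slope of probability ratings
#'
#' Ordinary least-squares slope of the rating (on the 0-100 scale) on the
#' within-phase reversal-cue presentation index over the first `window`
#' presentations of every post-reversal phase — the period of change.
#' Phases with fewer than 3 rated trials in the window yield `NA`.
#'
#' @param ratings Ratings in \[0, 1\] aligned with the schedule's trials
#'   (`NA` on unrated trials).
#' @param sched A `"reversal_schedule"` or trial data frame.
#' @param window Number of post-reversal presentations fitted (default 10).
#' @return A data frame per post-reversal phase: `bphase`, `direction`
#'   (`"low_to_high"` / `"high_to_low"`), `slope` (% per trial), `n_rated`.
#' @export
post_reversal_slope <- function(ratings, sched, window = 10) {
  tt <- if (inherits(sched, "reversal_schedule")) sched$trials else sched
  stopifnot(length(ratings) == nrow(tt))
  bp <- behavioral_phases(tt)
  bp$rating <- ratings[match(bp$trial, tt$trial)]
  out <- lapply(setdiff(unique(bp$bphase), 1L), function(k) {
    sub <- bp[bp$bphase == k & bp$pos <= window, ]
    ok <- !is.na(sub$rating)
    slope <- if (sum(ok) >= 3)
      unname(stats::coef(stats::lm(I(rating * 100) ~ pos, data = sub))[2])
    else NA_real_
    data.frame(bphase = k,
               direction = if (sub$phase_type[1] == "high")
                 "low_to_high" else "high_to_low",
               slope = slope, n_rated = sum(ok), stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(bphase = integer(0), direction = character(0),
                      slope = numeric(0), n_rated = integer(0)))
  do.call(rbind, out)
}

#' Stable-window mean ratings
#'
#' Mean rating over reversal-cue presentations at within-phase position
#' `from_trial` or later (the window from which ratings have stabilised),
#' split by phase type.
#'
#' @inheritParams post_reversal_slope
#' @param from_trial First within-phase presentation included (default 10).
#' @return Named vector `c(high = ..., low = ...)`; `NA` when no trial
#'   qualifies.
#' @export
stable_window_mean <- function(ratings, sched, from_trial = 10) {
  tt <- if (inherits(sched, "reversal_schedule")) sched$trials else sched
  stopifnot(length(ratings) == nrow(tt))
  bp <- behavioral_phases(tt)
  bp$rating <- ratings[match(bp$trial, tt$trial)]
  sub <- bp[bp$pos >= from_trial, ]
  c(high = if (any(sub$phase_type == "high"))
      mean(sub$rating[sub$phase_type == "high"], na.rm = TRUE) else NA_real_,
    low = if (any(sub$phase_type == "low"))
      mean(sub$rating[sub$phase_type == "low"], na.rm = TRUE) else NA_real_)
}

#' Error from the running reinforcement rate
#'
#' Within each group (e.g. cue, or cue-by-phase-type), the running mean of
#' the delivered outcomes estimates the true shock probability; the error is
#' the rating minus that running mean (positive = overestimation).
#'
#' @param ratings Ratings in \[0, 1\].
#' @param outcomes Aligned 0/1 outcomes.
#' @param group Grouping factor/vector (same length); `NULL` for a single
#'   group.
#' @return Numeric vector of per-trial errors.
#' @export
#' @examples
#' reinforcement_error(c(1, 1, 1), c(1, 1, 0))  # 0, 0, 1/3
reinforcement_error <- function(ratings, outcomes, group = NULL) {
  stopifnot(length(ratings) == length(outcomes))
  if (is.null(group)) group <- rep(1L, length(ratings))
  err <- rep(NA_real_, length(ratings))
  for (g in unique(group)) {
    sel <- which(group == g)
    cm <- cumsum(outcomes[sel]) / seq_along(sel)
    err[sel] <- ratings[sel] - cm
  }
  err
}

#' Model-free marker table for a cohort
#'
#' Computes the per-participant/session behavioural markers on the reversal
#' cue: post-reversal slopes by switch direction and their mean magnitude,
#' meaningful and oddball trial-wise learning rates (raw and
#' log-transformed, natural log of values clipped below at 1e-3), their
#' difference, and stable-window mean ratings per phase type.
#'
#' @param trials A cohort trial data frame (columns `agent_id`, `session`,
#'   `trial`, `cue`, `phase_idx`, `phase_type`, `outcome`, `rating`) or a
#'   single-session table without id columns.
#' @param cutoff Meaningful/oddball cutoff (default 5; 7, 10, 13 supported
#'   for the sensitivity analysis).
#' @param slope_window Post-reversal window for the slope fit.
#' @param stable_from First within-phase presentation of the stable window.
#' @return A data frame, one row per agent x session, with columns
#'   `slope_lh`, `slope_hl`, `abs_slope`, `lr_meaningful`, `lr_oddball`,
#'   `lr_diff`, `log_lr_meaningful`, `log_lr_oddball`,
#'   `stable_mean_high`, `stable_mean_low` and, when present in the input,
#'   `ta_score`.
#' @export
compute_markers <- function(trials, cutoff = 5, slope_window = 10,
                            stable_from = 10) {
  if (!"agent_id" %in% names(trials)) trials$agent_id <- "agent"
  if (!"session" %in% names(trials)) trials$session <- "session"
  groups <- unique(trials[, c("agent_id", "session")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    tt <- trials[trials$agent_id == groups$agent_id[i] &
                 trials$session == groups$session[i], , drop = FALSE]
    tt <- tt[order(tt$trial), ]
    sl <- post_reversal_slope(tt$rating, tt, window = slope_window)
    lab <- classify_trials(tt, cutoff = cutoff)
    rev <- tt[tt$cue == "reversal", ]
    rev <- rev[order(rev$trial), ]
    n <- nrow(rev)
    lr <- if (n >= 2)
      cbind(trialwise_learning_rate(rev$rating[-n], rev$rating[-1],
                                    rev$outcome[-n]),
            label = lab$label[-n])
    else data.frame(alpha = numeric(0), status = character(0),
                    label = character(0))
    mean_lr <- function(l) {
      a <- lr$alpha[lr$label == l & lr$status == "ok"]
      if (length(a)) mean(a) else NA_real_
    }
    mean_log_lr <- function(l) {
      a <- lr$alpha[lr$label == l & lr$status == "ok"]
      if (length(a)) mean(log(pmax(a, 1e-3))) else NA_real_
    }
    sw <- stable_window_mean(tt$rating, tt, from_trial = stable_from)
    dir_mean <- function(d) {
      s <- sl$slope[sl$direction == d]
      if (any(!is.na(s))) mean(s, na.rm = TRUE) else NA_real_
    }
    data.frame(agent_id = groups$agent_id[i], session = groups$session[i],
               slope_lh = dir_mean("low_to_high"),
               slope_hl = dir_mean("high_to_low"),
               abs_slope = if (any(!is.na(sl$slope)))
                 mean(abs(sl$slope), na.rm = TRUE) else NA_real_,
               lr_meaningful = mean_lr("meaningful"),
               lr_oddball = mean_lr("oddball"),
               lr_diff = mean_lr("meaningful") - mean_lr("oddball"),
               log_lr_meaningful = mean_log_lr("meaningful"),
               log_lr_oddball = mean_log_lr("oddball"),
               stable_mean_high = sw[["high"]],
               stable_mean_low = sw[["low"]],
               ta_score = if ("ta_score" %in% names(tt))
                 tt$ta_score[1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
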