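# Independent brute-force oracles. These re-derive the learner semantics and
# the marker definitions with plain loops and inline formulas, on purpose not
# reusing the package's engine, so that implementation and oracle can disagree.

oracle_mode <- function(a, b) if (a + b == 2) 0.5 else (a - 1) / (a + b - 2)
oracle_sd <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))

oracle_clip <- function(x, eps) min(max(x, eps), 1 - eps)

oracle_update <- function(a, b, o, active, tp, tm, lam, cap) {
  if (active) {
    if (o == 1) { a <- lam * (a + tp); b <- lam * b }
    else { b <- lam * (b + tm); a <- lam * a }
  } else { a <- lam * a; b <- lam * b }
  a <- max(a, 1); b <- max(b, 1)
  if (a + b > cap) {
    f <- cap / (a + b); a <- a * f; b <- b * f
    if (a < 1) { a <- 1; b <- cap - 1 } else if (b < 1) { b <- 1; a <- cap - 1 }
  }
  c(a, b)
}

# plain-loop forward pass of the n-state learner (one-state when eta = NULL)
oracle_forward <- function(outcomes, p, q_table, pi_s = 0.3, cap = 30,
                           eps = 0.005) {
  nst <- !is.null(p$eta)
  a <- p$a0; b <- p$b0; S <- 0; last <- -1; act <- 1
  sd0 <- oracle_sd(p$a0, p$b0)
  T <- length(outcomes)
  p_hat <- sigma <- a_pre <- b_pre <- numeric(T)
  event <- character(T); nstates <- integer(T)
  for (t in seq_len(T)) {
    m <- oracle_clip(oracle_mode(a[act], b[act]), eps)
    sg <- oracle_sd(a[act], b[act])
    p_hat[t] <- m; sigma[t] <- sg; a_pre[t] <- a[act]; b_pre[t] <- b[act]
    O <- outcomes[t]
    S[act] <- (1 - pi_s) * S[act] + pi_s * abs(O - m)
    Sa <- S[act]; last[act] <- t - 1
    K <- length(a)
    for (j in seq_len(K)) {
      ab <- oracle_update(a[j], b[j], O, j == act, p$tau_plus, p$tau_minus,
                          p$lam, cap)
      a[j] <- ab[1]; b[j] <- ab[2]
    }
    ev <- "update"
    if (nst) {
      thr <- sg * p$eta
      if (Sa > thr) {
        q <- q_table[min(K + 1, length(q_table))]
        E <- oracle_clip(m + sign(O - m) * Sa, eps)
        best <- 0; bestd <- -1
        for (j in seq_len(K)) {
          if (abs(oracle_mode(a[j], b[j]) - E) <= thr) {
            d <- dbeta(E, a[j], b[j])
            if (d > bestd || (d == bestd && best > 0 &&
                              last[j] > last[best])) { bestd <- d; best <- j }
          }
        }
        if (Sa <= thr * q) {
          if (best > 0 && best != act) { act <- best; ev <- "switch" }
        } else if (best > 0) {
          if (best != act) { act <- best; ev <- "switch" }
        } else {
          # bisection for the concentration matching the starting SD
          lo <- 0; hi <- cap - 2
          f <- function(c) oracle_sd(1 + E * c, 1 + (1 - E) * c)
          if (f(hi) >= sd0) { cc <- hi } else {
            for (i in 1:100) {
              mid <- (lo + hi) / 2
              if (f(mid) > sd0) lo <- mid else hi <- mid
            }
            cc <- (lo + hi) / 2
          }
          a <- c(a, 1 + E * cc); b <- c(b, 1 + (1 - E) * cc)
          S <- c(S, 0); last <- c(last, -1)
          act <- length(a); ev <- "create"
        }
      }
    }
    event[t] <- ev; nstates[t] <- length(a)
  }
  list(p_hat = p_hat, sigma = sigma, a_pre = a_pre, b_pre = b_pre,
       event = event, n_states = nstates)
}

oracle_nll <- function(outcomes, ratings, p, q_table, eps = 0.005) {
  fw <- oracle_forward(outcomes, p, q_table, eps = eps)
  s <- 0
  for (t in seq_along(outcomes)) {
    r <- ratings[t]
    if (is.na(r)) next
    s <- s - dbeta(min(max(r, eps), 1 - eps), fw$a_pre[t], fw$b_pre[t],
                   log = TRUE)
  }
  s
}

random_params <- function(nstate = FALSE) {
  learner_params(tau_plus = runif(1, 0.1, 2), tau_minus = runif(1, 0.1, 2),
                 lam = runif(1, 0.8, 0.999), a0 = runif(1, 1, 6),
                 b0 = runif(1, 1, 6),
                 eta = if (nstate) exp(runif(1, log(0.5), log(6))) else NULL)
}

# small random schedule-like trial table for marker oracles
random_trial_table <- function(n_phases = 4, len_range = c(8, 25)) {
  types <- rep(c("low", "high"), length.out = n_phases)
  if (runif(1) < 0.5) types <- rev(types)
  rows <- lapply(seq_len(n_phases), function(k) {
    n <- sample(seq(len_range[1], len_range[2]), 1)
    cue <- sample(c("reversal", "stable_low", "stable_high"), n,
                  replace = TRUE, prob = c(0.6, 0.2, 0.2))
    p <- ifelse(cue == "reversal",
                ifelse(types[k] == "high", 0.9, 0.1),
                ifelse(cue == "stable_high", 0.9, 0.1))
    data.frame(cue = cue, phase_idx = k, phase_type = types[k], p_true = p,
               outcome = rbinom(n, 1, p), stringsAsFactors = FALSE)
  })
  tt <- do.call(rbind, rows)
  tt <- cbind(trial = seq_len(nrow(tt)) - 1L, tt)
  tt$rating <- pmin(pmax(rbeta(nrow(tt), 2, 2), 0.005), 0.995)
  tt
}
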