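#' @export
print.beta_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Beta-belief learner fit (%s model)\n",
              gsub("_", "-", x$model)))
  cat(sprintf("  %d rated trials, %d parameters, %d restarts\n",
              x$n_trials, x$n_params, x$n_restarts))
  cat("  parameters:\n")
  print(round(x$par, digits))
  cat(sprintf("  nll = %.4f, BIC = %.4f\n", x$nll, x$bic))
  invisible(x)
}

#' @export
summary.beta_fit <- function(object, ...) {
  tr <- object$trace
  structure(list(fit = object,
                 n_states = max(tr$n_states),
                 n_switch = sum(tr$event == "switch"),
                 n_create = sum(tr$event == "create"),
                 restart_spread = stats::quantile(
                   object$restarts$nll[is.finite(object$restarts$nll)],
                   c(0, 0.5, 1)),
                 rmse = sqrt(mean((object$ratings - tr$p_hat)^2,
                                  na.rm = TRUE))),
            class = "summary.beta_fit")
}

#' @export
print.summary.beta_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  states used: %d (%d switch, %d create events)\n",
              x$n_states, x$n_switch, x$n_create))
  cat(sprintf("  rating RMSE around prediction: %.3f\n", x$rmse))
  cat("  restart nll spread (min / median / max):",
      paste(sprintf("%.3f", x$restart_spread), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.beta_fit <- function(object, ...) object$par

#' @export
logLik.beta_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, nobs = object$n_trials,
            class = "logLik")
}

#' @export
nobs.beta_fit <- function(object, ...) object$n_trials

#' Predicted shock probabilities from a fitted learner
#'
#' Returns the trial-wise predicted probability (the belief mode before each
#' outcome) for the fitted outcome sequence, or forward-simulates the fitted
#' parameters on a new outcome sequence.
#'
#' @param object A `"beta_fit"`.
#' @param newdata Optional new 0/1 outcome vector.
#' @param ... Unused.
#' @return A numeric vector of predicted probabilities.
#' @export
predict.beta_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$trace$p_hat)
  simulate_learner(newdata, object$params, object$model,
                   object$constants)$p_hat
}

#' @export
fitted.beta_fit <- function(object, ...) object$trace$p_hat

#' @export
residuals.beta_fit <- function(object, ...) {
  object$ratings - object$trace$p_hat
}

#' Simulate rating sequences from a fitted learner
#'
#' Draws synthetic rating sequences from the fitted model: the forward
#' prediction on the fitted outcome sequence plus mode-parameterised beta
#' response noise with concentration `kappa`.
#'
#' @param object A `"beta_fit"`.
#' @param nsim Number of sequences.
#' @param seed Optional seed.
#' @param kappa Response-noise concentration (larger = less noise).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of ratings.
#' @export
simulate.beta_fit <- function(object, nsim = 1, seed = NULL, kappa = 200,
                              ...) {
  m <- object$trace$p_hat
  eps <- object$constants$prob_clip
  with_seed(seed, {
    out <- replicate(nsim,
                     clip01(stats::rbeta(length(m), 1 + m * kappa,
                                         1 + (1 - m) * kappa), eps))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' Plot a fitted learner's trace
#'
#' Plots observed ratings against the model's trial-wise prediction, with
#' switch/create events marked.
#'
#' @param x A `"beta_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.beta_fit <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$trial, x$ratings, col = "grey50", pch = 16, cex = 0.6,
                 ylim = c(0, 1), xlab = "trial",
                 ylab = "shock probability", ...)
  graphics::lines(tr$trial, tr$p_hat, col = "firebrick", lwd = 2)
  graphics::points(tr$trial[tr$outcome == 1],
                   rep(1.0, sum(tr$outcome == 1)), pch = "|", col = "black")
  ev <- tr$trial[tr$event != "update"]
  if (length(ev)) graphics::abline(v = ev, col = "steelblue", lty = 3)
  graphics::legend("bottomright", bty = "n", lwd = c(NA, 2, NA),
                   pch = c(16, NA, NA), lty = c(NA, 1, 3),
                   col = c("grey50", "firebrick", "steelblue"),
                   legend = c("rating", "model", "switch/create"))
  invisible(x)
}
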