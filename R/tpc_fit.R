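#' Fit a temporal predictive coding filter to an observation sequence
#'
#' The main user-facing entry point.  Runs a tPC network along a sequence of
#' observations, optionally learning the transition and emission weights
#' online by Hebbian plasticity, and returns a fitted object with the usual
#' accessor methods (`print`, `summary`, `coef`, `fitted`, `predict`,
#' `residuals`, `plot`).
#'
#' When no `model` is given, weights are initialised for learning: `A = 0`
#' and `C` an identity rectangle (ones on the main diagonal), with identity
#' precisions.
#'
#' @param y Observations: an `N` by `dy` matrix (or a `tpc_trajectory`, in
#'   which case its observations, controls and -- for state-level scoring --
#'   true states are used).
#' @param u Optional controls (`N` x `du`).
#' @param model Optional [tpc_model()] or [state_space_model()] supplying the
#'   weights (a state-space model is converted with [as_tpc_model()], i.e.
#'   treated as the true-parameter network).
#' @param dx Latent dimension when `model` is missing (default `dy`).
#' @param f Nonlinearity for the default-initialised network.
#' @param learn Learn the weights online (default `TRUE` when `model` is
#'   missing, `FALSE` otherwise).
#' @param learn_A,learn_B,learn_C Which weights to learn (defaults: `A` and
#'   `C` when `learn` is `TRUE`).
#' @param states Optional true states (`N` x `dx`) for `mse_state` scoring.
#' @param inference_steps,step_size,eta,lambda_x,lambda_C,convergence_tol,seed
#'   Hyper-parameters, see [tpc_config()].
#' @return An object of class `c("tpc", "tpc_filter_result")`.
#' @examples
#' ssm <- make_tracking_model(seed = 1)
#' tr <- simulate(ssm, N = 200, controls = make_control_sequence(200), seed = 2)
#' fit <- tpc(tr, model = ssm, learn = FALSE)
#' fit
#' coef(fit)$A
#' @export
tpc <- function(y, u = NULL, model = NULL, dx = NULL,
                f = c("linear", "tanh"), learn = is.null(model),
                learn_A = learn, learn_B = FALSE, learn_C = learn,
                states = NULL,
                inference_steps = 20, step_size = 0.2, eta = 1e-4,
                lambda_x = 0, lambda_C = 0, convergence_tol = NULL,
                seed = NULL) {
  f <- match.arg(f)
  cl <- match.call()
  if (inherits(y, "tpc_trajectory")) {
    traj <- y
  } else {
    y <- as.matrix(y)
    N <- nrow(y)
    u <- if (is.null(u)) matrix(0, N, 1) else as.matrix(u)
    states <- if (is.null(states)) matrix(NA_real_, N, 0) else
      as.matrix(states)
    if (nrow(states) == 0) states <- matrix(NA_real_, N, 1)
    traj <- structure(list(states = states, observations = y, controls = u,
                           N = N, x0 = NULL), class = "tpc_trajectory")
  }
  dy <- ncol(traj$observations)
  if (is.null(model)) {
    dx <- dx %||% dy
    C0 <- diag(1, dy, dx)
    model <- tpc_model(A = matrix(0, dx, dx), C = C0,
                       B = matrix(0, dx, ncol(traj$controls)), f = f,
                       learn_A = learn_A, learn_B = learn_B,
                       learn_C = learn_C)
  } else {
    if (inherits(model, "state_space_model")) model <- as_tpc_model(model)
    model$learn_A <- learn_A && learn
    model$learn_B <- learn_B && learn
    model$learn_C <- learn_C && learn
  }
  cfg <- tpc_config(inference_steps = inference_steps,
                    step_size = step_size, eta = eta, lambda_x = lambda_x,
                    lambda_C = lambda_C, convergence_tol = convergence_tol,
                    seed = seed)
  res <- filter_sequence(model, traj, cfg, learn = learn)
  res$call <- cl
  res$observations <- traj$observations
  res$learn <- learn
  class(res) <- c("tpc", class(res))
  res
}

#' @export
print.tpc <- function(x, ...) {
  cat("Temporal predictive coding filter\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("N = %d steps, %s weights, %d inference step(s), step size %g\n",
              x$N, if (isTRUE(x$learn)) "learnt" else "fixed",
              x$config$inference_steps, x$config$step_size))
  cat(sprintf("one-step observation MSE: %.5g\n", x$mse_observation))
  if (is.finite(x$mse_state))
    cat(sprintf("state MSE vs true states: %.5g\n", x$mse_state))
  invisible(x)
}

#' @export
summary.tpc <- function(object, ...) {
  structure(list(N = object$N, learn = object$learn,
                 config = object$config,
                 mse_state = object$mse_state,
                 mse_observation = object$mse_observation,
                 free_energy = summary(object$free_energy_trace),
                 A = object$model$A, C = object$model$C),
            class = "summary.tpc")
}

#' @export
print.summary.tpc <- function(x, ...) {
  cat(sprintf("tPC filter over N = %d steps (%s weights)\n", x$N,
              if (isTRUE(x$learn)) "learnt" else "fixed"))
  cat(sprintf("mse_observation = %.5g; mse_state = %.5g\n",
              x$mse_observation, x$mse_state))
  cat("final free energy per step:\n"); print(x$free_energy)
  cat("A (final):\n"); print(signif(x$A, 4))
  invisible(x)
}

#' @export
coef.tpc <- function(object, ...) {
  list(A = object$model$A, B = object$model$B, C = object$model$C)
}

#' @export
fitted.tpc <- function(object, ...) object$predicted_observations

#' @export
residuals.tpc <- function(object, ...) {
  object$observations - object$predicted_observations
}

#' Predict from a fitted tPC filter
#'
#' Without new data, returns the recorded one-step-ahead observation
#' predictions.  With `n_ahead > 0`, rolls the learnt dynamics forward from
#' the final state estimate without further observations (open loop).
#'
#' @param object A fitted [tpc()] object.
#' @param n_ahead Number of steps to forecast beyond the sequence end.
#' @param u Optional future controls (`n_ahead` x `du`).
#' @param ... Unused.
#' @return A matrix of observation predictions.
#' @export
predict.tpc <- function(object, n_ahead = 0, u = NULL, ...) {
  if (n_ahead == 0) return(object$predicted_observations)
  m <- object$model
  u <- if (is.null(u)) matrix(0, n_ahead, m$du) else as.matrix(u)
  out <- matrix(0, n_ahead, m$dy)
  for (k in seq_len(n_ahead)) {
    fp <- forward_predict(m, u[k, ])
    out[k, ] <- fp$y_pred
    m$x_prev <- fp$x_pred
  }
  out
}

#' Plot a fitted tPC filter
#'
#' Observed versus one-step-predicted observations for a chosen dimension,
#' with the free-energy trace below.
#'
#' @param x A fitted [tpc()] object.
#' @param dim Observation dimension to display.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.tpc <- function(x, dim = 1, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(cbind(x$observations[, dim],
                          x$predicted_observations[, dim]),
                    type = "l", lty = c(1, 2), col = c("grey40", "red"),
                    xlab = "k", ylab = paste0("y_", dim), ...)
  graphics::legend("topleft", c("observed", "predicted"), lty = c(1, 2),
                   col = c("grey40", "red"), bty = "n")
  graphics::plot(x$free_energy_trace, type = "l", xlab = "k",
                 ylab = "free energy")
  invisible(x)
}
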