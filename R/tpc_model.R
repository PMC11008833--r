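#' Temporal predictive coding network
#'
#' Holds the (possibly learnable) weights of a temporal predictive coding
#' network: recurrent transition weights `A`, control weights `B`, emission
#' weights `C`, the state and observation precisions `Pi_x = Sigma_x^-1` and
#' `Pi_y = Sigma_y^-1`, the nonlinearity `f`, and the carried previous
#' estimate `x_prev` (the activity of the neurons that memorise the latent
#' state inferred at the previous step).
#'
#' Precisions default to the identity; learnt configurations typically keep
#' them at identity and let `A` and `C` absorb the noise structure.
#'
#' @param A,B,C Weight matrices (see [state_space_model()] for shapes); `B`
#'   defaults to a zero column.
#' @param Pi_x,Pi_y Precision matrices (symmetric positive definite);
#'   identity by default.
#' @param f Nonlinearity, `"linear"` or `"tanh"`.
#' @param x_prev Initial previous estimate (zero vector by default).
#' @param learn_A,learn_B,learn_C Which weights receive Hebbian updates.
#' @return An object of class `tpc_model`.
#' @seealso [as_tpc_model()], [filter_sequence()], [tpc()]
#' @export
tpc_model <- function(A, C, B = NULL, Pi_x = NULL, Pi_y = NULL,
                      f = c("linear", "tanh"), x_prev = NULL,
                      learn_A = FALSE, learn_B = FALSE, learn_C = FALSE) {
  f <- match.arg(f)
  A <- as.matrix(A); C <- as.matrix(C)
  if (!is_square(A)) stop_config("A must be square")
  dx <- nrow(A)
  if (is.null(B)) B <- matrix(0, dx, 1)
  B <- as.matrix(B)
  if (ncol(C) != dx || nrow(B) != dx)
    stop_config("inconsistent weight shapes")
  dy <- nrow(C)
  Pi_x <- if (is.null(Pi_x)) diag(dx) else as.matrix(Pi_x)
  Pi_y <- if (is.null(Pi_y)) diag(dy) else as.matrix(Pi_y)
  check_spd(Pi_x, "Pi_x"); check_spd(Pi_y, "Pi_y")
  x_prev <- if (is.null(x_prev)) numeric(dx) else
    as_num_vec(x_prev, dx, "x_prev")
  structure(list(A = A, B = B, C = C, Pi_x = Pi_x, Pi_y = Pi_y, f = f,
                 x_prev = x_prev, dx = dx, du = ncol(B), dy = dy,
                 learn_A = learn_A, learn_B = learn_B, learn_C = learn_C),
            class = "tpc_model")
}

#' @export
print.tpc_model <- function(x, ...) {
  cat(sprintf("tPC model (%s f): dx = %d, du = %d, dy = %d; learns:%s\n",
              x$f, x$dx, x$du, x$dy,
              paste0(c(" A", " B", " C")[c(x$learn_A, x$learn_B, x$learn_C)],
                     collapse = "") |> (\(s) if (nzchar(s)) s else " none")()))
  invisible(x)
}

#' Convert a generative model to a tPC network with matched parameters
#'
#' The returned network carries the generative weights and the *inverted*
#' noise covariances as precisions, i.e. the "true-parameter" network.
#'
#' @param model A [state_space_model()].
#' @param ... Passed on to [tpc_model()] (e.g. `learn_A`).
#' @return A [tpc_model()].
#' @export
as_tpc_model <- function(model, ...) {
  tpc_model(A = model$A, C = model$C, B = model$B,
            Pi_x = solve(model$Sigma_x), Pi_y = solve(model$Sigma_y),
            f = model$f, ...)
}

#' Inference and learning hyper-parameters
#'
#' @param inference_steps Gradient iterations per observation (`>= 1`;
#'   `Inf` requests the analytic equilibrium, linear models only).
#' @param step_size Euler step `dt/tau` of the inference dynamics (`> 0`).
#'   Must be below [max_stable_step_size()] of the model for convergence.
#' @param eta Hebbian learning rate (`>= 0`).
#' @param normalize_eta Scale the per-step learning rate by
#'   `1 / (1 + ||f(xhat_k)||^2 + ||f(xhat_{k-1})||^2 + ||u_k||^2)` (the
#'   normalised-LMS rule).  Plain Hebbian SGD is only stable while
#'   `eta * ||activity||^2` stays small, so on systems whose latent scale is
#'   not known in advance the normalised rule is the standard safeguard;
#'   `eta` is then a dimensionless rate of order 0.1-1.
#' @param lambda_x,lambda_C L1 sparsity weights on latent activities and on
#'   the emission weights (used by the sparse variant).
#' @param convergence_tol Optional sup-norm tolerance on the inference update
#'   for early stopping.
#' @param seed Seed governing any randomness in routines taking this config.
#' @return An object of class `tpc_config`.
#' @export
tpc_config <- function(inference_steps = 20, step_size = 0.2, eta = 1e-4,
                       normalize_eta = FALSE, lambda_x = 0, lambda_C = 0,
                       convergence_tol = NULL, seed = NULL) {
  if (!is.infinite(inference_steps) && inference_steps < 1)
    stop_config("inference_steps must be >= 1")
  if (step_size <= 0) stop_config("step_size must be > 0")
  if (eta < 0 || lambda_x < 0 || lambda_C < 0)
    stop_config("eta and lambdas must be >= 0")
  structure(list(inference_steps = inference_steps, step_size = step_size,
                 eta = eta, normalize_eta = normalize_eta,
                 lambda_x = lambda_x, lambda_C = lambda_C,
                 convergence_tol = convergence_tol, seed = seed),
            class = "tpc_config")
}

## Residuals of the two generative predictions at candidate state x.
residuals_xy <- function(m, x, u, y) {
  ey <- y - drop(m$C %*% apply_nl(x, m$f))
  ex <- x - drop(m$A %*% apply_nl(m$x_prev, m$f)) - drop(m$B %*% u)
  list(ex = ex, ey = ey)
}

#' Variational free energy of a tPC network
#'
#' The precision-weighted sum of squared sensory and temporal prediction
#' errors,
#' `F = 1/2 (y - C f(x))' Pi_y (y - C f(x))
#'    + 1/2 (x - A f(x_prev) - B u)' Pi_x (x - A f(x_prev) - B u)`.
#' Inference minimises `F` over `x`; learning minimises it over the weights.
#'
#' @param m A [tpc_model()] (its `x_prev` supplies the previous estimate).
#' @param x Candidate current state (`dx`-vector).
#' @param u Control input (`du`-vector).
#' @param y Observation (`dy`-vector).
#' @return A non-negative scalar.
#' @examples
#' m <- tpc_model(A = 1, C = 1)
#' free_energy(m, x = 1, u = 0, y = 2)  # 1/2 + 1/2 = 1
#' @export
free_energy <- function(m, x, u, y) {
  x <- as_num_vec(x, m$dx, "x"); u <- as_num_vec(u, m$du, "u")
  y <- as_num_vec(y, m$dy, "y")
  r <- residuals_xy(m, x, u, y)
  0.5 * drop(r$ey %*% m$Pi_y %*% r$ey) + 0.5 * drop(r$ex %*% m$Pi_x %*% r$ex)
}

#' Precision-weighted prediction errors
#'
#' `eps_y = Pi_y (y - C f(x))` (sensory) and
#' `eps_x = Pi_x (x - A f(x_prev) - B u)` (temporal) -- the activities of the
#' two populations of prediction-error neurons.
#'
#' @inheritParams free_energy
#' @return List with `eps_x` (`dx`-vector) and `eps_y` (`dy`-vector).
#' @export
prediction_errors <- function(m, x, u, y) {
  x <- as_num_vec(x, m$dx, "x"); u <- as_num_vec(u, m$du, "u")
  y <- as_num_vec(y, m$dy, "y")
  r <- residuals_xy(m, x, u, y)
  list(eps_x = drop(m$Pi_x %*% r$ex), eps_y = drop(m$Pi_y %*% r$ey))
}

#' One Euler step of the inference dynamics
#'
#' Updates the candidate state down the free-energy gradient:
#' `x <- x + step_size * (-eps_x + f'(x) * C' eps_y)`, a discretisation of
#' `tau dx/dt = -dF/dx`.  For linear `f` the derivative factor is 1.
#'
#' @inheritParams free_energy
#' @param step_size Euler step `dt/tau` (`> 0`).
#' @return The updated `dx`-vector.
#' @export
inference_step <- function(m, x, u, y, step_size) {
  if (step_size <= 0) stop_config("step_size must be > 0")
  e <- prediction_errors(m, x, u, y)
  xn <- x + step_size *
    (-e$eps_x + nl_deriv(x, m$f) * drop(crossprod(m$C, e$eps_y)))
  if (any(!is.finite(xn)))
    stop("non-finite inference update (eps_x = ",
         paste(signif(e$eps_x, 3), collapse = ", "), ")")
  xn
}

#' Iterative inference of the current latent state
#'
#' Starting from the previous estimate `x_prev`, applies [inference_step()]
#' `cfg$inference_steps` times (stopping early once the sup-norm change drops
#' below `cfg$convergence_tol`, when set).  Does not modify `m`.
#'
#' @param m A [tpc_model()].
#' @param u,y Control input and observation for the current step.
#' @param cfg A [tpc_config()].
#' @param x_init Optional starting point of the iteration (defaults to
#'   `m$x_prev`; for linear `f` the objective is convex, so the result does
#'   not depend on it given enough iterations).
#' @return The inferred state estimate (a `dx`-vector).
#' @export
infer <- function(m, u, y, cfg = tpc_config(), x_init = NULL) {
  x <- if (is.null(x_init)) m$x_prev else as_num_vec(x_init, m$dx, "x_init")
  tol <- cfg$convergence_tol
  if (is.infinite(cfg$inference_steps))
    stop_config("inference_steps = Inf requires filter_sequence on a linear model")
  if (m$f == "linear") {
    ## Linear f makes the iteration affine; precompute it once:
    ## x <- (I - s (Pi_x + C'Pi_y C)) x + s (Pi_x (A x_prev + B u) + C'Pi_y y)
    s <- cfg$step_size
    M <- diag(m$dx) - s * (m$Pi_x + crossprod(m$C, m$Pi_y %*% m$C))
    b <- drop(m$A %*% m$x_prev) + drop(m$B %*% u)
    v <- s * (drop(m$Pi_x %*% b) + drop(crossprod(m$C, m$Pi_y %*% y)))
    for (i in seq_len(cfg$inference_steps)) {
      xn <- drop(M %*% x) + v
      if (!is.null(tol) && max(abs(xn - x)) < tol) { x <- xn; break }
      x <- xn
    }
    if (any(!is.finite(x))) stop("non-finite inference update")
    return(x)
  }
  ## tanh path: same arithmetic as inference_step with hoisted constants
  s <- cfg$step_size
  b <- drop(m$A %*% apply_nl(m$x_prev, m$f)) + drop(m$B %*% u)
  CtPy <- crossprod(m$C, m$Pi_y)
  for (i in seq_len(cfg$inference_steps)) {
    th <- tanh(x)
    xn <- x + s * (-drop(m$Pi_x %*% (x - b)) +
                     (1 - th^2) * drop(CtPy %*% (y - drop(m$C %*% th))))
    if (any(!is.finite(xn))) stop("non-finite inference update")
    if (!is.null(tol) && max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  x
}

#' Fully online single-step state update
#'
#' The one-iteration-per-observation variant obtained by equating the
#' observation and inference time indices:
#' `xhat_k = x + step_size * (-x + A f(x_prev) + B u + f'(x) * C' eps_y)`
#' with `x = x_prev`.  The state precision is omitted (it can be absorbed
#' into `A`); the observation precision enters via `eps_y`.
#'
#' @inheritParams infer
#' @param step_size Euler step (`> 0`).
#' @return The updated state estimate (a `dx`-vector).
#' @export
single_step_update <- function(m, u, y, step_size) {
  if (step_size <= 0) stop_config("step_size must be > 0")
  x <- m$x_prev
  u <- as_num_vec(u, m$du, "u"); y <- as_num_vec(y, m$dy, "y")
  ey <- drop(m$Pi_y %*% (y - drop(m$C %*% apply_nl(x, m$f))))
  xn <- x + step_size *
    (-x + drop(m$A %*% apply_nl(m$x_prev, m$f)) + drop(m$B %*% u) +
       nl_deriv(x, m$f) * drop(crossprod(m$C, ey)))
  if (any(!is.finite(xn))) stop("non-finite single-step update")
  xn
}

#' Hebbian weight update
#'
#' Gradient steps of the free energy with respect to the weights, evaluated
#' at the converged estimate `x_hat`:
#' `dA = eta * eps_x f(x_prev)'`, `dB = eta * eps_x u'`,
#' `dC = eta * eps_y f(x_hat)'` -- outer products of prediction errors with
#' presynaptic activities, i.e. purely local Hebbian plasticity.  Deltas are
#' applied only where the model's `learn_*` flags are set, and `x_prev` is
#' reloaded with `x_hat` afterwards.
#'
#' @param m A [tpc_model()].
#' @param x_hat Converged state estimate for the current step.
#' @param u,y Control input and observation for the current step.
#' @param eta Learning rate (`>= 0`).
#' @return List with the updated `model` and the raw deltas `dA`, `dB`, `dC`.
#' @export
update_weights <- function(m, x_hat, u, y, eta) {
  if (eta < 0) stop_config("eta must be >= 0")
  x_hat <- as_num_vec(x_hat, m$dx, "x_hat")
  u <- as_num_vec(u, m$du, "u")
  e <- prediction_errors(m, x_hat, u, y)
  dA <- eta * tcrossprod(e$eps_x, apply_nl(m$x_prev, m$f))
  dB <- eta * tcrossprod(e$eps_x, u)
  dC <- eta * tcrossprod(e$eps_y, apply_nl(x_hat, m$f))
  if (m$learn_A) m$A <- m$A + dA
  if (m$learn_B) m$B <- m$B + dB
  if (m$learn_C) m$C <- m$C + dC
  if (any(!is.finite(m$A), !is.finite(m$B), !is.finite(m$C)))
    stop("non-finite weights after update")
  m$x_prev <- x_hat
  list(model = m, dA = dA, dB = dB, dC = dC)
}

## One-step observation prediction with the current weights (forward pass).
forward_predict <- function(m, u) {
  xp <- drop(m$A %*% apply_nl(m$x_prev, m$f)) + drop(m$B %*% u)
  list(x_pred = xp, y_pred = drop(m$C %*% apply_nl(xp, m$f)))
}

#' Filter a whole observation sequence with a tPC network
#'
#' Runs a single training epoch over the trajectory: for each step `k` the
#' one-step observation prediction `yhat_k = C f(A f(xhat_{k-1}) + B u_k)` is
#' recorded with the weights *before* any update (honest one-step-ahead
#' prediction), the state is inferred (iteratively, by the single-step rule
#' when `inference_steps = 1`, or analytically when
#' `inference_steps = Inf` and `f` is linear), the weights are optionally
#' updated, and the previous-estimate memory advances.
#'
#' @param m A [tpc_model()].
#' @param traj A `tpc_trajectory` (see [simulate.state_space_model()]); its
#'   `states` are used only to score `mse_state`.
#' @param cfg A [tpc_config()].
#' @param learn Apply Hebbian weight updates after each step?
#' @return An object of class `tpc_filter_result`: `estimates` (`N` x `dx`),
#'   `predicted_observations` (`N` x `dy`), `free_energy_trace`, `mse_state`,
#'   `mse_observation`, and the final `model`.
#' @seealso [tpc()] for the formula-free front end with standard S3 methods.
#' @export
filter_sequence <- function(m, traj, cfg = tpc_config(), learn = FALSE) {
  N <- traj$N
  if (N > 0 && (ncol(traj$observations) != m$dy ||
                ncol(traj$controls) != m$du))
    stop_config("trajectory dimensions do not match the model")
  est <- matrix(NA_real_, N, m$dx)
  yhat <- matrix(NA_real_, N, m$dy)
  fe <- numeric(N)
  equilibrium <- is.infinite(cfg$inference_steps)
  if (equilibrium && m$f != "linear")
    stop_config("analytic equilibrium requires a linear model")
  for (k in seq_len(N)) {
    u <- traj$controls[k, ]
    y <- traj$observations[k, ]
    yhat[k, ] <- forward_predict(m, u)$y_pred
    x_hat <-
      if (equilibrium) tpc_equilibrium_prec(m, u, y)
      else if (cfg$inference_steps == 1)
        single_step_update(m, u, y, cfg$step_size)
      else infer(m, u, y, cfg)
    fe[k] <- free_energy(m, x_hat, u, y)
    est[k, ] <- x_hat
    if (learn) {
      eta_k <- if (isTRUE(cfg$normalize_eta))
        cfg$eta / (1 + sum(apply_nl(x_hat, m$f)^2) +
                     sum(apply_nl(m$x_prev, m$f)^2) + sum(u^2))
      else cfg$eta
      m <- update_weights(m, x_hat, u, y, eta_k)$model
    } else m$x_prev <- x_hat
  }
  structure(list(estimates = est, predicted_observations = yhat,
                 free_energy_trace = fe,
                 mse_state = if (ncol(traj$states) == m$dx)
                   mse(est, traj$states) else NaN,
                 mse_observation = mse(yhat, traj$observations),
                 model = m, config = cfg, N = N),
            class = "tpc_filter_result")
}

## Exact minimiser of the free energy (linear f), in precision form:
## x = (Pi_x + C'Pi_y C)^-1 (Pi_x (A x_prev + B u) + C'Pi_y y).
tpc_equilibrium_prec <- function(m, u, y) {
  xp <- drop(m$A %*% m$x_prev) + drop(m$B %*% u)
  H <- m$Pi_x + crossprod(m$C, m$Pi_y %*% m$C)
  drop(solve(H, m$Pi_x %*% xp + crossprod(m$C, m$Pi_y %*% y)))
}

#' @export
print.tpc_filter_result <- function(x, ...) {
  cat(sprintf(
    "tPC filter result: N = %d, mse_state = %.4g, mse_observation = %.4g\n",
    x$N, x$mse_state, x$mse_observation))
  invisible(x)
}

#' Export a filter result as CSV / JSON summary
#'
#' The CSV holds `k`, the state estimates, one-step observation predictions
#' and the per-step free energy; the JSON summary holds the MSEs and an echo
#' of the configuration.
#'
#' @param result A `tpc_filter_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_filter_csv <- function(result, path) {
  df <- data.frame(k = seq_len(result$N))
  for (j in seq_len(ncol(result$estimates)))
    df[[paste0("xhat_", j)]] <- result$estimates[, j]
  for (j in seq_len(ncol(result$predicted_observations)))
    df[[paste0("yhat_", j)]] <- result$predicted_observations[, j]
  df$free_energy <- result$free_energy_trace
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_filter_csv
#' @export
write_filter_summary_json <- function(result, path) {
  cfg <- result$config
  jsonlite::write_json(
    list(mse_state = result$mse_state,
         mse_observation = result$mse_observation,
         N = result$N,
         config = cfg[!vapply(cfg, is.null, logical(1))]),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
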