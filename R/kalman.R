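#' Kalman filter projection step
#'
#' Propagates the posterior of the previous step through the linear dynamics:
#' `x_minus = A xhat + B u`, `Sigma_minus = A Sigma A' + Sigma_x`.
#'
#' @param x_hat Posterior mean at step `k-1`.
#' @param Sigma Posterior covariance at step `k-1`.
#' @param model A linear [state_space_model()].
#' @param u Control input at step `k`.
#' @return List with `x_minus` and `Sigma_minus`.
#' @export
kalman_project <- function(x_hat, Sigma, model, u) {
  if (model$f != "linear") stop_config("Kalman filtering requires linear f")
  x_hat <- as_num_vec(x_hat, model$dx, "x_hat")
  u <- as_num_vec(u, model$du, "u")
  list(x_minus = drop(model$A %*% x_hat) + drop(model$B %*% u),
       Sigma_minus = model$A %*% Sigma %*% t(model$A) + model$Sigma_x)
}

#' Kalman filter correction step
#'
#' Incorporates the observation: `K = S C' (C S C' + Sigma_y)^-1`,
#' `xhat = x_minus + K (y - C x_minus)`, `Sigma = (I - K C) S` (symmetrised;
#' the numerically safer Joseph form is available via `joseph = TRUE`).
#'
#' @param x_minus,Sigma_minus Output of [kalman_project()].
#' @param model A linear [state_space_model()].
#' @param y Observation.
#' @param joseph Use the Joseph-form covariance update.
#' @return List (`kalman_state`) with `x_hat`, `Sigma` and the gain `K`.
#' @export
kalman_correct <- function(x_minus, Sigma_minus, model, y, joseph = FALSE) {
  if (model$f != "linear") stop_config("Kalman filtering requires linear f")
  y <- as_num_vec(y, model$dy, "y")
  C <- model$C
  S <- C %*% Sigma_minus %*% t(C) + model$Sigma_y
  K <- t(solve(S, C %*% Sigma_minus))  # Sigma_minus C' S^-1
  x_hat <- x_minus + drop(K %*% (y - drop(C %*% x_minus)))
  IKC <- diag(model$dx) - K %*% C
  Sigma <- if (joseph)
    IKC %*% Sigma_minus %*% t(IKC) + K %*% model$Sigma_y %*% t(K)
  else IKC %*% Sigma_minus
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(x_hat = x_hat, Sigma = Sigma, K = K),
            class = "kalman_state")
}

#' Kalman filter over a trajectory
#'
#' Alternates [kalman_project()] and [kalman_correct()] over `k = 1..N`.
#' One-step observation predictions `yhat_k = C (A xhat_{k-1} + B u_k)` are
#' recorded before each correction so that observation-level accuracy is
#' directly comparable with [filter_sequence()].
#'
#' @param model A linear [state_space_model()].
#' @param traj A `tpc_trajectory`.
#' @param x0 Initial mean (zero vector by default).
#' @param Sigma0 Initial covariance (identity by default).
#' @param joseph Use the Joseph-form covariance update.
#' @return Object of class `kalman_filter`: `estimates`,
#'   `predicted_observations`, `Sigmas` (list of posterior covariances),
#'   `gains` (list), `mse_state`, `mse_observation`.
#' @export
kalman_filter <- function(model, traj, x0 = NULL, Sigma0 = diag(model$dx),
                          joseph = FALSE) {
  if (model$f != "linear") stop_config("Kalman filtering requires linear f")
  N <- traj$N
  x <- if (is.null(x0)) numeric(model$dx) else
    as_num_vec(x0, model$dx, "x0")
  Sigma <- as.matrix(Sigma0)
  est <- matrix(NA_real_, N, model$dx)
  yhat <- matrix(NA_real_, N, model$dy)
  Sigmas <- vector("list", N); gains <- vector("list", N)
  for (k in seq_len(N)) {
    pr <- kalman_project(x, Sigma, model, traj$controls[k, ])
    yhat[k, ] <- drop(model$C %*% pr$x_minus)
    co <- kalman_correct(pr$x_minus, pr$Sigma_minus, model,
                         traj$observations[k, ], joseph = joseph)
    x <- co$x_hat; Sigma <- co$Sigma
    est[k, ] <- x; Sigmas[[k]] <- Sigma; gains[[k]] <- co$K
  }
  structure(list(estimates = est, predicted_observations = yhat,
                 Sigmas = Sigmas, gains = gains,
                 mse_state = if (ncol(traj$states) == model$dx)
                   mse(est, traj$states) else NaN,
                 mse_observation = mse(yhat, traj$observations),
                 N = N),
            class = "kalman_filter")
}

#' @export
print.kalman_filter <- function(x, ...) {
  cat(sprintf(
    "Kalman filter result: N = %d, mse_state = %.4g, mse_observation = %.4g\n",
    x$N, x$mse_state, x$mse_observation))
  invisible(x)
}

#' Analytic tPC equilibrium (zero-variance Kalman update)
#'
#' The closed-form minimiser of the linear tPC free energy:
#' `x_minus = A x_prev + B u`, then
#' `xhat = x_minus + Sigma_x C' (C Sigma_x C' + Sigma_y)^-1 (y - C x_minus)`.
#' This is exactly the Kalman correction with the previous posterior
#' covariance forced to zero: tPC does not propagate posterior uncertainty.
#'
#' @param model A linear [state_space_model()].
#' @param x_prev Previous state estimate.
#' @param u,y Control input and observation.
#' @return The equilibrium state estimate (a `dx`-vector).
#' @export
tpc_equilibrium <- function(model, x_prev, u, y) {
  if (model$f != "linear") stop_config("equilibrium requires linear f")
  x_prev <- as_num_vec(x_prev, model$dx, "x_prev")
  u <- as_num_vec(u, model$du, "u")
  y <- as_num_vec(y, model$dy, "y")
  xm <- drop(model$A %*% x_prev) + drop(model$B %*% u)
  C <- model$C
  S <- C %*% model$Sigma_x %*% t(C) + model$Sigma_y
  K <- t(solve(S, C %*% model$Sigma_x))
  xm + drop(K %*% (y - drop(C %*% xm)))
}

#' Exact posterior by brute-force Gaussian conditioning
#'
#' Stacks the linear-Gaussian system over steps `1..k` into one joint
#' Gaussian over `(x_1, ..., x_k, y_1, ..., y_k)` with prior
#' `x_0 ~ N(x0, Sigma0)`, conditions on all observations, and returns the
#' marginal posterior of `x_k`.  An independent oracle for recursive
#' filters; tractable only for small `k`.
#'
#' @param model A linear [state_space_model()].
#' @param observations `k` by `dy` matrix of observations.
#' @param controls `k` by `du` matrix of controls.
#' @param k Step at which the posterior is requested (`<= 30`).
#' @param x0,Sigma0 Prior mean and covariance on `x_0`.
#' @return List with `mean` and `covariance` of `p(x_k | y_{1:k})`.
#' @export
brute_force_posterior <- function(model, observations, controls, k,
                                  x0 = NULL, Sigma0 = diag(model$dx)) {
  if (model$f != "linear") stop_config("oracle requires linear f")
  if (k < 1 || k > 30) stop_config("k must be in 1..30")
  observations <- as.matrix(observations); controls <- as.matrix(controls)
  if (nrow(observations) < k || nrow(controls) < k)
    stop_config("need at least k observations and controls")
  dx <- model$dx; dy <- model$dy
  A <- model$A; B <- model$B; C <- model$C
  x0 <- if (is.null(x0)) numeric(dx) else as_num_vec(x0, dx, "x0")
  ## Means of x_1..x_k.
  mu <- matrix(0, k, dx)
  mprev <- x0
  for (i in seq_len(k)) {
    mprev <- drop(A %*% mprev) + drop(B %*% controls[i, ])
    mu[i, ] <- mprev
  }
  ## Block covariance of (x_1..x_k): P_ii recursively, P_ij = A^(i-j) P_jj.
  P <- matrix(0, k * dx, k * dx)
  idx <- function(i) ((i - 1) * dx + 1):(i * dx)
  Pii <- A %*% as.matrix(Sigma0) %*% t(A) + model$Sigma_x
  P[idx(1), idx(1)] <- Pii
  diags <- list(Pii)
  for (i in seq_len(k - 1)) {
    Pii <- A %*% diags[[i]] %*% t(A) + model$Sigma_x
    diags[[i + 1]] <- Pii
    P[idx(i + 1), idx(i + 1)] <- Pii
  }
  for (j in seq_len(k)) {
    Aij <- diag(dx)
    if (j < k) for (i in (j + 1):k) {
      Aij <- A %*% Aij
      blk <- Aij %*% diags[[j]]
      P[idx(i), idx(j)] <- blk
      P[idx(j), idx(i)] <- t(blk)
    }
  }
  ## Observation blocks: y = (I_k kron C) x + noise.
  Cbig <- kronecker(diag(k), C)
  Sxy <- P %*% t(Cbig)
  Syy <- Cbig %*% Sxy + kronecker(diag(k), model$Sigma_y)
  mu_y <- as.vector(t(mu %*% t(C)))
  yv <- as.vector(t(observations[seq_len(k), , drop = FALSE]))
  rows <- idx(k)
  gain <- t(solve(Syy, t(Sxy[rows, , drop = FALSE])))
  mean_k <- mu[k, ] + drop(gain %*% (yv - mu_y))
  cov_k <- P[rows, rows] - gain %*% t(Sxy[rows, , drop = FALSE])
  list(mean = mean_k, covariance = (cov_k + t(cov_k)) / 2)
}
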