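#' Pendulum phase-space derivatives
#'
#' First-order form of the frictionless pendulum: `dtheta1/dt = theta2`,
#' `dtheta2/dt = -(g/L) sin(theta1)` (the mass cancels).
#'
#' @param theta1 Angle (rad).
#' @param theta2 Angular velocity (rad/s).
#' @param g Gravitational acceleration (m/s^2).
#' @param L Pendulum length (m).
#' @return Numeric vector `c(dtheta1, dtheta2)`.
#' @examples
#' pendulum_derivatives(1.8, 2.2)
#' @export
pendulum_derivatives <- function(theta1, theta2, g = 9.81, L = 3.0) {
  c(theta2, -(g / L) * sin(theta1))
}

#' Simulate a noisy pendulum time series
#'
#' Integrates the pendulum with the classic explicit 4th-order Runge--Kutta
#' method (fixed internal step `dk / substeps` for determinism), samples the
#' state every `dk` seconds, and observes it directly (`C = I`, no control)
#' plus isotropic Gaussian noise.  The angle is not wrapped during
#' integration.
#'
#' @param duration Total simulated time (s).
#' @param dk Observation interval (s).
#' @param g,L Gravity (m/s^2) and length (m).
#' @param theta0 Initial state `c(theta1, theta2)` at `t = 0` (rad, rad/s).
#' @param noise_std Observation noise standard deviation (`>= 0`).
#' @param seed Seed for the observation noise.
#' @param substeps Internal integrator steps per observation interval.
#' @return A `tpc_trajectory` with 2-column `states` (noise-free) and
#'   `observations` (noisy); `x0 = theta0`.
#' @examples
#' tr <- simulate_pendulum(duration = 10, seed = 1)
#' @export
simulate_pendulum <- function(duration = 2500, dk = 0.1, g = 9.81, L = 3.0,
                              theta0 = c(1.8, 2.2), noise_std = 0.1,
                              seed = NULL, substeps = 10) {
  if (L <= 0 || dk <= 0 || duration <= 0 || noise_std < 0)
    stop_config("invalid pendulum configuration")
  times <- seq(0, duration, by = dk / substeps)
  deriv <- function(t, y, parms)
    list(pendulum_derivatives(y[1], y[2], g = g, L = L))
  sol <- deSolve::rk4(y = c(theta1 = theta0[1], theta2 = theta0[2]),
                      times = times, func = deriv, parms = NULL)
  N <- floor(round(duration / dk, 9))
  pick <- 1 + substeps * seq_len(N)  # t = dk, 2 dk, ..., N dk
  states <- unname(as.matrix(sol[pick, c("theta1", "theta2")]))
  obs <- with_seed(seed,
    states + matrix(rnorm(2 * N, sd = noise_std), N, 2))
  new_trajectory(states, obs, controls = matrix(0, N, 1),
                 x0 = theta0, seed = seed)
}

#' Total mechanical energy of pendulum states
#'
#' `E = theta2^2 / 2 + (g / L) (1 - cos theta1)` per unit `m L^2`; conserved
#' by the frictionless dynamics, so its drift measures integrator error.
#'
#' @param states Two-column matrix of `(theta1, theta2)`.
#' @param g,L Gravity and length.
#' @return Numeric vector of energies.
#' @export
pendulum_energy <- function(states, g = 9.81, L = 3.0) {
  states <- as.matrix(states)
  states[, 2]^2 / 2 + (g / L) * (1 - cos(states[, 1]))
}

#' Linear versus nonlinear tPC on pendulum prediction
#'
#' For each simulation, generates a fresh noisy pendulum series and trains a
#' linear-f and a tanh-f tPC network online (learning `A` and `C`; `A`
#' initialised to zero, `C` to the identity; identity precisions, `B = 0`),
#' then scores one-step observation predictions over the final
#' `eval_window` seconds against the noise-free states (and, secondarily,
#' against the noisy observations).
#'
#' @param n_sims Number of paired simulations.
#' @param duration,dk,g,L,theta0,noise_std Passed to [simulate_pendulum()].
#' @param eval_window Final stretch (s) over which MSE is scored.
#' @param inference_steps,step_size,eta tPC hyper-parameters.
#' @param epochs Passes over each series (training is online within each
#'   pass; several passes over the shortened series match the training
#'   exposure of a single pass over the full-length one).
#' @param seed Base seed; simulation `i` uses `seed + i`.
#' @return List with `results` (one row per simulation: `mse_linear`,
#'   `mse_nonlinear` vs clean states and `mse_linear_noisy`,
#'   `mse_nonlinear_noisy` vs noisy observations), the means, and a paired
#'   Wilcoxon signed-rank summary of linear minus nonlinear.
#' @export
run_pendulum_comparison <- function(n_sims = 20, duration = 250, dk = 0.1,
                                    g = 9.81, L = 3.0, theta0 = c(1.8, 2.2),
                                    noise_std = 0.1, eval_window = 80,
                                    inference_steps = 20, step_size = 0.2,
                                    eta = 2e-3, epochs = 10, seed = 1) {
  if (n_sims < 1) stop_config("n_sims must be >= 1")
  cfg <- tpc_config(inference_steps = inference_steps,
                    step_size = step_size, eta = eta)
  one <- function(i) {
    traj <- simulate_pendulum(duration = duration, dk = dk, g = g, L = L,
                              theta0 = theta0, noise_std = noise_std,
                              seed = seed + i)
    n_eval <- min(floor(eval_window / dk), traj$N)
    keep <- traj$N - n_eval + seq_len(n_eval)
    score <- function(f) {
      m <- tpc_model(A = matrix(0, 2, 2), C = diag(2), f = f,
                     learn_A = TRUE, learn_C = TRUE)
      for (ep in seq_len(epochs)) {
        m$x_prev <- numeric(2)
        fit <- filter_sequence(m, traj, cfg, learn = TRUE)
        m <- fit$model
      }
      yh <- fit$predicted_observations[keep, , drop = FALSE]
      c(clean = mse(yh, traj$states[keep, , drop = FALSE]),
        noisy = mse(yh, traj$observations[keep, , drop = FALSE]))
    }
    safe_score <- function(f) tryCatch(score(f), error = function(e)
      c(clean = NA_real_, noisy = NA_real_))
    lin <- safe_score("linear"); nl <- safe_score("tanh")
    c(mse_linear = unname(lin["clean"]), mse_nonlinear = unname(nl["clean"]),
      mse_linear_noisy = unname(lin["noisy"]),
      mse_nonlinear_noisy = unname(nl["noisy"]))
  }
  res <- as.data.frame(do.call(rbind, lapply(seq_len(n_sims), one)))
  res$sim <- seq_len(n_sims)
  ok <- stats::complete.cases(res[, c("mse_linear", "mse_nonlinear")])
  test <- if (sum(ok) >= 2)
    stats::wilcox.test(res$mse_linear[ok], res$mse_nonlinear[ok],
                       paired = TRUE, exact = FALSE)
  else NULL
  list(results = res,
       mean_linear = mean(res$mse_linear, na.rm = TRUE),
       mean_nonlinear = mean(res$mse_nonlinear, na.rm = TRUE),
       wilcoxon = test)
}
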