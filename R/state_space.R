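#' Linear or tanh Gaussian state-space model
#'
#' The generative process assumed by temporal predictive coding: hidden states
#' evolve as `x_k = A f(x_{k-1}) + B u_k + w_x` with process noise
#' `w_x ~ N(0, Sigma_x)`, and observations arise as `y_k = C f(x_k) + w_y`
#' with `w_y ~ N(0, Sigma_y)`.  `f` is either the identity or `tanh` applied
#' elementwise.
#'
#' @param A State-transition matrix (`dx` by `dx`).
#' @param C Emission matrix (`dy` by `dx`).
#' @param B Control-gain matrix (`dx` by `du`); defaults to a single zero
#'   column (no control input).
#' @param Sigma_x,Sigma_y Process and observation noise covariances; symmetric
#'   positive definite (all-zero allowed only with `noise_free = TRUE`).
#' @param f Nonlinearity, `"linear"` or `"tanh"`.
#' @param noise_free Allow `Sigma_x`/`Sigma_y` to be exactly zero (useful for
#'   deterministic checks; the public simulation API otherwise requires
#'   positive-definite noise).
#' @return An object of class `state_space_model` with elements `A`, `B`, `C`,
#'   `Sigma_x`, `Sigma_y`, `f` and the dimensions `dx`, `du`, `dy`.
#' @seealso [simulate.state_space_model()], [make_tracking_model()],
#'   [kalman_filter()]
#' @examples
#' m <- state_space_model(A = diag(2), C = diag(2))
#' simulate(m, N = 5, seed = 1)
#' @export
state_space_model <- function(A, C, B = NULL,
                              Sigma_x = diag(nrow(A)),
                              Sigma_y = diag(nrow(C)),
                              f = c("linear", "tanh"),
                              noise_free = FALSE) {
  f <- match.arg(f)
  A <- as.matrix(A); C <- as.matrix(C)
  if (!is_square(A)) stop_config("A must be square")
  dx <- nrow(A)
  if (is.null(B)) B <- matrix(0, dx, 1)
  B <- as.matrix(B)
  if (ncol(C) != dx) stop_config("C must have ", dx, " columns")
  if (nrow(B) != dx) stop_config("B must have ", dx, " rows")
  dy <- nrow(C); du <- ncol(B)
  Sigma_x <- as.matrix(Sigma_x); Sigma_y <- as.matrix(Sigma_y)
  if (!all(dim(Sigma_x) == dx)) stop_config("Sigma_x must be ", dx, "x", dx)
  if (!all(dim(Sigma_y) == dy)) stop_config("Sigma_y must be ", dy, "x", dy)
  check_spd(Sigma_x, "Sigma_x", allow_zero = noise_free)
  check_spd(Sigma_y, "Sigma_y", allow_zero = noise_free)
  structure(list(A = A, B = B, C = C, Sigma_x = Sigma_x, Sigma_y = Sigma_y,
                 f = f, dx = dx, du = du, dy = dy),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("State-space model (%s f): dx = %d, du = %d, dy = %d\n",
              x$f, x$dx, x$du, x$dy))
  invisible(x)
}

#' Simulate a trajectory from a state-space model
#'
#' Draws hidden states and observations from the generative process, starting
#' from the initial condition `x0` at step `k = 0` (the zero vector by
#' default; `x0` itself is not part of the returned states).
#'
#' @param object A [state_space_model()].
#' @param nsim Number of independent trajectories; if 1 (default) a single
#'   trajectory is returned, otherwise a list of them.
#' @param seed Integer seed making the noise draws reproducible; the caller's
#'   RNG state is left untouched.
#' @param N Number of discrete observation steps (`N >= 0`).
#' @param controls Control inputs: an `N` by `du` matrix (or vector recycled
#'   across `du = 1`), rows indexed `k = 1..N`.  Defaults to zeros.
#' @param x0 Initial hidden state at `k = 0`; defaults to the zero vector.
#' @param ... Unused.
#' @return A `tpc_trajectory`: list with `states` (`N` x `dx`),
#'   `observations` (`N` x `dy`), `controls` (`N` x `du`), `N`, `x0`, `seed`.
#' @examples
#' m <- make_tracking_model(seed = 1)
#' tr <- simulate(m, N = 100, controls = make_control_sequence(100), seed = 2)
#' @export
simulate.state_space_model <- function(object, nsim = 1, seed = NULL,
                                       N, controls = NULL, x0 = NULL, ...) {
  if (N < 0) stop_config("N must be >= 0")
  if (is.null(controls)) controls <- matrix(0, N, object$du)
  controls <- as.matrix(controls)
  if (N > 0 && ncol(controls) != object$du)
    stop_config("controls must have ", object$du, " columns")
  if (nrow(controls) < N) stop_config("controls must have at least N rows")
  x0 <- if (is.null(x0)) numeric(object$dx) else
    as_num_vec(x0, object$dx, "x0")
  one <- function() {
    states <- matrix(0, N, object$dx)
    obs <- matrix(0, N, object$dy)
    x <- x0
    for (k in seq_len(N)) {
      x <- drop(object$A %*% apply_nl(x, object$f)) +
        drop(object$B %*% controls[k, ]) + rmvn0(object$Sigma_x)
      states[k, ] <- x
      obs[k, ] <- drop(object$C %*% apply_nl(x, object$f)) +
        rmvn0(object$Sigma_y)
    }
    new_trajectory(states, obs, controls[seq_len(N), , drop = FALSE],
                   x0 = x0, seed = seed)
  }
  res <- with_seed(seed, replicate(nsim, one(), simplify = FALSE))
  if (nsim == 1) res[[1]] else res
}

new_trajectory <- function(states, observations, controls, x0, seed = NULL) {
  stopifnot(nrow(states) == nrow(observations),
            nrow(states) == nrow(controls))
  structure(list(states = states, observations = observations,
                 controls = controls, N = nrow(states), x0 = x0,
                 seed = seed),
            class = "tpc_trajectory")
}

#' @export
print.tpc_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: N = %d steps, dx = %d, dy = %d, du = %d\n",
              x$N, ncol(x$states), ncol(x$observations), ncol(x$controls)))
  invisible(x)
}

#' Constant-acceleration tracking benchmark model
#'
#' The classic 3-dimensional tracking task: the hidden state holds position,
#' velocity and acceleration of an object; `A` is the Taylor integrator for
#' constant acceleration over an interval `dk`, the control enters the
#' acceleration, and the observations are scrambled through a fixed random
#' Gaussian emission matrix `C` with `C_ij ~ N(0, 1)`.  Both noise
#' covariances are identity.
#'
#' @param dk Interval between successive observations (`> 0`).
#' @param seed Seed for the random draw of `C` (same seed, same `C`).
#' @param Sigma_x,Sigma_y Optional noise covariances overriding the identity
#'   default (e.g. from [make_covariance_case()]).
#' @return A [state_space_model()] with `dx = du = 1`-column `B = (0,0,1)'`.
#' @examples
#' make_tracking_model(dk = 0.001, seed = 1)$A
#' @export
make_tracking_model <- function(dk = 0.001, seed = NULL,
                                Sigma_x = diag(3), Sigma_y = diag(3)) {
  if (dk < 0) stop_config("dk must be positive")
  A <- matrix(c(1, dk, dk^2 / 2,
                0, 1, dk,
                0, 0, 1), 3, 3, byrow = TRUE)
  B <- matrix(c(0, 0, 1), 3, 1)
  C <- with_seed(seed, matrix(rnorm(9), 3, 3))
  state_space_model(A = A, C = C, B = B, Sigma_x = Sigma_x,
                    Sigma_y = Sigma_y, f = "linear")
}

#' Exponentially decaying control inputs
#'
#' The benchmark control sequence `u_k = exp(-0.01 k)` for `k = 1..N` (the
#' index origin is configurable since some conventions start at `k = 0`).
#'
#' @param N Number of steps.
#' @param rate Decay rate (default 0.01).
#' @param k_origin Index of the first control (default 1).
#' @return An `N` by 1 matrix of controls.
#' @examples
#' make_control_sequence(3)
#' @export
make_control_sequence <- function(N, rate = 0.01, k_origin = 1) {
  if (N < 0) stop_config("N must be >= 0")
  k <- seq_len(N) + (k_origin - 1)
  matrix(exp(-rate * k), ncol = 1)
}

#' Benchmark noise-covariance settings
#'
#' Three settings of the (shared) process and observation noise covariance
#' used to probe whether learnt weights can absorb non-identity noise
#' structure: the identity, a non-identity diagonal with one deliberately
#' large entry (10), and a dense symmetric positive-definite matrix.
#'
#' @param case One of `"identity"`, `"nonidentity_diagonal"`,
#'   `"positive_definite"`.
#' @return List with elements `Sigma_x` and `Sigma_y` (equal 3x3 matrices).
#' @examples
#' make_covariance_case("nonidentity_diagonal")$Sigma_x
#' @export
make_covariance_case <- function(case = c("identity", "nonidentity_diagonal",
                                          "positive_definite")) {
  case <- match.arg(case)
  S <- switch(case,
    identity = diag(3),
    nonidentity_diagonal = diag(c(10, 1, 1)),
    positive_definite = matrix(c(1, 0.2, 0.5,
                                 0.2, 1, 0.4,
                                 0.5, 0.4, 1), 3, 3))
  check_spd(S, case)
  list(Sigma_x = S, Sigma_y = S)
}

#' Read and write trajectories as CSV
#'
#' Columns are `k`, `x_1..x_dx`, `y_1..y_dy`, `u_1..u_du`; the initial
#' condition `x0` and seed are not stored.
#'
#' @param traj A `tpc_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a `tpc_trajectory` (with `x0` set to zero).
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(k = seq_len(traj$N))
  add <- function(df, M, prefix) {
    M <- as.matrix(M)
    for (j in seq_len(ncol(M))) df[[paste0(prefix, "_", j)]] <- M[, j]
    df
  }
  df <- add(df, traj$states, "x")
  df <- add(df, traj$observations, "y")
  df <- add(df, traj$controls, "u")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_\\d+$"), names(df), value = TRUE)
    as.matrix(df[, cols, drop = FALSE])
  }
  states <- pick("x")
  new_trajectory(states, pick("y"), pick("u"),
                 x0 = numeric(ncol(states)))
}

#' Read and write state-space model matrices as JSON
#'
#' @param model A [state_space_model()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a [state_space_model()].
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(A = model$A, B = model$B, C = model$C,
         Sigma_x = model$Sigma_x, Sigma_y = model$Sigma_y, f = model$f),
    path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  state_space_model(A = m(j$A), C = m(j$C), B = m(j$B),
                    Sigma_x = m(j$Sigma_x), Sigma_y = m(j$Sigma_y),
                    f = j$f, noise_free = TRUE)
}
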