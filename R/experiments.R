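#' Tracking-benchmark sweep over inference steps and step sizes
#'
#' Builds the constant-acceleration tracking system (fixed random `C` drawn
#' from `seed`), simulates `n_trials` fresh noisy trajectories with the
#' exponentially decaying control inputs, and measures state-level MSE of
#' the tPC network with true weights (no learning) for every combination of
#' inference-step count and step size, alongside the Kalman filter and the
#' analytic-equilibrium tPC variant.
#'
#' @param steps_grid Inference-step counts to sweep.
#' @param stepsize_grid Step sizes to sweep.
#' @param n_trials Trajectories to average over.
#' @param N Steps per trajectory.
#' @param dk Observation interval of the tracking model.
#' @param seed Base seed (system matrix and trials derive from it).
#' @param model Optional [state_space_model()] overriding the constructed
#'   tracking system.
#' @return A data.frame with one row per grid cell plus one `"equilibrium"`
#'   row: columns `variant`, `inference_steps`, `step_size`, `mse_tpc`,
#'   `mse_kalman`, `mse_diff` (tPC minus Kalman).
#' @export
run_tracking_sweep <- function(steps_grid = c(1, 5, 20),
                               stepsize_grid = c(0.05, 0.2, 0.5),
                               n_trials = 10, N = 1000, dk = 0.001,
                               seed = 1, model = NULL) {
  if (!length(steps_grid) || !length(stepsize_grid))
    stop_config("grids must be nonempty")
  model <- model %||% make_tracking_model(dk = dk, seed = seed)
  controls <- make_control_sequence(N)
  trajs <- lapply(seq_len(n_trials), function(i)
    simulate(model, N = N, controls = controls, seed = seed + i))
  kal <- vapply(trajs, function(tr)
    kalman_filter(model, tr)$mse_state, numeric(1))
  tm <- as_tpc_model(model)
  ## Cells whose step size exceeds the stability bound of gradient
  ## inference (see max_stable_step_size) diverge; record them as NA.
  cell <- function(steps, s) {
    cfg <- tpc_config(inference_steps = steps, step_size = s)
    mean(vapply(trajs, function(tr) {
      m <- tm; m$x_prev <- numeric(m$dx)
      tryCatch(filter_sequence(m, tr, cfg)$mse_state,
               error = function(e) NA_real_)
    }, numeric(1)))
  }
  grid <- expand.grid(inference_steps = steps_grid,
                      step_size = stepsize_grid)
  grid$variant <- "iterative"
  grid$mse_tpc <- mapply(cell, grid$inference_steps, grid$step_size)
  eq <- data.frame(inference_steps = Inf, step_size = NA_real_,
                   variant = "equilibrium",
                   mse_tpc = mean(vapply(trajs, function(tr)
                     filter_sequence(tm, tr,
                       tpc_config(inference_steps = Inf))$mse_state,
                     numeric(1))))
  out <- rbind(grid, eq)
  out$mse_kalman <- mean(kal)
  out$mse_diff <- out$mse_tpc - out$mse_kalman
  out[, c("variant", "inference_steps", "step_size", "mse_tpc",
          "mse_kalman", "mse_diff")]
}

#' Compare true, learnt and random weights against the Kalman filter
#'
#' On the tracking benchmark, runs four estimators per trial: the Kalman
#' filter; the tPC network with the true weights (precisions set to the
#' inverted noise covariances); a tPC network that learns `A` and `C` online
#' by Hebbian plasticity (initialised at `A = 0`, `C = I`, identity
#' precisions); and a network with fixed random Gaussian `A` and `C`.
#' Accuracy is scored at both the hidden-state and the observation level
#' (one-step forward-pass predictions).
#'
#' @param n_trials Trials (fresh noise per trial).
#' @param N Steps per trajectory.
#' @param dk Observation interval.
#' @param covariance_case Noise setting, see [make_covariance_case()].
#' @param inference_steps,step_size,eta tPC hyper-parameters; `eta` is a
#'   normalised-LMS rate (see `normalize_eta` in [tpc_config()]), which
#'   keeps Hebbian learning stable across systems whose latent scale
#'   depends on the random emission draw.
#' @param epochs Training passes over the trajectory for the learnt model
#'   (the Hebbian learner needs several passes to converge; scoring uses the
#'   final pass, during which weights still update online).
#' @param seed Base seed.
#' @param model Optional system override.
#' @return List with `results` (long data.frame: `trial`, `estimator`,
#'   `mse_state`, `mse_observation`), `summary` (means by estimator,
#'   over converged trials), `learnt_models` (the trained [tpc_model()]s,
#'   `NULL` where training diverged) and `n_diverged`.
#' @export
run_learning_comparison <- function(n_trials = 10, N = 1000, dk = 0.001,
                                    covariance_case = "identity",
                                    inference_steps = 20, step_size = 0.2,
                                    eta = 0.1, epochs = 25, seed = 1,
                                    model = NULL) {
  if (n_trials < 1) stop_config("n_trials must be >= 1")
  covs <- make_covariance_case(covariance_case)
  model <- model %||% make_tracking_model(dk = dk, seed = seed,
                                          Sigma_x = covs$Sigma_x,
                                          Sigma_y = covs$Sigma_y)
  controls <- make_control_sequence(N)
  cfg <- tpc_config(inference_steps = inference_steps,
                    step_size = step_size, eta = eta, normalize_eta = TRUE)
  rows <- list(); learnt_models <- vector("list", n_trials)
  n_diverged <- 0
  for (i in seq_len(n_trials)) {
    tr <- simulate(model, N = N, controls = controls, seed = seed + i)
    kf <- kalman_filter(model, tr)
    true_fit <- filter_sequence(as_tpc_model(model), tr, cfg)
    learn_m <- tpc_model(A = matrix(0, model$dx, model$dx),
                         C = diag(1, model$dy, model$dx), B = model$B,
                         f = model$f, learn_A = TRUE, learn_C = TRUE)
    ## A trial whose learnt weights push inference past its stability
    ## bound is recorded as diverged (NA) rather than aborting the run.
    learn_fit <- tryCatch({
      for (ep in seq_len(epochs)) {
        learn_m$x_prev <- numeric(model$dx)
        lf <- filter_sequence(learn_m, tr, cfg, learn = TRUE)
        learn_m <- lf$model
      }
      lf
    }, error = function(e) NULL)
    if (is.null(learn_fit)) {
      n_diverged <- n_diverged + 1
      learn_fit <- list(mse_state = NA_real_, mse_observation = NA_real_)
    } else {
      learnt_models[[i]] <- learn_fit$model
    }
    ## Random weights at the standard stable scale N(0, 1/dx), with the
    ## recurrent matrix capped at spectral radius 0.9 so the mismatched
    ## filter stays bounded over long sequences.
    rand_m <- with_seed(seed + 10000 + i, {
      Ar <- matrix(rnorm(model$dx^2, sd = 1 / sqrt(model$dx)),
                   model$dx, model$dx)
      rho <- max(abs(eigen(Ar, only.values = TRUE)$values))
      if (rho > 0.9) Ar <- 0.9 * Ar / rho
      tpc_model(A = Ar,
                C = matrix(rnorm(model$dy * model$dx,
                                 sd = 1 / sqrt(model$dx)),
                           model$dy, model$dx),
                B = model$B, f = model$f)
    })
    rand_fit <- filter_sequence(rand_m, tr, cfg)
    grab <- function(fit, nm)
      data.frame(trial = i, estimator = nm, mse_state = fit$mse_state,
                 mse_observation = fit$mse_observation)
    rows[[i]] <- rbind(grab(kf, "kalman"), grab(true_fit, "true"),
                       grab(learn_fit, "learnt"), grab(rand_fit, "random"))
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    results[, c("mse_state", "mse_observation")],
    by = list(estimator = results$estimator),
    FUN = function(z) mean(z, na.rm = TRUE))
  list(results = results, summary = summary,
       learnt_models = learnt_models, n_diverged = n_diverged,
       model = model)
}

#' Noise-covariance encoding experiment
#'
#' Runs [run_learning_comparison()] under a chosen noise-covariance setting
#' and additionally reports, per trial, whether the learnt recurrent matrix
#' `A` expresses the high-variance dimension of the process noise (the
#' deliberately large diagonal entry of `Sigma_x`).
#'
#' Because the hidden state is identifiable only up to the learnt emission
#' mapping (many latent codes predict the same observations), the latent
#' coordinate `j*` carrying the largest-magnitude diagonal entry of the
#' learnt `A` is first attributed to a true state dimension by projecting
#' the learnt emission column through the true one:
#' `i* = argmax_i |(C_true^-1 C_learnt)[i, j*]|`.  Alignment holds when `i*`
#' is the high-variance dimension.  The naive positional comparison (is
#' `argmax_j |A_jj|` itself the high-variance index?) is also reported; it
#' is only meaningful when the true emission is close to the identity.
#'
#' @inheritParams run_learning_comparison
#' @param case Covariance case tag, see [make_covariance_case()].
#' @return List: the `comparison` result, `A_learnt` (list of matrices),
#'   `alignment` / `alignment_naive` (logical per trial), `alignment_rate`,
#'   and the target dimension `high_var_dim`.
#' @export
run_covariance_experiment <- function(case = "nonidentity_diagonal",
                                      n_trials = 10, N = 1000, dk = 0.001,
                                      inference_steps = 20, step_size = 0.2,
                                      eta = 0.1, epochs = 25, seed = 1) {
  comp <- run_learning_comparison(n_trials = n_trials, N = N, dk = dk,
                                  covariance_case = case,
                                  inference_steps = inference_steps,
                                  step_size = step_size, eta = eta,
                                  epochs = epochs, seed = seed)
  Sx <- make_covariance_case(case)$Sigma_x
  target <- which.max(diag(Sx))
  Ct <- comp$model$C
  A_learnt <- lapply(comp$learnt_models, function(m)
    if (is.null(m)) NULL else m$A)
  attrib <- vapply(comp$learnt_models, function(m) {
    if (is.null(m)) return(NA_integer_)
    j <- which.max(abs(diag(m$A)))
    which.max(abs(solve(Ct, m$C[, j])))
  }, integer(1))
  alignment <- attrib == target
  alignment_naive <- vapply(A_learnt, function(A)
    if (is.null(A)) NA else which.max(abs(diag(A))) == target, logical(1))
  list(comparison = comp, A_learnt = A_learnt, alignment = alignment,
       alignment_naive = alignment_naive,
       alignment_rate = mean(alignment, na.rm = TRUE),
       high_var_dim = target)
}
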