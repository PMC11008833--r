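test_that("free energy matches hand arithmetic and a quadratic-form oracle", {
  m <- tpc_model(A = 1, C = 1)
  expect_equal(free_energy(m, x = 1, u = 0, y = 2), 1.0)
  ## perfect prediction
  set.seed(1)
  m3 <- rand_tpc()
  u <- rnorm(1)
  x <- drop(m3$A %*% m3$x_prev) + drop(m3$B %*% u)
  expect_equal(free_energy(m3, x, u, drop(m3$C %*% x)), 0)
  ## independent quadratic-form evaluation
  for (i in 1:10) {
    m3 <- rand_tpc()
    x <- rnorm(3); u <- rnorm(1); y <- rnorm(3)
    ey <- y - m3$C %*% x
    ex <- x - m3$A %*% m3$x_prev - m3$B %*% u
    oracle <- 0.5 * sum(diag(t(ey) %*% m3$Pi_y %*% ey)) +
      0.5 * sum(diag(t(ex) %*% m3$Pi_x %*% ex))
    expect_equal(free_energy(m3, x, u, y), oracle, tolerance = 1e-12)
  }
})

test_that("prediction errors equal solve-based precision weighting", {
  m <- tpc_model(A = 1, C = 1)
  e <- prediction_errors(m, x = 1, u = 0, y = 2)
  expect_equal(e$eps_x, 1); expect_equal(e$eps_y, 1)
  set.seed(2)
  m3 <- rand_tpc()
  x <- rnorm(3); u <- rnorm(1); y <- rnorm(3)
  e <- prediction_errors(m3, x, u, y)
  ## oracle: residual weighted by solve(Sigma) with Sigma the inverse precision
  Sx <- solve(m3$Pi_x); Sy <- solve(m3$Pi_y)
  expect_equal(e$eps_y, drop(solve(Sy, y - m3$C %*% x)), tolerance = 1e-9)
  expect_equal(e$eps_x,
               drop(solve(Sx, x - m3$A %*% m3$x_prev - m3$B %*% u)),
               tolerance = 1e-9)
})

test_that("inference step descends the numerical free-energy gradient", {
  set.seed(3)
  for (f in c("linear", "tanh")) for (i in 1:10) {
    dx <- sample(1:5, 1); dy <- sample(1:5, 1)
    m <- rand_tpc(dx, dy, f = f)
    x <- rnorm(dx); u <- rnorm(1); y <- rnorm(dy)
    s <- 0.05
    dir <- (inference_step(m, x, u, y, s) - x) / s
    g <- num_grad(function(z) free_energy(m, z, u, y), x)
    expect_lt(sqrt(sum((dir + g)^2)) / max(sqrt(sum(g^2)), 1e-8), 1e-5)
  }
  ## hand arithmetic
  m <- tpc_model(A = 1, C = 1)
  expect_equal(inference_step(m, x = 0, u = 0, y = 1, step_size = 0.5), 0.5)
})

test_that("the analytic equilibrium is a fixed point of the inference step", {
  set.seed(4)
  for (i in 1:5) {
    m <- rand_tpc()
    u <- rnorm(1); y <- rnorm(3)
    xe <- tpc_equilibrium(ssm_of(m), m$x_prev, u, y)
    expect_lt(max(abs(inference_step(m, xe, u, y, 0.2) - xe)), 1e-10)
  }
})

test_that("iterative inference converges to the closed form from any start", {
  set.seed(5)
  m <- rand_tpc()
  u <- rnorm(1); y <- rnorm(3)
  cfg <- tpc_config(inference_steps = 1000, step_size = 0.1)
  x1 <- infer(m, u, y, cfg, x_init = rnorm(3))
  x2 <- infer(m, u, y, cfg, x_init = rnorm(3))
  expect_lt(max(abs(x1 - x2)), 1e-6)
  expect_equal(x1, tpc_equilibrium(ssm_of(m), m$x_prev, u, y),
               tolerance = 1e-6)
})

test_that("convergence tolerance stops the iteration early", {
  set.seed(6)
  m <- rand_tpc()
  u <- rnorm(1); y <- rnorm(3)
  xa <- infer(m, u, y, tpc_config(5000, 0.1, convergence_tol = 1e-12))
  expect_equal(xa, tpc_equilibrium(ssm_of(m), m$x_prev, u, y),
               tolerance = 1e-8)
})

test_that("single-step update matches hand arithmetic and one-step infer", {
  ## no sensory term: pure prediction
  m <- tpc_model(A = matrix(c(0.5, 0, 0.1, 0.9), 2, 2),
                 C = matrix(0, 2, 2), B = diag(2), x_prev = c(1, -1))
  expect_equal(single_step_update(m, u = c(2, 0), y = c(0, 0), step_size = 1),
               drop(m$A %*% c(1, -1)) + c(2, 0))
  m1 <- tpc_model(A = 1, C = 1)
  expect_equal(single_step_update(m1, u = 0, y = 2, step_size = 0.5), 1.0)
  ## identity precisions: single step == one iteration of infer
  set.seed(7)
  m2 <- tpc_model(A = matrix(rnorm(4, sd = 0.3), 2, 2),
                  C = matrix(rnorm(4, sd = 0.3), 2, 2), x_prev = rnorm(2))
  u <- 0; y <- rnorm(2)
  expect_equal(single_step_update(m2, u, y, 0.3),
               infer(m2, u, y, tpc_config(1, 0.3)), tolerance = 1e-12)
})

test_that("weight updates are the Hebbian outer products", {
  m <- tpc_model(A = matrix(0, 2, 2), C = matrix(0, 2, 2),
                 x_prev = c(2, 3), learn_A = TRUE)
  ## craft eps_x = (1, 0): x_hat - A x_prev - B u = (1, 0)
  up <- update_weights(m, x_hat = c(1, 0), u = 0, y = c(0, 0), eta = 0.1)
  expect_equal(up$dA, matrix(c(0.2, 0, 0.3, 0), 2, 2))
  expect_equal(up$model$A, up$dA)        # learn_A applied
  expect_equal(up$model$C, matrix(0, 2, 2))  # learn_C off
  expect_equal(up$model$x_prev, c(1, 0))     # memory reloaded
  ## zero errors give zero deltas
  set.seed(8)
  m3 <- rand_tpc()
  u <- rnorm(1)
  xh <- drop(m3$A %*% m3$x_prev) + drop(m3$B %*% u)
  up0 <- update_weights(m3, xh, u, drop(m3$C %*% xh), eta = 0.5)
  expect_equal(up0$dA, matrix(0, 3, 3))
  expect_equal(up0$dC, matrix(0, 3, 3))
})

test_that("Hebbian updates are local: each delta ignores unrelated inputs", {
  set.seed(9)
  m <- rand_tpc()
  x_hat <- rnorm(3); u <- rnorm(1); y <- rnorm(3)
  base <- update_weights(m, x_hat, u, y, eta = 0.1)
  ## dA depends only on (eps_x, f(x_prev)): perturbing C or y leaves it alone
  mC <- m; mC$C <- m$C + matrix(rnorm(9), 3, 3)
  expect_equal(update_weights(mC, x_hat, u, y, 0.1)$dA, base$dA)
  expect_equal(update_weights(m, x_hat, u, y + 1, 0.1)$dA, base$dA)
  ## dC depends only on (eps_y, f(x_hat)): perturbing A or u leaves it alone
  mA <- m; mA$A <- m$A + matrix(rnorm(9), 3, 3)
  expect_equal(update_weights(mA, x_hat, u, y, 0.1)$dC, base$dC)
  expect_equal(update_weights(m, x_hat, u + 1, y, 0.1)$dC, base$dC)
})

test_that("filtering an empty trajectory returns an empty result", {
  m <- state_space_model(A = diag(2), C = diag(2))
  tr <- simulate(m, N = 0, seed = 1)
  res <- filter_sequence(as_tpc_model(m), tr)
  expect_equal(res$N, 0)
  expect_true(is.nan(res$mse_state))
})

test_that("noise-free exact-model filtering drives state error to zero", {
  set.seed(10)
  ssm <- rand_stable_ssm()
  clean <- state_space_model(A = ssm$A, C = ssm$C, B = ssm$B,
                             Sigma_x = matrix(0, 3, 3),
                             Sigma_y = matrix(0, 3, 3), noise_free = TRUE)
  tr <- simulate(clean, N = 30, x0 = rnorm(3), seed = 2)
  m <- as_tpc_model(ssm)  # finite precisions, exact weights
  ## score after the transient from the (unknown) initial state has decayed
  late <- function(steps) {
    fit <- filter_sequence(m, tr, tpc_config(steps, 0.1))
    mean((fit$estimates[11:30, ] - tr$states[11:30, ])^2)
  }
  err <- vapply(c(5, 50, 500), late, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-4)
})

test_that("one-step observation predictions use pre-update weights", {
  set.seed(11)
  ssm <- rand_stable_ssm()
  tr <- simulate(ssm, N = 10, seed = 3)
  m <- tpc_model(A = matrix(0, 3, 3), C = diag(3), learn_A = TRUE,
                 learn_C = TRUE)
  res <- filter_sequence(m, tr, tpc_config(10, 0.1, eta = 0.01),
                         learn = TRUE)
  ## with A = 0, C = I and x_prev = 0 the first prediction must be zero
  ## regardless of any update applied at step 1
  expect_equal(res$predicted_observations[1, ], c(0, 0, 0))
})

test_that("tpc() fit object supports the standard accessors", {
  ssm <- make_tracking_model(seed = 1)
  tr <- simulate(ssm, N = 100, controls = make_control_sequence(100),
                 seed = 2)
  fit <- tpc(tr, model = ssm, learn = FALSE)
  expect_s3_class(fit, "tpc")
  expect_named(coef(fit), c("A", "B", "C"))
  expect_equal(coef(fit)$A, ssm$A)
  expect_equal(dim(fitted(fit)), c(100, 3))
  expect_equal(residuals(fit), tr$observations - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(dim(predict(fit, n_ahead = 5)), c(5, 3))
  expect_output(print(fit), "observation MSE")
  expect_output(print(summary(fit)), "free energy")
  ## learning front end reduces observation error relative to no learning
  fit_learn <- tpc(tr$observations, u = tr$controls, dx = 3,
                   eta = 1e-4, inference_steps = 20, step_size = 0.2)
  expect_true(is.finite(fit_learn$mse_observation))
})
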