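test_that("projection step matches hand arithmetic", {
  m <- state_space_model(A = diag(2), C = diag(2))
  pr <- kalman_project(c(1, 2), matrix(0, 2, 2), m, 0)
  expect_equal(pr$x_minus, c(1, 2))
  expect_equal(pr$Sigma_minus, diag(2))
  ms <- state_space_model(A = matrix(2), C = matrix(1))
  expect_equal(kalman_project(1, matrix(1), ms, 0)$Sigma_minus, matrix(5))
})

test_that("correction step matches hand cases and Gaussian conditioning", {
  m <- state_space_model(A = diag(2), C = diag(2))
  co <- kalman_correct(c(0, 0), diag(2), m, c(2, 4))
  expect_equal(co$K, 0.5 * diag(2))
  expect_equal(co$x_hat, c(1, 2))
  ## uninformative observations leave the prior untouched
  mb <- state_space_model(A = diag(2), C = diag(2), Sigma_y = 1e8 * diag(2))
  cb <- kalman_correct(c(1, -1), diag(2), mb, c(100, 100))
  expect_equal(cb$x_hat, c(1, -1), tolerance = 1e-5)
  ## random instance vs closed-form conditioning of the joint (x, y)
  set.seed(30)
  for (i in 1:5) {
    ssm <- rand_stable_ssm()
    S <- rand_spd(3)
    xm <- rnorm(3); y <- rnorm(3)
    co <- kalman_correct(xm, S, ssm, y)
    Syy <- ssm$C %*% S %*% t(ssm$C) + ssm$Sigma_y
    Sxy <- S %*% t(ssm$C)
    mu <- xm + drop(Sxy %*% solve(Syy, y - ssm$C %*% xm))
    Sig <- S - Sxy %*% solve(Syy, t(Sxy))
    expect_equal(co$x_hat, mu, tolerance = 1e-10)
    expect_equal(co$Sigma, (Sig + t(Sig)) / 2, tolerance = 1e-10)
  }
})

test_that("posterior means match the brute-force conditioning oracle", {
  set.seed(31)
  worst <- 0
  for (rep in 1:25) {
    ssm <- rand_stable_ssm()
    controls <- matrix(rnorm(20), 20, 1)
    ssm$B <- matrix(rnorm(3, sd = 0.5), 3, 1); ssm$du <- 1
    tr <- simulate(ssm, N = 20, controls = controls, seed = 31 + rep)
    kf <- kalman_filter(ssm, tr)
    for (k in c(1, 5, 20)) {
      bf <- brute_force_posterior(ssm, tr$observations, tr$controls, k)
      worst <- max(worst, max(abs(bf$mean - kf$estimates[k, ])))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("brute-force posterior covariance contracts without process noise", {
  set.seed(32)
  A <- 0.7 * diag(3)
  ssm <- state_space_model(A = A, C = diag(3),
                           Sigma_x = 1e-12 * diag(3), Sigma_y = diag(3))
  tr <- simulate(ssm, N = 12, x0 = rnorm(3), seed = 33)
  v <- vapply(c(2, 6, 12), function(k)
    sum(diag(brute_force_posterior(ssm, tr$observations, tr$controls,
                                   k)$covariance)), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("tPC equilibrium is the zero-variance Kalman update", {
  ## scalar hand case
  ms <- state_space_model(A = matrix(1), C = matrix(1))
  expect_equal(tpc_equilibrium(ms, 0, 0, 2), 1.0)
  ## zero innovation returns the projection
  set.seed(34)
  ssm <- rand_stable_ssm()
  xp <- rnorm(3)
  xm <- drop(ssm$A %*% xp)
  expect_equal(tpc_equilibrium(ssm, xp, 0, drop(ssm$C %*% xm)), xm,
               tolerance = 1e-12)
  ## forcing Sigma_{k-1} = 0 through project/correct reproduces it exactly
  for (i in 1:10) {
    ssm <- rand_stable_ssm()
    xp <- rnorm(3); y <- rnorm(3)
    pr <- kalman_project(xp, matrix(0, 3, 3), ssm, 0)
    co <- kalman_correct(pr$x_minus, pr$Sigma_minus, ssm, y)
    expect_lt(max(abs(co$x_hat - tpc_equilibrium(ssm, xp, 0, y))), 1e-10)
  }
})

test_that("posterior covariances stay PSD over long runs", {
  m <- make_tracking_model(seed = 1)
  tr <- simulate(m, N = 10000, controls = make_control_sequence(10000),
                 seed = 2)
  for (joseph in c(FALSE, TRUE)) {
    kf <- kalman_filter(m, tr, joseph = joseph)
    mins <- vapply(kf$Sigmas[seq(1, 10000, by = 200)], function(S)
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), numeric(1))
    expect_gt(min(mins), -1e-10)
  }
})

test_that("noise-free exact-model Kalman filtering recovers the state", {
  set.seed(35)
  ssm <- rand_stable_ssm()
  clean <- state_space_model(A = ssm$A, C = ssm$C, B = ssm$B,
                             Sigma_x = matrix(0, 3, 3),
                             Sigma_y = 1e-10 * diag(3), noise_free = TRUE)
  tr <- simulate(clean, N = 40, x0 = rnorm(3), seed = 36)
  kf <- kalman_filter(clean, tr)
  expect_lt(mean((kf$estimates[30:40, ] - tr$states[30:40, ])^2), 1e-8)
})

test_that("nonlinear models are rejected by the Kalman routines", {
  m <- state_space_model(A = diag(2), C = diag(2), f = "tanh")
  expect_error(kalman_filter(m, simulate(m, N = 2, seed = 1)),
               class = "tpc_config_error")
  expect_error(tpc_equilibrium(m, c(0, 0), 0, c(0, 0)),
               class = "tpc_config_error")
})
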