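## Shared generators and oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random SPD matrix with eigenvalues bounded away from 0 and infinity.
rand_spd <- function(d, lo = 0.5, hi = 2) {
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  Q %*% diag(runif(d, lo, hi), d) %*% t(Q)
}

## Random tPC network with bounded curvature so that gradient inference at
## moderate step sizes is provably convergent (entries of C uniform in
## [-0.5, 0.5] bound lambda_max(C'C) by its trace).
rand_tpc <- function(dx = 3, dy = 3, f = "linear", du = 1) {
  tpc_model(A = matrix(rnorm(dx * dx, sd = 0.3), dx, dx),
            C = matrix(runif(dy * dx, -0.5, 0.5), dy, dx),
            B = matrix(rnorm(dx * du, sd = 0.3), dx, du),
            Pi_x = rand_spd(dx), Pi_y = rand_spd(dy),
            f = f, x_prev = rnorm(dx))
}

## Matching generative model (Sigma = inverse precision) for a linear network.
ssm_of <- function(m) {
  state_space_model(A = m$A, C = m$C, B = m$B,
                    Sigma_x = solve(m$Pi_x), Sigma_y = solve(m$Pi_y),
                    f = m$f)
}

## Random stable linear-Gaussian system (spectral radius capped).
rand_stable_ssm <- function(dx = 3, dy = 3, rho = 0.8) {
  A <- matrix(rnorm(dx * dx, sd = 0.5), dx, dx)
  r <- max(abs(eigen(A, only.values = TRUE)$values))
  if (r > rho) A <- rho * A / r
  state_space_model(A = A, C = matrix(rnorm(dy * dx), dy, dx),
                    B = matrix(0, dx, 1),
                    Sigma_x = rand_spd(dx), Sigma_y = rand_spd(dy))
}

## Central-difference gradient, an oracle independent of the analytic form.
num_grad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

## The L1-regularised objective that the sparse gradient steps descend
## (1/2-weighted quadratics plus the L1 terms).
sparse_objective <- function(m, x, y, lambda_x) {
  free_energy(m, x, numeric(m$du), y) + lambda_x * sum(abs(x))
}

## First system seed whose tracking model admits the benchmark step size 0.2
## with margin (documented stability precondition, see max_stable_step_size).
stable_tracking_seed <- function(from = 1, min_bound = 0.25) {
  for (s in from:(from + 500)) {
    if (max_stable_step_size(make_tracking_model(seed = s)) > min_bound)
      return(s)
  }
  stop("no stable tracking seed found")
}
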