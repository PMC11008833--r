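#' Sparse free energy
#'
#' The L1-regularised objective used for training on movie-like stimuli:
#' `||y - C f(x)||^2 + ||x - A f(x_prev)||^2 + lambda_x |x|_1 +
#'  lambda_C sum_ij |C_ij|`.
#' There is no control input (`B = 0`) and precisions are identity.  Note the
#' quadratic terms carry no 1/2 factor, so with both lambdas zero this equals
#' twice [free_energy()] at identity precisions.
#'
#' @param m A [tpc_model()].
#' @param x Candidate state.
#' @param y Observation.
#' @param lambda_x,lambda_C Sparsity weights (`>= 0`).
#' @return A non-negative scalar.
#' @export
sparse_free_energy <- function(m, x, y, lambda_x = 0, lambda_C = 0) {
  x <- as_num_vec(x, m$dx, "x"); y <- as_num_vec(y, m$dy, "y")
  ey <- y - drop(m$C %*% apply_nl(x, m$f))
  ex <- x - drop(m$A %*% apply_nl(m$x_prev, m$f))
  sum(ey^2) + sum(ex^2) + lambda_x * sum(abs(x)) + lambda_C * sum(abs(m$C))
}

## sign with sign(0) = 0 (plain subgradient; no proximal step).
sgn <- function(x) sign(x)

#' Sparse inference step
#'
#' [inference_step()] plus the L1 subgradient shrinkage term
#' `- step_size * lambda_x * sign(x)`; with `lambda_x = 0` it is identical
#' to the plain step.  Controls are ignored (`B = 0` in the sparse model).
#'
#' @inheritParams sparse_free_energy
#' @param step_size Euler step (`> 0`).
#' @return Updated state vector.
#' @export
sparse_inference_step <- function(m, x, y, step_size, lambda_x = 0) {
  xn <- inference_step(m, x, numeric(m$du), y, step_size) -
    step_size * lambda_x * sgn(x)
  if (any(!is.finite(xn))) stop("non-finite sparse inference update")
  xn
}

#' Sparse iterative inference
#'
#' Applies [sparse_inference_step()] `cfg$inference_steps` times starting
#' from the carried previous estimate.
#'
#' @param m A [tpc_model()].
#' @param y Observation.
#' @param cfg A [tpc_config()] (its `lambda_x` is used).
#' @return The inferred state estimate.
#' @export
sparse_infer <- function(m, y, cfg = tpc_config()) {
  x <- m$x_prev
  if (m$f == "linear") {
    ## Affine part precomputed; the L1 subgradient stays inside the loop.
    s <- cfg$step_size
    M <- diag(m$dx) - s * (m$Pi_x + crossprod(m$C, m$Pi_y %*% m$C))
    b <- drop(m$A %*% m$x_prev)
    v <- s * (drop(m$Pi_x %*% b) + drop(crossprod(m$C, m$Pi_y %*% y)))
    sl <- s * cfg$lambda_x
    for (i in seq_len(cfg$inference_steps))
      x <- drop(M %*% x) + v - sl * sgn(x)
    if (any(!is.finite(x))) stop("non-finite sparse inference update")
    return(x)
  }
  for (i in seq_len(cfg$inference_steps))
    x <- sparse_inference_step(m, x, y, cfg$step_size, cfg$lambda_x)
  x
}

#' Sparse Hebbian weight update
#'
#' [update_weights()] plus weight decay `- eta * lambda_C * sign(C)` on the
#' emission weights; with `lambda_C = 0` it reduces to the plain update.
#'
#' @inheritParams update_weights
#' @param lambda_C L1 weight on `C`.
#' @return List with updated `model` and deltas `dA`, `dC`.
#' @export
sparse_weight_update <- function(m, x_hat, y, eta, lambda_C = 0) {
  up <- update_weights(m, x_hat, numeric(m$du), y, eta)
  m <- up$model
  dC_l1 <- -eta * lambda_C * sgn(m$C)
  if (m$learn_C) m$C <- m$C + dC_l1
  list(model = m, dA = up$dA, dC = up$dC + dC_l1)
}
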