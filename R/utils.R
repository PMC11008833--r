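#' @keywords internal
"_PACKAGE"

## Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("tpc_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

## Symmetric positive (semi-)definite check via Cholesky.
check_spd <- function(M, name, allow_zero = FALSE) {
  if (!is_square(M)) stop_config(name, " must be a square matrix")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop_config(name, " must be symmetric")
  if (allow_zero && all(M == 0)) return(invisible(M))
  ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
  if (!ok) stop_config(name, " must be positive definite (Cholesky failed)")
  invisible(M)
}

## One multivariate normal draw N(0, Sigma); Sigma = 0 allowed (returns zeros).
rmvn0 <- function(Sigma) {
  d <- nrow(Sigma)
  if (all(Sigma == 0)) return(numeric(d))
  drop(rnorm(d) %*% chol(Sigma))
}

as_num_vec <- function(x, d, name) {
  x <- as.numeric(x)
  if (length(x) == 1 && d > 1) x <- rep(x, d)
  if (length(x) != d) stop_config(name, " must have length ", d)
  if (any(!is.finite(x))) stop(name, " contains non-finite values")
  x
}

## Nonlinearity and its elementwise derivative.
apply_nl <- function(x, f) if (f == "tanh") tanh(x) else x

nl_deriv <- function(x, f) {
  if (f == "tanh") 1 - tanh(x)^2 else rep(1, length(x))
}

match_nl <- function(f) match.arg(f, c("linear", "tanh"))

#' Largest stable inference step size
#'
#' Gradient-descent inference on the free energy of a linear model converges
#' only if the step size is below `2 / lambda_max(Pi_x + C' Pi_y C)` (the
#' curvature of the quadratic objective).  This returns that bound; a common
#' choice in practice is half of it.
#'
#' @param m A [tpc_model()] (or a [state_space_model()], whose noise
#'   covariances are inverted to precisions).
#' @return The supremum of convergent step sizes (a positive scalar).
#' @examples
#' m <- tpc_model(A = diag(2), C = diag(2))
#' max_stable_step_size(m)  # hessian = 2 I -> bound 1
#' @export
max_stable_step_size <- function(m) {
  if (inherits(m, "state_space_model")) m <- as_tpc_model(m)
  H <- m$Pi_x + crossprod(m$C, m$Pi_y %*% m$C)
  2 / max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

## Mean squared error averaged over time steps and dimensions.
mse <- function(a, b) {
  if (length(a) == 0) return(NaN)
  mean((a - b)^2)
}
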