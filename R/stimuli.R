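#' Synthetic drifting-grating movie dataset
#'
#' Generates movie patches of drifting oriented sinusoidal gratings with
#' per-movie random orientation, spatial frequency, speed and phase -- a
#' controlled stand-in for natural-movie patches -- and augments the dataset
#' with left-right mirrored copies so both drift directions are represented.
#'
#' @param n_movies Number of base movies (`>= 1`; the augmented dataset has
#'   twice as many).
#' @param patch_size Height = width of each frame in pixels.
#' @param n_frames Frames per movie.
#' @param speeds Candidate drift speeds (pixels/frame); sampled per movie.
#' @param orientations Candidate orientations (rad); default 8 evenly spaced.
#' @param cycles Candidate spatial frequencies (cycles per patch).
#' @param seed Seed for all draws.
#' @param augment Append mirrored copies (default `TRUE`).
#' @return Object of class `movie_dataset`: list of `movies` (arrays
#'   `n_frames` x `patch_size` x `patch_size`), plus the generation
#'   parameters.
#' @export
generate_synthetic_movies <- function(n_movies = 8, patch_size = 16,
                                      n_frames = 50,
                                      speeds = c(0.5, 1, 2),
                                      orientations = NULL,
                                      cycles = c(1, 2, 3),
                                      seed = NULL, augment = TRUE) {
  if (n_movies < 1) stop_config("n_movies must be >= 1")
  orientations <- orientations %||% (seq_len(8) - 1) * pi / 8
  P <- patch_size
  movies <- with_seed(seed, lapply(seq_len(n_movies), function(i) {
    th <- sample(orientations, 1)
    sp <- sample(speeds, 1)
    cyc <- sample(cycles, 1)
    ph <- runif(1, 0, 2 * pi)
    nu <- cyc / P  # cycles per pixel
    gx <- outer(seq_len(P) - 1, rep(1, P)) * cos(th) +
      outer(rep(1, P), seq_len(P) - 1) * sin(th)
    arr <- array(0, c(n_frames, P, P))
    for (t in seq_len(n_frames))
      arr[t, , ] <- sin(2 * pi * nu * (gx - sp * (t - 1)) + ph)
    arr
  }))
  if (augment) {
    mirrored <- lapply(movies, function(a) a[, , dim(a)[3]:1, drop = FALSE])
    movies <- c(movies, mirrored)
  }
  structure(list(movies = movies, patch_size = P, n_frames = n_frames,
                 seed = seed, augmented = augment),
            class = "movie_dataset")
}

#' @export
print.movie_dataset <- function(x, ...) {
  cat(sprintf("Movie dataset: %d movies of %d frames, %dx%d pixels\n",
              length(x$movies), x$n_frames, x$patch_size, x$patch_size))
  invisible(x)
}

#' Difference-of-Gaussians (centre-surround) kernel
#'
#' Each Gaussian is normalised to unit sum before subtraction, so the kernel
#' sums to zero exactly and rejects constant (DC) input.
#'
#' @param sigma_center,sigma_surround Standard deviations in pixels
#'   (`sigma_surround > sigma_center > 0`).
#' @param radius Kernel half-width (default `ceiling(3 * sigma_surround)`).
#' @return A square matrix of side `2 * radius + 1`.
#' @export
dog_kernel <- function(sigma_center = 1, sigma_surround = 2,
                       radius = ceiling(3 * sigma_surround)) {
  if (!(sigma_surround > sigma_center && sigma_center > 0))
    stop_config("need sigma_surround > sigma_center > 0")
  g <- function(s) {
    d <- outer((-radius:radius)^2, (-radius:radius)^2, `+`)
    K <- exp(-d / (2 * s^2))
    K / sum(K)
  }
  g(sigma_center) - g(sigma_surround)
}

## 2-D "same" convolution with replicate (edge) padding.
conv2d_replicate <- function(M, K) {
  r <- (nrow(K) - 1) / 2
  n <- nrow(M); p <- ncol(M)
  ri <- pmin(pmax(seq_len(n + 2 * r) - r, 1), n)
  ci <- pmin(pmax(seq_len(p + 2 * r) - r, 1), p)
  P <- M[ri, ci, drop = FALSE]
  out <- matrix(0, n, p)
  for (a in seq_len(nrow(K))) for (b in seq_len(ncol(K))) {
    if (K[a, b] == 0) next
    out <- out + K[a, b] * P[(a - 1) + seq_len(n), (b - 1) + seq_len(p)]
  }
  out
}

#' Retina-like centre-surround filtering of a movie
#'
#' Convolves every frame with a zero-mean difference-of-Gaussians kernel
#' (replicate padding at the borders).  Constant frames map to zero.
#'
#' @param movie Array `n_frames` x `H` x `W`.
#' @param sigma_center,sigma_surround Kernel scales in pixels.
#' @return Filtered movie of the same shape.
#' @export
centre_surround_filter <- function(movie, sigma_center = 1,
                                   sigma_surround = 2) {
  K <- dog_kernel(sigma_center, sigma_surround)
  out <- movie
  for (t in seq_len(dim(movie)[1]))
    out[t, , ] <- conv2d_replicate(movie[t, , ], K)
  out
}

#' Centre-surround filter and z-score a movie dataset
#'
#' Applies [centre_surround_filter()] to each movie and standardises it to
#' zero mean and unit variance (movies with zero variance are left at zero).
#'
#' @param dataset A `movie_dataset`.
#' @param sigma_center,sigma_surround Kernel scales in pixels.
#' @return The preprocessed `movie_dataset`.
#' @export
preprocess_movies <- function(dataset, sigma_center = 1, sigma_surround = 2) {
  dataset$movies <- lapply(dataset$movies, function(a) {
    a <- centre_surround_filter(a, sigma_center, sigma_surround)
    s <- stats::sd(a)
    if (s > 0) (a - mean(a)) / s else a * 0
  })
  dataset
}

## Flatten a movie to a frames x pixels matrix (column-major per frame).
flatten_movie <- function(movie) {
  t(apply(movie, 1, as.vector))
}

#' Train a sparse tPC model on a movie dataset
#'
#' Runs the filtering/learning loop with the sparse operations over all
#' movies and epochs: frames are flattened to `patch_size^2` observation
#' vectors, `B = 0`, `f` linear, the recurrent weights start at zero, the
#' emission weights at small Gaussian values, and the carried estimate
#' `x_prev` is reset to zero at every movie boundary (no temporal leakage
#' across movies).
#'
#' @param dataset A (preprocessed) `movie_dataset`.
#' @param hidden_size Number of hidden neurons.
#' @param cfg A [tpc_config()]; its `eta`, `lambda_x`, `lambda_C`,
#'   `inference_steps`, `step_size` and `seed` are used.
#' @param epochs Number of passes over the dataset.
#' @param C_init_sd Standard deviation of the initial emission weights.
#' @return List with the trained `model` (a [tpc_model()]) and
#'   `reconstruction_error`: mean `||y - C xhat||^2 / dy` per frame, by
#'   epoch.
#' @export
train_movie_model <- function(dataset, hidden_size, cfg = tpc_config(),
                              epochs = 1, C_init_sd = 0.1) {
  dy <- dataset$patch_size^2
  C0 <- with_seed(cfg$seed,
                  matrix(rnorm(dy * hidden_size, sd = C_init_sd),
                         dy, hidden_size))
  m <- tpc_model(A = matrix(0, hidden_size, hidden_size), C = C0,
                 f = "linear", learn_A = TRUE, learn_C = TRUE)
  rec <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    err <- 0; nframes <- 0
    for (mov in dataset$movies) {
      Y <- flatten_movie(mov)
      m$x_prev <- numeric(hidden_size)
      for (k in seq_len(nrow(Y))) {
        y <- Y[k, ]
        x_hat <- sparse_infer(m, y, cfg)
        err <- err + mse(drop(m$C %*% x_hat), y)
        nframes <- nframes + 1
        m <- sparse_weight_update(m, x_hat, y, cfg$eta, cfg$lambda_C)$model
        if (any(!is.finite(m$C)))
          stop("training diverged at epoch ", ep)
      }
    }
    rec[ep] <- err / nframes
  }
  list(model = m, reconstruction_error = rec)
}

#' White-noise probe movie
#'
#' @param n_frames Number of frames.
#' @param patch_size Frame side length.
#' @param seed Seed.
#' @return Array `n_frames` x `patch_size` x `patch_size` of i.i.d. standard
#'   normal pixels.
#' @export
white_noise_movie <- function(n_frames, patch_size, seed = NULL) {
  with_seed(seed,
            array(rnorm(n_frames * patch_size^2),
                  c(n_frames, patch_size, patch_size)))
}

#' Reverse correlation of an activity trace with stimulus frames
#'
#' Computes `1/(T - lags) * sum_{k = lags..T} x_k * y_{k-lags+1 : k}`: the
#' activity-weighted average of the preceding stimulus frames (the divisor
#' `T - lags` with `T - lags + 1` terms follows the conventional estimator
#' verbatim; set `divisor = "T-4"` for the unbiased count).
#'
#' @param activity Numeric vector of length `T` (one neuron's responses).
#' @param frames `T` x `n_pixels` matrix of stimulus frames.
#' @param lags Number of frames in the kernel (default 5).
#' @param divisor `"T-5"` (default, i.e. `T - lags`) or `"T-4"`
#'   (`T - lags + 1`).
#' @return A `lags` x `n_pixels` matrix; row 1 is lag 0 (the current frame),
#'   row `lags` the oldest.
#' @export
reverse_correlation <- function(activity, frames, lags = 5,
                                divisor = c("T-5", "T-4")) {
  divisor <- match.arg(divisor)
  frames <- as.matrix(frames)
  T_ <- length(activity)
  if (nrow(frames) != T_) stop_config("activity and frames lengths differ")
  if (T_ < lags) stop_config("need at least `lags` frames")
  ks <- lags:T_
  den <- if (divisor == "T-5") T_ - lags else T_ - lags + 1
  out <- matrix(0, lags, ncol(frames))
  for (l in 0:(lags - 1))
    out[l + 1, ] <- colSums(activity[ks] * frames[ks - l, , drop = FALSE]) / den
  out
}

#' Spatio-temporal receptive field by white-noise reverse correlation
#'
#' Presents a white-noise movie to the model, lets the hidden neurons relax
#' by the (sparse) inference dynamics at every frame while the carried
#' estimate advances, and reverse-correlates the chosen neuron's activity
#' trace with the preceding stimulus frames.
#'
#' @param model A trained [tpc_model()].
#' @param noise_frames White-noise movie: array `T` x `H` x `W` (e.g. from
#'   [white_noise_movie()]) or a `T` x `H*W` matrix with attribute-free
#'   square frames.
#' @param neuron_index Index of the hidden neuron.
#' @param cfg A [tpc_config()] (inference settings; `lambda_x` used if the
#'   model was trained sparsely).
#' @param lags Temporal extent of the kernel in frames (default 5).
#' @param divisor Normalisation, see [reverse_correlation()].
#' @return Object of class `tpc_strf`: `kernel` (array `lags` x `H` x `W`,
#'   slice 1 = lag 0), `neuron_index`, `n_samples`.
#' @export
compute_strf <- function(model, noise_frames, neuron_index,
                         cfg = tpc_config(inference_steps = 30),
                         lags = 5, divisor = c("T-5", "T-4")) {
  if (is.array(noise_frames) && length(dim(noise_frames)) == 3) {
    H <- dim(noise_frames)[2]; W <- dim(noise_frames)[3]
    Y <- flatten_movie(noise_frames)
  } else {
    Y <- as.matrix(noise_frames)
    H <- W <- as.integer(round(sqrt(ncol(Y))))
    if (H * W != ncol(Y)) stop_config("frames are not square")
  }
  T_ <- nrow(Y)
  if (T_ < lags) stop_config("need at least `lags` noise frames")
  if (neuron_index < 1 || neuron_index > model$dx)
    stop_config("neuron_index out of range")
  act <- numeric(T_)
  for (k in seq_len(T_)) {
    x_hat <- sparse_infer(model, Y[k, ], cfg)
    act[k] <- x_hat[neuron_index]
    model$x_prev <- x_hat
  }
  rc <- reverse_correlation(act, Y, lags = lags, divisor = divisor)
  kernel <- array(0, c(lags, H, W))
  for (l in seq_len(lags)) kernel[l, , ] <- matrix(rc[l, ], H, W)
  structure(list(kernel = kernel, neuron_index = neuron_index,
                 n_samples = T_, lags = lags),
            class = "tpc_strf")
}

#' @export
print.tpc_strf <- function(x, ...) {
  cat(sprintf("STRF of neuron %d: %d lags, %dx%d pixels (T = %d frames)\n",
              x$neuron_index, x$lags, dim(x$kernel)[2], dim(x$kernel)[3],
              x$n_samples))
  invisible(x)
}

#' Plot a spatio-temporal receptive field
#'
#' One panel per lag, lag 0 rightmost (most recent frame).
#'
#' @param x A `tpc_strf`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.tpc_strf <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$lags), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  zl <- max(abs(x$kernel)) * c(-1, 1)
  for (l in x$lags:1)
    graphics::image(t(x$kernel[l, , ])[, dim(x$kernel)[2]:1],
                    zlim = zl, axes = FALSE,
                    main = paste0("lag -", l - 1), ...)
  invisible(x)
}

#' Export an STRF as CSV
#'
#' Long format with columns `lag` (0 = current frame), `row`, `col`, `value`.
#'
#' @param strf A `tpc_strf`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_strf_csv <- function(strf, path) {
  d <- dim(strf$kernel)
  df <- expand.grid(lag = 0:(d[1] - 1), row = seq_len(d[2]),
                    col = seq_len(d[3]))
  df$value <- strf$kernel[cbind(df$lag + 1, df$row, df$col)]
  utils::write.csv(df[order(df$lag, df$row, df$col), ], path,
                   row.names = FALSE)
  invisible(path)
}
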