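test_that("zero drift speed yields a static movie", {
  ds <- generate_synthetic_movies(n_movies = 2, patch_size = 8,
                                  n_frames = 10, speeds = 0, seed = 1,
                                  augment = FALSE)
  for (mov in ds$movies)
    for (t in 2:10) expect_equal(mov[t, , ], mov[1, , ])
})

test_that("augmentation doubles the dataset with mirrored movies", {
  ds <- generate_synthetic_movies(n_movies = 3, patch_size = 8,
                                  n_frames = 6, seed = 2, augment = TRUE)
  expect_length(ds$movies, 6)
  for (i in 1:3)
    expect_equal(ds$movies[[i + 3]], ds$movies[[i]][, , 8:1])
})

test_that("movie generation is reproducible from the seed", {
  a <- generate_synthetic_movies(n_movies = 2, seed = 3)
  b <- generate_synthetic_movies(n_movies = 2, seed = 3)
  expect_identical(a$movies, b$movies)
})

test_that("the DoG kernel is zero-mean and rejects constant frames", {
  K <- dog_kernel(1, 2)
  expect_equal(sum(K), 0, tolerance = 1e-12)
  mov <- array(7, c(3, 12, 12))
  out <- centre_surround_filter(mov)
  expect_lt(max(abs(out)), 1e-10)
  expect_error(dog_kernel(2, 1), class = "tpc_config_error")
})

test_that("an impulse reproduces the analytic DoG kernel", {
  P <- 15
  mov <- array(0, c(1, P, P)); mov[1, 8, 8] <- 1
  out <- centre_surround_filter(mov, 1, 2)
  K <- dog_kernel(1, 2)  # radius 6, 13x13
  expect_equal(out[1, 2:14, 2:14], K[13:1, 13:1], tolerance = 1e-12)
})

test_that("preprocessing leaves movies standardised", {
  ds <- generate_synthetic_movies(n_movies = 2, patch_size = 8,
                                  n_frames = 10, seed = 4)
  ds <- preprocess_movies(ds)
  for (mov in ds$movies) {
    expect_lt(abs(mean(mov)), 1e-10)
    expect_equal(sd(mov), 1, tolerance = 1e-10)
  }
})

test_that("movie training reduces reconstruction error", {
  ds <- preprocess_movies(generate_synthetic_movies(
    n_movies = 3, patch_size = 8, n_frames = 20, seed = 5))
  fit <- train_movie_model(ds, hidden_size = 12,
                           tpc_config(inference_steps = 30, step_size = 0.1,
                                      eta = 5e-3, seed = 6), epochs = 4)
  expect_lt(fit$reconstruction_error[4], fit$reconstruction_error[1])
  expect_s3_class(fit$model, "tpc_model")
})

test_that("emission sparsity increases with the L1 weight", {
  ds <- preprocess_movies(generate_synthetic_movies(
    n_movies = 3, patch_size = 8, n_frames = 20, seed = 7))
  dense <- train_movie_model(ds, 12,
    tpc_config(30, 0.1, eta = 5e-3, lambda_C = 0, seed = 8), epochs = 3)
  sparse <- train_movie_model(ds, 12,
    tpc_config(30, 0.1, eta = 5e-3, lambda_C = 0.05, seed = 8), epochs = 3)
  frac_small <- function(C) mean(abs(C) < 0.01)
  expect_gt(frac_small(sparse$model$C), frac_small(dense$model$C))
})

test_that("reverse correlation of zero activity is a zero kernel", {
  nf <- white_noise_movie(50, 6, seed = 9)
  m <- tpc_model(A = matrix(0, 1, 1), C = matrix(0, 36, 1))
  st <- compute_strf(m, nf, 1, tpc_config(10, 0.2))
  expect_equal(max(abs(st$kernel)), 0)
  expect_equal(dim(st$kernel), c(5, 6, 6))
})

test_that("constant activity averages to a vanishing kernel", {
  set.seed(10)
  Y <- matrix(rnorm(4000 * 16), 4000, 16)
  rc <- reverse_correlation(rep(2, 4000), Y)
  expect_lt(max(abs(rc)), 0.15)  # O(1/sqrt(T)) with c = 2
})

test_that("reverse correlation recovers a known linear spatial filter", {
  set.seed(11)
  w <- rnorm(36); w <- w / sqrt(sum(w^2))
  nf <- white_noise_movie(6000, 6, seed = 12)
  Y <- t(apply(nf, 1, as.vector))
  act <- drop(Y %*% w)  # surrogate neuron, no dynamics
  rc <- reverse_correlation(act, Y)
  cosim <- sum(rc[1, ] * w) / sqrt(sum(rc[1, ]^2) * sum(w^2))
  expect_gt(cosim, 0.95)
  ## non-zero lags carry no structure
  expect_lt(sqrt(sum(rc[3, ]^2)) / sqrt(sum(rc[1, ]^2)), 0.25)
})

test_that("reverse-correlation normalisation variants differ as documented", {
  set.seed(13)
  Y <- matrix(rnorm(100 * 4), 100, 4)
  act <- rnorm(100)
  a <- reverse_correlation(act, Y, divisor = "T-5")
  b <- reverse_correlation(act, Y, divisor = "T-4")
  expect_equal(a * (100 - 5), b * (100 - 4), tolerance = 1e-12)
  expect_error(reverse_correlation(act[1:3], Y[1:3, ]),
               class = "tpc_config_error")
})

test_that("STRF export writes a readable CSV grid", {
  nf <- white_noise_movie(30, 4, seed = 14)
  m <- tpc_model(A = matrix(0, 1, 1), C = matrix(rnorm(16), 16, 1))
  st <- compute_strf(m, nf, 1, tpc_config(10, 0.2))
  f <- tempfile(fileext = ".csv")
  write_strf_csv(st, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 5 * 16)
  expect_equal(df$value[df$lag == 0 & df$row == 1 & df$col == 1],
               st$kernel[1, 1, 1])
})
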