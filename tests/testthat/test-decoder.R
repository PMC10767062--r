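test_that("lag grid reproduces the decoding-window arithmetic", {
  lw <- lag_grid(-0.2, 0.35, 64)
  expect_equal(length(lw$shifts), 36)
  expect_equal(range(lw$shifts), c(-13, 22))
  expect_true(0L %in% lw$shifts)
  expect_equal(lag_grid(0, 0, 64)$shifts, 0L)
  lw2 <- lag_grid(-0.1, 0.4, 128)
  expect_equal(range(lw2$shifts), c(-13, 51))
  expect_equal(length(lw2$shifts), 65)
  expect_error(lag_grid(0.5, -0.5, 64), "t_min")
})

test_that("lagged design matrix shifts with zero padding, channel-major", {
  lw <- lag_grid(-1, 1, 1)
  D <- build_lagged_matrix(matrix(c(1, 2, 3), nrow = 1), lw)
  expect_equal(D, rbind(c(0, 1, 2), c(1, 2, 3), c(2, 3, 0)))
  # single channel, zero shift: identity lagging
  x <- rnorm(50)
  D0 <- build_lagged_matrix(matrix(x, nrow = 1), lag_grid(0, 0, 64))
  expect_equal(drop(D0), x)
  # shape contract: channels * |shifts| columns, time rows
  eeg <- matrix(rnorm(5 * 100), nrow = 5)
  lw3 <- lag_grid(-0.05, 0.1, 64)
  D3 <- build_lagged_matrix(eeg, lw3)
  expect_equal(dim(D3), c(100, 5 * length(lw3$shifts)))
})

test_that("ridge solution matches hand examples and least squares", {
  expect_equal(ridge_fit(diag(2), c(3, 5), 0), c(3, 5))
  expect_equal(ridge_fit(diag(2), c(3, 5), 1), c(1.5, 2.5))
  set.seed(41)
  D <- matrix(rnorm(60), 20, 3); s <- rnorm(20)
  expect_equal(ridge_fit(D, s, 0), unname(coef(lm.fit(D, s))),
               tolerance = 1e-10)
  # extreme shrinkage drives the coefficients to zero
  expect_lt(sqrt(sum(ridge_fit(D, s, 1e9)^2)), 1e-6)
  expect_error(ridge_fit(matrix(c(1, NA, 0, 1), 2), c(1, 1), 0), "finite")
})

test_that("ridge agrees with brute-force penalized least squares", {
  # independent oracle: BFGS minimisation of the penalised objective
  brute <- function(D, s, lambda) {
    obj <- function(g) sum((s - D %*% g)^2) + lambda * sum(g^2)
    grad <- function(g) -2 * crossprod(D, s - D %*% g) + 2 * lambda * g
    stats::optim(rep(0, ncol(D)), obj, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))$par
  }
  set.seed(7)
  for (i in 1:10) {
    D <- matrix(rnorm(160), 20, 8)
    s <- rnorm(20)
    lambda <- 10^runif(1, -3, 2)
    g_closed <- ridge_fit(D, s, lambda)
    g_brute <- brute(D, s, lambda)
    expect_lt(sqrt(sum((g_closed - g_brute)^2)) / sqrt(sum(g_closed^2)), 1e-6)
  }
})

test_that("coefficient norm shrinks monotonically with lambda", {
  set.seed(13)
  D <- matrix(rnorm(200), 25, 8); s <- rnorm(25)
  norms <- sapply(10^seq(-4, 4), function(l) sqrt(sum(ridge_fit(D, s, l)^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("rank-deficient design at lambda zero warns and returns minimum norm", {
  D <- cbind(1:4, 1:4)  # duplicated column
  s <- c(1, 2, 3, 4)
  expect_warning(g <- ridge_fit(D, s, 0), "minimum-norm")
  expect_equal(drop(D %*% g), s, tolerance = 1e-8)
  expect_equal(unname(g[1]), unname(g[2]), tolerance = 1e-8)  # equal split
})

test_that("reconstruction is the least-squares projection on the training epoch", {
  set.seed(3)
  eeg <- matrix(rnorm(3 * 200), nrow = 3)
  s <- rnorm(200)
  lw <- lag_grid(-0.05, 0.1, 64)
  D <- build_lagged_matrix(eeg, lw)
  g <- ridge_fit(D, s, 0)
  model <- list(g = g, lag_window = lw)
  s_hat <- reconstruct(eeg, model)
  expect_equal(length(s_hat), 200)
  # residual orthogonal to the design columns (normal equations)
  expect_lt(max(abs(crossprod(D, s - s_hat))), 1e-8 * sqrt(sum(s^2)))
  # all-zero coefficients give an all-zero reconstruction
  expect_equal(reconstruct(eeg, list(g = rep(0, length(g)), lag_window = lw)),
               rep(0, 200))
})

test_that("Pearson scoring matches closed-form values and rejects constants", {
  expect_equal(score_reconstruction(1:10, 1:10), 1)
  expect_equal(score_reconstruction(1:10, -(1:10)), -1)
  expect_equal(score_reconstruction(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.982708,
               tolerance = 1e-6)
  expect_error(score_reconstruction(rep(1, 5), 1:5), "constant")
})

test_that("nested LOO returns one model per epoch and decodes clean signal", {
  eps <- tiny_epochs(5, snr = Inf, seed = 20)
  out <- nested_loo_decode(eps, t_min = -0.1, t_max = 0.25,
                           lambda_grid = c(1e-6, 1e-2))
  expect_equal(nrow(out), 5)
  expect_equal(length(out$model), 5)
  expect_true(all(out$accuracy >= 0.99))
})

test_that("a singleton lambda grid forces that selection", {
  eps <- tiny_epochs(4, snr = 1, seed = 30)
  out <- nested_loo_decode(eps, t_min = -0.1, t_max = 0.25, lambda_grid = 3.7)
  expect_true(all(out$lambda_selected == 3.7))
})

test_that("three identical noise-free epochs are all reconstructed near-perfectly", {
  one <- tiny_epochs(1, snr = Inf, seed = 40)
  eps <- one[rep(1, 3), ]
  out <- nested_loo_decode(eps, t_min = -0.1, t_max = 0.25,
                           lambda_grid = 1e-6)
  expect_true(all(out$accuracy >= 0.99))
})

test_that("accuracy increases with SNR on paired epoch sets", {
  lo <- nested_loo_decode(tiny_epochs(8, snr = 0.1, seed = 50),
                          t_min = -0.1, t_max = 0.25, lambda_grid = c(1, 100))
  hi <- nested_loo_decode(tiny_epochs(8, snr = 5, seed = 50),
                          t_min = -0.1, t_max = 0.25, lambda_grid = c(1, 100))
  expect_gt(mean(hi$accuracy), mean(lo$accuracy))
})

test_that("mismatched envelope pairing scores at chance", {
  eps <- tiny_epochs(8, snr = 2, seed = 60)
  out <- nested_loo_decode(eps, t_min = -0.1, t_max = 0.25, lambda_grid = 1)
  set.seed(61)
  rs <- replicate(60, {
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    cor(out$reconstruction[[i]], out$envelope[[j]])
  })
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)) + 0.05)
})
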