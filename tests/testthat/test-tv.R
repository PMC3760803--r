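test_that("moving-window variance matches the brute-force window statistic", {
  grid <- volume_grid(c(10, 10, 1), c(1, 1, 2.5))
  set.seed(12)
  el <- array(rnorm(prod(grid$shape) * 6, 0, 2), c(grid$shape, 6))
  nf <- tensor_field(el, grid)
  v <- local_variance_tensor(nf, 5)
  for (c in c(1, 4)) for (i in 3:8) for (j in 3:8) {
    blk <- el[(i - 2):(i + 2), (j - 2):(j + 2), 1, c]
    expect_equal(unname(v$elements[i, j, 1, c]), var(as.vector(blk)),
                 tolerance = 1e-12)
  }
  # edges use the truncated window
  blk <- el[1:3, 1:3, 1, 1]
  expect_equal(unname(v$elements[1, 1, 1, 1]), var(as.vector(blk)),
               tolerance = 1e-12)
  # constant field has zero variance
  cf <- tensor_field(array(3, c(grid$shape, 6)), grid)
  expect_true(all(local_variance_tensor(cf, 5)$elements == 0))
  expect_error(local_variance_tensor(nf, 4), "odd")
  expect_error(local_variance_tensor(nf, 11), "larger than slice")
})

test_that("window variance estimates the population variance of i.i.d. noise", {
  grid <- volume_grid(c(60, 60, 4), c(1, 1, 2.5))
  nf <- make_noise_tensor_field(grid, noise_model(base_sigma = 2,
                                                  center_gain = 1, seed = 1))
  v <- local_variance_tensor(nf, 5)
  expect_equal(mean(v$elements[, , , 1]), 4, tolerance = 0.05)
})

test_that("the coupled TV seminorm reduces to scalar TV and is 1-homogeneous", {
  set.seed(5)
  u <- matrix(rnorm(64), 8, 8)
  expect_equal(tv_norm_tensor(u), tv_brute(u), tolerance = 1e-12)
  expect_equal(tv_norm_tensor(matrix(7, 8, 8)), 0)
  A <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  expect_equal(tv_norm_tensor(-2.5 * A), 2.5 * tv_norm_tensor(A),
               tolerance = 1e-12)
  # off-diagonal channels count twice in the squared gradient norm
  one_off <- array(0, c(8, 8, 6)); one_off[, , 4] <- u
  one_diag <- array(0, c(8, 8, 6)); one_diag[, , 1] <- u
  expect_equal(tv_norm_tensor(one_off), sqrt(2) * tv_norm_tensor(one_diag),
               tolerance = 1e-12)
})

test_that("zero noise level or constant input leave the image untouched", {
  set.seed(2)
  f <- matrix(rnorm(256), 16, 16)
  u <- chambolle_scalar(f, 0)
  expect_identical(unclass(u)[seq_along(f)], f[seq_along(f)])
  cf <- matrix(4, 16, 16)
  expect_equal(unclass(chambolle_scalar(cf, 1))[1:256], rep(4, 256))
})

test_that("the converged residual satisfies the discrepancy principle", {
  set.seed(7)
  f0 <- matrix(0, 32, 32); f0[10:22, 5:27] <- 2
  sigma <- 0.15
  f <- f0 + matrix(rnorm(1024, 0, sigma), 32, 32)
  u <- chambolle_scalar(f, sigma, tv_solve_options(outer_iterations = 100))
  expect_equal(attr(u, "residual"), sigma * 32, tolerance = 0.02)
  expect_true(attr(u, "converged"))
})

test_that("the dual projection solution matches an independent ROF minimizer", {
  set.seed(42)
  f0 <- matrix(0, 32, 32); f0[8:24, 8:24] <- 1
  sigma <- 0.1
  f <- f0 + matrix(rnorm(1024, 0, sigma), 32, 32)
  u <- chambolle_scalar(f, sigma,
                        tv_solve_options(tol = 1e-6, outer_iterations = 200))
  uref <- rof_reference(f, attr(u, "lambda"), n_iter = 20000, tol = 1e-12)
  expect_lt(max(abs(u - uref)), 1e-3 * diff(range(f)))
})

test_that("the dual energy is non-increasing for a stable step size", {
  set.seed(3)
  f <- array(rnorm(30 * 30 * 2), c(30, 30, 2))
  lam <- array(0.5, dim(f))
  st <- tvdti:::tv_dual_iterate(f, lam,
                                tv_solve_options(inner_iterations = 150),
                                trace_energy = TRUE)
  expect_true(all(diff(st$dual_trace) <= 1e-12))
  expect_error(tv_solve_options(tau = 0.2), "1/8")
})

test_that("zero-variance tensors pass through the slice regularizer", {
  fx <- phantom_slice_fixture()
  v0 <- fx$variance * 0
  out <- regularize_tensor_slice(fx$noisy, v0)
  expect_equal(out[seq_along(fx$noisy)], fx$noisy[seq_along(fx$noisy)],
               tolerance = 1e-8)
})

test_that("regularization reduces the error to ground truth in every channel", {
  fx <- phantom_slice_fixture()
  out <- regularize_tensor_slice(fx$noisy, fx$variance)
  for (c in 1:6) {
    rmse_before <- sqrt(mean((fx$noisy[, , c] - fx$truth[, , c])^2))
    rmse_after <- sqrt(mean((out[, , c] - fx$truth[, , c])^2))
    expect_lt(rmse_after, rmse_before)
  }
})

test_that("the regularization tensor is weaker (smaller) where the noise is stronger", {
  fx <- phantom_slice_fixture()
  out <- regularize_tensor_slice(fx$noisy, fx$variance)
  rt <- attr(out, "reg_tensor")
  gain <- tvdti:::noise_gain_map(fx$grid, 3)[, , fx$z]
  for (c in 1:6)
    expect_lt(mean(rt[, , c][gain > 2.3]), mean(rt[, , c][gain < 1.3]))
})

test_that("local residual RMS tracks the local noise level in homogeneous regions", {
  fx <- phantom_slice_fixture(seed = 4)
  out <- regularize_tensor_slice(fx$noisy, fx$variance,
                                 tv_solve_options(outer_iterations = 80,
                                                  tol = 1e-6))
  interior <- matrix(FALSE, 60, 60); interior[10:50, 10:50] <- TRUE
  m <- interior & fx$labels == 0
  for (c in 1:6) {
    res2 <- tvdti:::window_mean((out[, , c] - fx$noisy[, , c])^2, 5)$mean
    ratio <- sqrt(res2[m] / fx$variance[, , c][m])
    expect_lt(abs(median(ratio) - 1), 0.1)
  }
})

test_that("the converged residual is insensitive to the initial regularization scale", {
  fx <- phantom_slice_fixture()
  res <- sapply(c(0.3, 1, 3), function(l0) {
    out <- regularize_tensor_slice(fx$noisy, fx$variance,
                                   tv_solve_options(outer_iterations = 80,
                                                    tol = 1e-6),
                                   lambda0_scale = l0)
    sqrt(mean((out - fx$noisy)^2))
  })
  expect_lt(diff(range(res)) / mean(res), 0.03)
})

test_that("doubling the variance never decreases the amount of smoothing", {
  fx <- phantom_slice_fixture()
  o1 <- regularize_tensor_slice(fx$noisy, fx$variance)
  o2 <- regularize_tensor_slice(fx$noisy, 2 * fx$variance)
  d1 <- sqrt(sum((o1 - fx$noisy)^2))
  d2 <- sqrt(sum((o2 - fx$noisy)^2))
  expect_gte(d2, d1)
})

test_that("edges survive regularization while flat-region noise collapses", {
  set.seed(31)
  nx <- 40
  truth <- array(0, c(nx, nx, 6))
  truth[, , 1:3] <- 0.7e-3
  truth[1:20, , 1] <- 1.7e-3                    # step edge in Dxx
  sigma <- 1.2e-4
  noise <- array(rnorm(nx * nx * 6, 0, sigma), c(nx, nx, 6))
  noisy <- truth + noise
  variance <- array(sigma^2, c(nx, nx, 6))
  out <- regularize_tensor_slice(noisy, variance)
  edge_grad <- function(u) mean(abs(u[21, , 1] - u[20, , 1]))
  expect_gt(edge_grad(out), 0.8 * edge_grad(truth))
  flat <- out[5:16, 5:36, 1]
  expect_lt(var(as.vector(flat)), var(as.vector(noisy[5:16, 5:36, 1])) / 5)
})

test_that("field regularization is slice-independent and a no-op for zero noise", {
  ph <- reference_phantom()
  sub <- volume_grid(c(30, 30, 4), c(1, 1, 2.5))
  tf <- tensor_field(ph$tensors$elements[1:30, 1:30, 9:12, , drop = FALSE], sub)
  zero <- tensor_field(array(0, dim(tf$elements)), sub)
  out0 <- regularize_tensor_field(tf, zero)
  expect_equal(out0$elements, tf$elements, tolerance = 1e-8)
  nf <- make_noise_tensor_field(sub, noise_model(seed = 3))
  noisy <- add_tensor_noise(tf, nf)
  reg <- regularize_tensor_field(noisy, nf)
  # permuting slices and regularizing equals regularizing then permuting
  perm <- c(3, 1, 4, 2)
  noisy_p <- tensor_field(noisy$elements[, , perm, , drop = FALSE], sub)
  nf_p <- tensor_field(nf$elements[, , perm, , drop = FALSE], sub)
  reg_p <- regularize_tensor_field(noisy_p, nf_p)
  expect_equal(reg_p$elements, reg$elements[, , perm, , drop = FALSE],
               tolerance = 1e-12)
})
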