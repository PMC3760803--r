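test_that("known mixtures of super-Gaussian sources are recovered up to permutation and sign", {
  set.seed(99)
  nx <- 50; ny <- 50; P <- nx * ny
  S_true <- rbind(matrix(rnorm(3 * P), 3)^3,      # super-Gaussian sources
                  matrix(rnorm(9 * P), 9))        # Gaussian maps
  A <- matrix(rnorm(144), 12)
  stack <- array(t(A %*% S_true), c(nx, ny, 12))
  dec <- decompose_slice(stack, seed = 4)
  expect_equal(nrow(dec$components), 12)
  cors <- abs(cor(t(dec$components), t(S_true[1:3, ])))
  expect_true(all(apply(cors, 2, max) > 0.95))
})

test_that("decomposition is deterministic and complete", {
  dwi <- add_dwi_noise(small_smooth_dwi(c(20, 20, 2)), sigma = 10, seed = 2)
  sl <- dwi$dwi[, , 1, ]
  dim(sl) <- c(20, 20, 12)
  d1 <- decompose_slice(sl, seed = 5)
  d2 <- decompose_slice(sl, seed = 5)
  expect_identical(d1$components, d2$components)
  expect_identical(d1$mixing, d2$mixing)
  # mixing reproduces the centred input within 1e-8 relative error
  rec <- d1$mixing %*% d1$components + d1$row_means
  X <- t(matrix(sl, 400, 12))
  expect_lt(max(abs(rec - X)) / max(abs(X)), 1e-8)
  # mixing is well conditioned
  expect_lt(kappa(d1$mixing), 1e8)
})

test_that("rank-deficient slices are rejected with a named deficiency", {
  dwi <- small_smooth_dwi(c(20, 20, 1))
  sl <- dwi$dwi[, , 1, ]
  dim(sl) <- c(20, 20, 12)
  sl[, , 2] <- sl[, , 1]
  expect_error(decompose_slice(sl, seed = 1), "rank-deficient")
  expect_error(decompose_slice(sl[, , 1:6, drop = FALSE], seed = 1),
               "more than six")
})

test_that("classification separates structured maps from spatially white maps", {
  set.seed(8)
  nx <- 30; ny <- 30
  smooth_map <- outer(sin(seq(0, pi, length.out = nx)),
                      cos(seq(0, 2 * pi, length.out = ny)))
  white_map <- matrix(rnorm(nx * ny), nx, ny)
  dec <- structure(list(
    components = rbind(as.vector(smooth_map) / sd(smooth_map),
                       as.vector(white_map) / sd(white_map)),
    mixing = diag(2), row_means = c(0, 0),
    labels = rep(NA_character_, 2), nx = nx, ny = ny),
    class = "ica_decomposition")
  dec <- classify_components(dec)
  expect_equal(dec$labels, c("signal", "noise"))
  # labels are a function of content, not order
  dec_perm <- dec
  dec_perm$components <- dec$components[2:1, ]
  dec_perm$labels <- rep(NA_character_, 2)
  expect_equal(classify_components(dec_perm)$labels, c("noise", "signal"))
})

test_that("reconstruction is complete and label-additive", {
  dwi <- add_dwi_noise(small_smooth_dwi(c(20, 20, 1)), sigma = 10, seed = 3)
  sl <- dwi$dwi[, , 1, ]
  dim(sl) <- c(20, 20, 12)
  dec <- classify_components(decompose_slice(sl, seed = 2))
  both <- ica_reconstruct(dec, c("signal", "noise"))
  expect_equal(both, sl, tolerance = 1e-10)
  none <- ica_reconstruct(dec, character(0))
  expect_true(all(none == 0))
  s <- ica_reconstruct(dec, "signal")
  n <- ica_reconstruct(dec, "noise")
  expect_lt(max(abs(s + n - sl)) / max(abs(sl)), 1e-8)
})

test_that("twelve-direction synthetic data yield six signal components", {
  grid <- volume_grid(c(60, 60, 2), c(1, 1, 2.5))
  dwi <- add_dwi_noise(synthesize_dwi(make_smooth_tensor_field(grid)),
                       sigma = 10, seed = 2, center_gain = 3)
  den <- denoise_series(dwi, seed = 27)
  expect_equal(den$n_signal, c(6L, 6L))
})

test_that("signal-labelled components span the true signal subspace", {
  # the recovered span tilts away from the truth in its weakest direction
  # roughly in proportion to the noise floor; this property is checked at a
  # noise level where the weakest source stays well resolved
  grid <- volume_grid(c(60, 60, 1), c(1, 1, 2.5))
  tf <- make_smooth_tensor_field(grid)
  clean <- synthesize_dwi(tf)
  dwi <- add_dwi_noise(clean, sigma = 4, seed = 12)
  sl <- dwi$dwi[, , 1, ]
  dim(sl) <- c(60, 60, 12)
  dec <- classify_components(decompose_slice(sl, seed = 13))
  sig_maps <- dec$components[dec$labels == "signal", , drop = FALSE]
  # true subspace: the centred noise-free direction images
  truth <- t(matrix(clean$dwi[, , 1, ], 3600, 12))
  truth <- truth - rowMeans(truth)
  sv <- svd(truth, nu = 0)
  basis_true <- t(sv$v[, sv$d > 1e-6 * sv$d[1], drop = FALSE])[1:6, ]
  orth <- function(M) qr.Q(qr(t(M)))
  Qa <- orth(sig_maps); Qb <- orth(basis_true)
  principal_cos <- svd(t(Qa) %*% Qb)$d
  angles_deg <- acos(pmin(1, principal_cos)) * 180 / pi
  expect_lt(max(angles_deg), 10)
})

test_that("series denoising is exactly complementary and preserves the fit", {
  grid <- volume_grid(c(40, 40, 2), c(1, 1, 2.5))
  clean <- synthesize_dwi(make_smooth_tensor_field(grid))
  dwi <- add_dwi_noise(clean, sigma = 10, seed = 4, center_gain = 3)
  den <- denoise_series(dwi, seed = 11)
  expect_equal(den$denoised$dwi + den$noise, dwi$dwi, tolerance = 1e-10)
  expect_identical(den$denoised$s0, dwi$s0)
  # fitting the denoised series changes the tensor only marginally
  fit_raw <- fit_tensor(dwi)$elements
  fit_den <- fit_tensor(den$denoised)$elements
  med_rel <- median(abs(fit_den - fit_raw) / (abs(fit_raw) + 1e-12))
  expect_lt(med_rel, 0.05)
})

test_that("noise-free input has a near-null noise subspace", {
  dwi <- small_smooth_dwi(c(30, 30, 1))
  den <- denoise_series(dwi, seed = 5)
  expect_lt(sqrt(mean(den$noise^2)) / sqrt(mean(dwi$dwi^2)), 0.02)
})

test_that("recovered noise tracks the injected spatial noise profile", {
  grid <- volume_grid(c(60, 60, 2), c(1, 1, 2.5))
  dwi <- add_dwi_noise(synthesize_dwi(make_smooth_tensor_field(grid)),
                       sigma = 10, seed = 2, center_gain = 3)
  den <- denoise_series(dwi, seed = 27)
  # local noise power at the moving-window scale the method consumes
  p_hat <- apply(den$noise^2, 1:3, mean)
  for (z in 1:2)
    p_hat[, , z] <- tvdti:::window_mean(p_hat[, , z], 5)$mean
  sigma_map <- attr(dwi, "sigma_map")
  expect_gt(cor(as.vector(sqrt(p_hat)), as.vector(sigma_map)), 0.8)
  # central-to-peripheral power ratio matches the injected profile
  gain <- tvdti:::noise_gain_map(grid, 3)
  ctr <- gain > 2.5; per <- gain < 1.3
  ratio_hat <- mean(p_hat[ctr]) / mean(p_hat[per])
  ratio_true <- mean(sigma_map[ctr]^2) / mean(sigma_map[per]^2)
  expect_equal(ratio_hat, ratio_true, tolerance = 0.25)
})

test_that("all-zero slices pass through unchanged", {
  dwi <- add_dwi_noise(small_smooth_dwi(c(20, 20, 3)), sigma = 10, seed = 9)
  dwi$dwi[, , 2, ] <- 0
  den <- denoise_series(dwi, seed = 3)
  expect_true(all(den$denoised$dwi[, , 2, ] == 0))
  expect_true(all(den$noise[, , 2, ] == 0))
  expect_true(is.na(den$n_signal[2]))
})
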