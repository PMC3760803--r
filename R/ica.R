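# Blind source separation of direction images. The N diffusion-weighted
# images of one slice are modelled as linear mixtures of N statistically
# independent spatial source maps; the unmixing matrix is estimated by a
# symmetric fixed-point negentropy iteration (tanh contrast) on whitened
# data. Components whose maps carry spatial structure are the tissue /
# directed-diffusion signal; spatially white components are noise.

# Symmetric fixed-point ICA on whitened data Z (N x P). Returns the N x N
# unmixing matrix W with orthonormal rows and a `converged` attribute. The
# fixed point can stall in a poor optimum for unlucky initializations, so
# callers restart from a different derived seed when not converged.
fixed_point_ica <- function(Z, seed, max_iter = 500, tol = 1e-9) {
  N <- nrow(Z); P <- ncol(Z)
  old <- .Random.seed_save()
  set.seed(seed)
  W <- matrix(stats::rnorm(N * N), N, N)
  .Random.seed_restore(old)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W_new <- (G %*% t(Z)) / P - gprime * W
    W_new <- sym_orth(W_new)
    delta <- 1 - abs(diag(W_new %*% t(W)))
    W <- W_new
    if (max(delta) < tol) { converged <- TRUE; break }
  }
  attr(W, "converged") <- converged
  W
}

#' Decompose one slice stack into independent components
#'
#' Treats the N direction images of one axial slice as mixtures of N
#' independent spatial sources. Rows are centred, whitened by the
#' eigendecomposition of the mixture covariance (small eigenvalues are
#' floored so near-noise-free data remain decomposable) and unmixed by a
#' seeded symmetric fixed-point iteration, so the decomposition is
#' deterministic given the seed. Component order is algorithmically
#' arbitrary; labelling is content-based (see [classify_components()]).
#'
#' @param slice_stack 3D array `[nx, ny, N]` with N >= 7 direction images.
#' @param seed integer seed for the unmixing initialization.
#' @return An object of class `ica_decomposition`: `components` (N x P,
#'   unit-variance spatial maps), `mixing` (N x N, maps components to
#'   centred direction images), `row_means` (length N), `labels`
#'   (filled by [classify_components()]), `nx`, `ny`.
#' @export
decompose_slice <- function(slice_stack, seed = 1) {
  d <- dim(slice_stack)
  if (length(d) != 3L) stop("slice_stack must be [nx, ny, N]")
  N <- d[3]
  if (N < 7L)
    stop("ICA noise separation needs more than six diffusion directions")
  P <- d[1] * d[2]
  X <- t(matrix(slice_stack, P, N))            # N x P
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / P
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] <= 0)
    stop("decomposition error: slice has no variance")
  small <- e$values < 1e-12 * e$values[1]
  if (any(small))
    stop(sprintf(
      "decomposition error: rank-deficient input (%d null mixture dimensions, e.g. duplicated direction images)",
      sum(small)))
  vals <- pmax(e$values, 1e-10 * e$values[1])  # floor near-null directions
  K <- diag(1 / sqrt(vals)) %*% t(e$vectors)   # whitening, N x N
  Z <- K %*% Xc
  # the fixed point can settle in a poor optimum for unlucky starts:
  # run a few deterministic restarts and keep the solution with the
  # largest negentropy proxy sum_i (E[log cosh s_i] - E[log cosh nu])^2
  E_logcosh_gauss <- 0.3745672
  W <- NULL; best <- -Inf
  for (r in 0:4) {
    Wr <- fixed_point_ica(Z, seed = (seed + 104729L * r) %% 2147483647L)
    Sr <- Wr %*% Z
    Sr <- Sr / pmax(sqrt(rowMeans(Sr^2)), 1e-300)
    J <- sum((rowMeans(log(cosh(Sr))) - E_logcosh_gauss)^2)
    if (J > best) { best <- J; W <- Wr }
  }
  U <- W %*% K                                 # unmixing in data space
  S <- U %*% Xc
  # variance-normalize components; carry scale in the mixing matrix
  sdS <- pmax(sqrt(rowMeans(S^2)), 1e-300)
  S <- S / sdS
  A <- e$vectors %*% diag(sqrt(vals)) %*% t(W) # K^-1 W' ; X_c = A S_raw
  A <- A * rep(sdS, each = N)
  structure(list(components = S, mixing = A, row_means = mu,
                 labels = rep(NA_character_, N), nx = d[1], ny = d[2]),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components on %d x %d pixels; labels: %s\n",
              nrow(x$components), x$nx, x$ny,
              if (all(is.na(x$labels))) "unset" else
                paste(sum(x$labels == "signal"), "signal /",
                      sum(x$labels == "noise"), "noise")))
  invisible(x)
}

# Mean lag-1 spatial autocorrelation (x and y shifts) of a component map.
lag1_autocorr <- function(map) {
  nx <- nrow(map); ny <- ncol(map)
  cx <- if (nx > 1) stats::cor(as.vector(map[-1, ]), as.vector(map[-nx, ])) else NA
  cy <- if (ny > 1) stats::cor(as.vector(map[, -1]), as.vector(map[, -ny])) else NA
  mean(c(cx, cy), na.rm = TRUE)
}

#' Label components as signal or noise
#'
#' Data-driven split: tissue / directed-diffusion components have spatially
#' structured maps, noise components are spatially white. Each component map
#' is scored by its mean lag-1 spatial autocorrelation (average of x- and
#' y-shifts); scores above `threshold` are labelled `"signal"`. The label is
#' a function of component content only, so it is invariant to the arbitrary
#' component ordering of the decomposition.
#'
#' @param dec an `ica_decomposition`.
#' @param threshold autocorrelation threshold (default 0.2).
#' @return the decomposition with `labels` filled, plus attribute
#'   `autocorr` (per-component scores).
#' @export
classify_components <- function(dec, threshold = 0.2) {
  ac <- vapply(seq_len(nrow(dec$components)), function(i) {
    m <- matrix(dec$components[i, ], dec$nx, dec$ny)
    a <- lag1_autocorr(m)
    if (is.na(a)) 0 else a
  }, numeric(1))
  dec$labels <- ifelse(ac > threshold, "signal", "noise")
  attr(dec, "autocorr") <- ac
  dec
}

#' Reconstruct a slice stack from labelled components
#'
#' Zeroes the components whose label is not in `keep` and applies the mixing
#' matrix. Row means (the DC level of each direction image, which is tissue
#' signal) are restored when `"signal"` is kept, so
#' `ica_reconstruct(dec, "signal") + ica_reconstruct(dec, "noise")` equals
#' the original stack.
#'
#' @param dec a labelled `ica_decomposition`.
#' @param keep character vector of labels to retain (subset of
#'   `c("signal", "noise")`).
#' @return 3D array `[nx, ny, N]`.
#' @export
ica_reconstruct <- function(dec, keep = "signal") {
  if (any(is.na(dec$labels))) stop("labels not assigned; run classify_components()")
  S <- dec$components
  S[!(dec$labels %in% keep), ] <- 0
  X <- dec$mixing %*% S
  if ("signal" %in% keep) X <- X + dec$row_means
  out <- t(X)
  dim(out) <- c(dec$nx, dec$ny, nrow(dec$components))
  out
}

#' ICA denoising of a DWI series
#'
#' Applies decompose -> classify -> reconstruct slice by slice: each axial
#' slice of the N direction images is split into independent components,
#' noise components are zeroed for the denoised series and signal components
#' are zeroed for the matched noise series. The two outputs sum to the input
#' voxel-for-voxel; the b=0 volume is passed through untouched. All-zero
#' slices (no object content) are passed through unchanged.
#'
#' @param dwi a [dwi_series()] with at least 7 directions.
#' @param seed integer; per-slice seeds are derived deterministically.
#' @param threshold autocorrelation threshold for the signal/noise split.
#' @return list with `denoised` (a [dwi_series()]), `noise` (4D array
#'   `[nx, ny, nz, N]`) and `n_signal` (per-slice signal-component counts).
#' @export
denoise_series <- function(dwi, seed = 1, threshold = 0.2) {
  nz <- dwi$grid$shape[3]
  Shat <- array(0, dim(dwi$dwi))
  eps <- array(0, dim(dwi$dwi))
  n_signal <- integer(nz)
  for (z in seq_len(nz)) {
    sl <- dwi$dwi[, , z, , drop = TRUE]
    dim(sl) <- c(dwi$grid$shape[1:2], dwi$scheme$n_directions)
    if (all(sl == 0)) { n_signal[z] <- NA_integer_; next }
    dec <- decompose_slice(sl, seed = (seed * 1009L + z) %% 2147483647L)
    dec <- classify_components(dec, threshold = threshold)
    n_signal[z] <- sum(dec$labels == "signal")
    Shat[, , z, ] <- ica_reconstruct(dec, "signal")
    eps[, , z, ] <- ica_reconstruct(dec, "noise")
  }
  list(denoised = dwi_series(dwi$s0, Shat, dwi$grid, dwi$scheme),
       noise = eps, n_signal = n_signal)
}
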