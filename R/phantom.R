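#' Fiber bundle specification
#'
#' An axis-aligned rectangular bundle of prescribed eigenvalues whose
#' principal eigenvector points along the bundle axis. Used to assemble
#' software phantoms with fibers in all three spatial directions.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param start_voxel integer 3-vector, 0-based corner voxel of the bundle.
#' @param length_voxels bundle extent along `axis` in voxels.
#' @param cross_section_voxels integer 2-vector, extent along the two
#'   remaining axes (in axis order).
#' @param eigenvalues numeric 3-vector (l1 >= l2 >= l3 > 0), mm^2/s.
#'   Default is white-matter-like (1.7e-3, 3e-4, 3e-4), giving FA ~ 0.79.
#' @return An object of class `fiber_bundle`.
#' @export
fiber_bundle <- function(axis, start_voxel, length_voxels,
                         cross_section_voxels,
                         eigenvalues = c(1.7e-3, 3e-4, 3e-4)) {
  axis <- match.arg(axis, c("x", "y", "z"))
  eigenvalues <- as.numeric(eigenvalues)
  if (!(eigenvalues[1] >= eigenvalues[2] &&
        eigenvalues[2] >= eigenvalues[3] && eigenvalues[3] > 0))
    stop("eigenvalues must satisfy l1 >= l2 >= l3 > 0")
  structure(list(axis = axis,
                 start_voxel = as.integer(start_voxel),
                 length_voxels = as.integer(length_voxels),
                 cross_section_voxels = as.integer(cross_section_voxels),
                 eigenvalues = eigenvalues),
            class = "fiber_bundle")
}

# 0-based index ranges occupied by a bundle, per axis.
bundle_extent <- function(b) {
  ax <- match(b$axis, c("x", "y", "z"))
  others <- setdiff(1:3, ax)
  lo <- integer(3); hi <- integer(3)
  lo[ax] <- b$start_voxel[ax]
  hi[ax] <- b$start_voxel[ax] + b$length_voxels - 1L
  lo[others] <- b$start_voxel[others]
  hi[others] <- b$start_voxel[others] + b$cross_section_voxels - 1L
  list(lo = lo, hi = hi)
}

# Tensor channel vector for a bundle: eigenvalues on the diagonal with l1 on
# the bundle axis (principal eigenvector along the axis), no off-diagonals.
bundle_tensor_vec <- function(b) {
  ax <- match(b$axis, c("x", "y", "z"))
  d <- numeric(3)
  d[ax] <- b$eigenvalues[1]
  d[setdiff(1:3, ax)] <- b$eigenvalues[2:3]
  c(d, 0, 0, 0)
}

#' Construct a software fiber phantom in tensor space
#'
#' Builds a tensor field on `grid` with an isotropic background and the
#' given non-overlapping fiber bundles, plus a ground-truth label map.
#' Bundles may not overlap: a single diffusion tensor cannot represent
#' crossing fibers.
#'
#' @param grid a [volume_grid()].
#' @param bundles list of [fiber_bundle()] objects.
#' @param background_iso isotropic background diffusivity in mm^2/s
#'   (default 0.7e-3).
#' @return a [tensor_field()] with attribute `labels`: an integer 3D array,
#'   0 for background, k for voxels of bundle k.
#' @export
make_tensor_phantom <- function(grid, bundles = list(),
                                background_iso = 0.7e-3) {
  el <- matrix(0, prod(grid$shape), 6)
  el[, 1:3] <- background_iso
  labels <- array(0L, grid$shape)
  occupied <- array(FALSE, grid$shape)
  for (k in seq_along(bundles)) {
    b <- bundles[[k]]
    ext <- bundle_extent(b)
    if (any(ext$lo < 0L) || any(ext$hi > grid$shape - 1L))
      stop(sprintf("bundle %d does not fit inside the grid", k))
    ix <- (ext$lo[1]:ext$hi[1]) + 1L
    iy <- (ext$lo[2]:ext$hi[2]) + 1L
    iz <- (ext$lo[3]:ext$hi[3]) + 1L
    if (any(occupied[ix, iy, iz]))
      stop(sprintf("bundle %d overlaps an earlier bundle", k))
    occupied[ix, iy, iz] <- TRUE
    labels[ix, iy, iz] <- k
    dvec <- bundle_tensor_vec(b)
    lin <- which(labels == k)
    for (c in 1:6) el[lin, c] <- dvec[c]
  }
  out <- matrix_as_tensor(el, grid)
  attr(out, "labels") <- labels
  out
}

#' Synthesize noise-free DWI from a tensor field
#'
#' Forward Stejskal-Tanner model: S_i = S0 exp(-b g_i' D g_i) per voxel and
#' direction. Input tensors must be PSD (negative eigenvalues would yield
#' unphysical signal amplification along some direction).
#'
#' @param tensors a [tensor_field()] (PSD).
#' @param s0_value scalar unweighted signal amplitude.
#' @param scheme a [gradient_scheme()].
#' @return a [dwi_series()] on the tensor grid.
#' @export
synthesize_dwi <- function(tensors, s0_value = 1000,
                           scheme = default_scheme()) {
  el <- tensor_as_matrix(tensors)
  ev <- tensor_eigvals(el)
  if (min(ev[, 3]) < -1e-12 * max(abs(ev)))
    stop("domain error: tensor field has negative eigenvalues")
  dm <- design_matrix(scheme)
  adc <- el %*% t(dm$B)                        # P x N of g' D g
  S <- s0_value * exp(-scheme$bvalue * adc)
  dim(S) <- c(tensors$grid$shape, scheme$n_directions)
  s0 <- array(s0_value, tensors$grid$shape)
  dwi_series(s0, S, tensors$grid, scheme)
}

#' Spatially varying tensor-space noise model
#'
#' Zero-mean Gaussian noise per tensor element whose standard deviation is
#' `base_sigma[element]` times a radial gain profile: `center_gain` at the
#' grid centre, decaying linearly in radius to 1 at the corner radius. This
#' emulates the higher noise level observed in central regions (coil
#' sensitivity, g-factor) with a parametric surrogate.
#'
#' @param base_sigma per-element standard deviations (6-vector or scalar,
#'   mm^2/s); default 1.5e-4.
#' @param center_gain multiplicative factor >= 1 at the grid centre
#'   (default 3).
#' @param seed integer seed making the field reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(base_sigma = 1.5e-4, center_gain = 3, seed = 1) {
  base_sigma <- rep(as.numeric(base_sigma), length.out = 6)
  if (any(base_sigma < 0)) stop("base_sigma must be non-negative")
  if (center_gain < 1) stop("center_gain must be >= 1")
  structure(list(base_sigma = base_sigma, center_gain = center_gain,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Radial gain map (3D array) for a grid, in mm from the grid centre.
noise_gain_map <- function(grid, center_gain) {
  d <- grid$voxel_size
  ctr <- (grid$shape - 1) / 2 * d
  x <- (seq_len(grid$shape[1]) - 1) * d[1] - ctr[1]
  y <- (seq_len(grid$shape[2]) - 1) * d[2] - ctr[2]
  z <- (seq_len(grid$shape[3]) - 1) * d[3] - ctr[3]
  r <- sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
  rmax <- sqrt(sum(ctr^2))
  if (rmax == 0) rmax <- 1
  1 + (center_gain - 1) * pmax(1 - r / rmax, 0)
}

#' Draw a tensor-space noise field
#'
#' @param grid a [volume_grid()].
#' @param model a [noise_model()].
#' @return a [tensor_field()] of zero-mean noise (mm^2/s) with attribute
#'   `sigma`: the `[nx, ny, nz, 6]` array of per-voxel, per-element standard
#'   deviations actually used.
#' @export
make_noise_tensor_field <- function(grid, model = noise_model()) {
  gain <- as.vector(noise_gain_map(grid, model$center_gain))
  P <- prod(grid$shape)
  el <- matrix(0, P, 6)
  sig <- matrix(0, P, 6)
  old <- .Random.seed_save()
  set.seed(model$seed)
  for (c in 1:6) {
    sig[, c] <- model$base_sigma[c] * gain
    el[, c] <- stats::rnorm(P, 0, 1) * sig[, c]
  }
  .Random.seed_restore(old)
  out <- matrix_as_tensor(el, grid)
  dim(sig) <- c(grid$shape, 6L)
  attr(out, "sigma") <- sig
  out
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Add a noise tensor field to a tensor field
#'
#' Plain elementwise sum; the result is deliberately not PSD-repaired here
#' (repair is an explicit downstream step, as in the processing chain).
#'
#' @param tensors,noise [tensor_field()] objects on the same grid.
#' @return a [tensor_field()].
#' @export
add_tensor_noise <- function(tensors, noise) {
  if (!identical(dim(tensors$elements), dim(noise$elements)))
    stop("shape mismatch between tensor field and noise field")
  tensor_field(tensors$elements + noise$elements, tensors$grid)
}

#' Add Gaussian noise to DWI signal magnitudes
#'
#' Signal-space companion of the tensor-space noise path, used to exercise
#' the ICA noise extraction: i.i.d. zero-mean Gaussian noise is added to
#' every diffusion-weighted volume (the b=0 reference is left noise-free,
#' matching the noise projection which extracts noise only from the weighted
#' volumes).
#'
#' @param dwi a [dwi_series()].
#' @param sigma noise standard deviation in signal units (at the periphery
#'   when `center_gain > 1`).
#' @param seed integer seed.
#' @param center_gain optional radial gain (>= 1) multiplying the noise std
#'   towards the grid centre, as in [noise_model()]; default 1 (homogeneous).
#' @return a [dwi_series()] with attributes `noise_true` (the injected noise
#'   array `[nx, ny, nz, N]`) and `sigma_map` (3D array of per-voxel std).
#' @export
add_dwi_noise <- function(dwi, sigma, seed = 1, center_gain = 1) {
  sigma_map <- sigma * noise_gain_map(dwi$grid, center_gain)
  old <- .Random.seed_save()
  set.seed(seed)
  eps <- array(stats::rnorm(length(dwi$dwi), 0, 1), dim(dwi$dwi)) *
    as.vector(sigma_map)
  .Random.seed_restore(old)
  out <- dwi_series(dwi$s0, dwi$dwi + eps, dwi$grid, dwi$scheme)
  attr(out, "noise_true") <- eps
  attr(out, "sigma_map") <- sigma_map
  out
}

#' Reference software phantom
#'
#' The package's default validation object: a 60 x 60 x 20 grid of
#' 1 x 1 x 2.5 mm voxels with three orthogonal, non-overlapping bundles
#' (white-matter-like eigenvalues) in an isotropic background, mirroring the
#' anisotropic-voxel acquisition geometry at desk scale.
#'
#' @return list with `tensors` (a [tensor_field()] with `labels` attribute),
#'   `grid`, `bundles` and `scheme` (the 12-direction reference scheme).
#' @export
reference_phantom <- function() {
  grid <- volume_grid(c(60, 60, 20), c(1, 1, 2.5))
  bundles <- list(
    fiber_bundle("x", c(5, 29, 9), 50, c(6, 4)),
    fiber_bundle("y", c(27, 5, 3), 50, c(6, 4)),
    fiber_bundle("z", c(42, 42, 2), 16, c(6, 6))
  )
  tensors <- make_tensor_phantom(grid, bundles)
  list(tensors = tensors, grid = grid, bundles = bundles,
       scheme = default_scheme())
}

#' Smooth tensor field with six independent spatial patterns
#'
#' Generates a PSD tensor field whose six element maps vary with six
#' distinct low-frequency spatial patterns. Unlike the piecewise-constant
#' bundle phantom (whose element maps span only a few spatial degrees of
#' freedom), this field exhibits the full six-dimensional signal subspace
#' that tissue does, which is what the ICA signal/noise split operates on.
#'
#' @param grid a [volume_grid()].
#' @param base_diag mean diagonal diffusivity (mm^2/s).
#' @param amp_diag,amp_offdiag pattern amplitudes for diagonal and
#'   off-diagonal elements (mm^2/s); defaults keep the field PSD by diagonal
#'   dominance.
#' @return a [tensor_field()].
#' @export
make_smooth_tensor_field <- function(grid, base_diag = 0.7e-3,
                                     amp_diag = 1e-4, amp_offdiag = 1e-4) {
  d <- grid$voxel_size
  x <- (seq_len(grid$shape[1]) - 1) * d[1]
  y <- (seq_len(grid$shape[2]) - 1) * d[2]
  z <- (seq_len(grid$shape[3]) - 1) * d[3]
  ext <- pmax((grid$shape - 1) * d, d)
  X <- array(rep(x, times = grid$shape[2] * grid$shape[3]), grid$shape)
  Y <- array(rep(rep(y, each = grid$shape[1]), times = grid$shape[3]),
             grid$shape)
  Z <- array(rep(z, each = grid$shape[1] * grid$shape[2]), grid$shape)
  u <- X / ext[1]; v <- Y / ext[2]
  # six distinct in-plane spatial frequencies: the per-slice element maps
  # stay linearly independent in every slice
  pats <- list(cos(2 * pi * u),
               cos(2 * pi * v),
               sin(2 * pi * (u + v)),
               cos(2 * pi * 2 * (u - v)),
               sin(2 * pi * (2 * u + v)),
               cos(2 * pi * (u + 2 * v)))
  el <- matrix(0, prod(grid$shape), 6)
  for (c in 1:3) el[, c] <- base_diag + amp_diag * as.vector(pats[[c]])
  for (c in 4:6) el[, c] <- amp_offdiag * as.vector(pats[[c]])
  matrix_as_tensor(el, grid)
}
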