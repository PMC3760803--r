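#' Voxel grid geometry
#'
#' Defines the sampling grid shared by all volumes in a data set: the number
#' of voxels along each axis and the physical voxel size in mm. Voxel indices
#' are 0-based and the world coordinate (in mm) of the centre of voxel
#' `(i, j, k)` is `(i*dx, j*dy, k*dz)`; no rotation or affine is carried
#' (the regularization and the tracker are grid-local).
#'
#' @param shape integer vector of length 3, voxels along x, y, z.
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#'   Anisotropic voxels are permitted (the reference configuration is
#'   1 x 1 x 2.5 mm).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 2.5)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L)
  if (any(shape <= 0L)) stop("grid dimensions must be positive")
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  structure(list(shape = shape, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Volume of one voxel in ml
#' @param grid a [volume_grid()].
#' @return voxel volume in millilitres (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

#' Diffusion gradient scheme
#'
#' A single-shell diffusion encoding scheme: one b-value (s/mm^2) and N unit
#' encoding directions. Directions are normalized on construction; at least
#' 6 directions are required for tensor estimation and the reference
#' configuration has 12.
#'
#' @param bvalue diffusion weighting in s/mm^2.
#' @param directions N x 3 numeric matrix of encoding directions; rows are
#'   normalized to unit length.
#' @return An object of class `gradient_scheme` with fields `bvalue`,
#'   `directions` (unit rows) and `n_directions`.
#' @export
gradient_scheme <- function(bvalue, directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an N x 3 matrix")
  if (nrow(directions) < 6L)
    stop("insufficient directions: tensor estimation needs at least 6")
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-12)) stop("zero-norm diffusion direction")
  directions <- directions / nrm
  structure(list(bvalue = as.numeric(bvalue)[1],
                 directions = directions,
                 n_directions = nrow(directions)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> b = %g s/mm^2, %d directions\n",
              x$bvalue, x$n_directions))
  invisible(x)
}

#' Reference 12-direction scheme
#'
#' Deterministic well-spread directions on the upper hemisphere (Fibonacci
#' spiral), matching the reference acquisition: b = 1000 s/mm^2, 12
#' non-collinear diffusion directions. The resulting design matrix has full
#' rank 6.
#'
#' @param n number of directions (default 12).
#' @param bvalue b-value in s/mm^2 (default 1000).
#' @return a [gradient_scheme()].
#' @export
default_scheme <- function(n = 12, bvalue = 1000) {
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- i / n                 # upper hemisphere only: antipodes are redundant
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * (seq_len(n) - 1)
  gradient_scheme(bvalue, cbind(r * cos(phi), r * sin(phi), z))
}

#' Diffusion-weighted series
#'
#' Container for one b=0 reference volume plus N diffusion-weighted volumes
#' on a common grid, with the encoding scheme that produced them.
#'
#' @param s0 3D array, signal without diffusion weighting (non-negative).
#' @param dwi 4D array `[nx, ny, nz, N]` of diffusion-weighted signal.
#' @param grid a [volume_grid()] matching the array dimensions.
#' @param scheme a [gradient_scheme()] with `n_directions == N`.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(s0, dwi, grid, scheme) {
  stopifnot(inherits(grid, "volume_grid"), inherits(scheme, "gradient_scheme"))
  s0 <- as.array(s0); dwi <- as.array(dwi)
  if (!identical(dim(s0), grid$shape)) stop("s0 shape does not match grid")
  if (length(dim(dwi)) != 4L || !identical(dim(dwi)[1:3], grid$shape))
    stop("dwi shape does not match grid")
  if (dim(dwi)[4] != scheme$n_directions)
    stop("dwi volume count does not match scheme$n_directions")
  structure(list(s0 = s0, dwi = dwi, grid = grid, scheme = scheme),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> %d x %d x %d voxels, %d directions, b = %g\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$scheme$n_directions, x$scheme$bvalue))
  invisible(x)
}

# Fixed project-wide channel order for symmetric tensor storage.
TENSOR_CHANNELS <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")

#' Symmetric tensor field
#'
#' Per-voxel symmetric 3x3 tensor stored as 6 channels in the fixed order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz. The same container holds diffusion tensors
#' (mm^2/s), noise tensors (mm^2/s) and variance tensors ((mm^2/s)^2).
#'
#' @param elements 4D array `[nx, ny, nz, 6]` of tensor elements.
#' @param grid a [volume_grid()].
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(elements, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  elements <- as.array(elements)
  if (length(dim(elements)) != 4L || dim(elements)[4] != 6L)
    stop("elements must be [nx, ny, nz, 6]")
  if (!identical(dim(elements)[1:3], grid$shape))
    stop("elements shape does not match grid")
  structure(list(elements = elements, grid = grid), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d x %d voxels, channels %s\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              paste(TENSOR_CHANNELS, collapse = ",")))
  invisible(x)
}

# Flatten a tensor field to a P x 6 matrix of voxel rows (and back).
tensor_as_matrix <- function(tf) {
  el <- tf$elements
  dim(el) <- c(prod(dim(el)[1:3]), 6L)
  el
}

matrix_as_tensor <- function(m, grid) {
  dim(m) <- c(grid$shape, 6L)
  tensor_field(m, grid)
}

# Rows of the 3x3 symmetric matrix for channel vector d (length 6).
tensor_vec_to_mat <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

tensor_mat_to_vec <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}
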