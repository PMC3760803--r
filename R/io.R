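#' Read a diffusion-weighted data set
#'
#' Reads a 4D NIfTI-1 volume together with FSL-dialect `.bval`/`.bvec`
#' gradient tables. Volumes with b < 50 s/mm^2 are treated as unweighted and
#' averaged into the b=0 reference; the remaining volumes form the
#' diffusion-weighted stack with their (normalized) encoding directions.
#' The grid is taken from the NIfTI header voxel dimensions.
#'
#' @param path_volume path to a 4D NIfTI-1 file.
#' @param path_bval path to a whitespace-separated b-value file (one row).
#' @param path_bvec path to a whitespace-separated direction file
#'   (3 rows x M columns).
#' @param b0_threshold b-values below this (s/mm^2) count as unweighted;
#'   default 50 tolerates vendor "b=0" volumes with small residual weighting.
#' @return a [dwi_series()].
#' @export
read_dwi <- function(path_volume, path_bval, path_bvec, b0_threshold = 50) {
  img <- RNifti::readNifti(path_volume)
  dat <- as.array(img)
  if (length(dim(dat)) != 4L) stop("volume must be 4D NIfTI-1")
  pix <- RNifti::pixdim(img)[1:3]
  grid <- volume_grid(dim(dat)[1:3], pix)

  tab <- read_bval_bvec(path_bval, path_bvec)
  if (ncol(tab$bvec) != dim(dat)[4])
    stop(sprintf("format error: %d volumes but %d gradient-table columns",
                 dim(dat)[4], ncol(tab$bvec)))

  is_b0 <- tab$bval < b0_threshold
  n_dwi <- sum(!is_b0)
  if (n_dwi < 6L)
    stop("insufficient directions: fewer than 6 nonzero-b volumes")
  if (!any(is_b0)) stop("no b=0 volume found")

  dirs <- t(tab$bvec[, !is_b0, drop = FALSE])
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm < 1e-12))
    stop("zero-norm direction paired with a nonzero b-value")
  scheme <- gradient_scheme(mean(tab$bval[!is_b0]), dirs)

  b0_idx <- which(is_b0)
  s0 <- dat[, , , b0_idx[1], drop = TRUE]
  dim(s0) <- grid$shape
  if (length(b0_idx) > 1L) {
    for (i in b0_idx[-1]) s0 <- s0 + dat[, , , i]
    s0 <- s0 / length(b0_idx)
  }
  dwi_series(s0, dat[, , , !is_b0, drop = FALSE], grid, scheme)
}

#' Read FSL bval/bvec gradient tables
#'
#' @param path_bval,path_bvec text files, whitespace separated; bvec has 3
#'   rows of M columns.
#' @return list with `bval` (length M) and `bvec` (3 x M matrix).
#' @export
read_bval_bvec <- function(path_bval, path_bvec) {
  bval <- scan(path_bval, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(path_bvec))
  dimnames(bvec) <- NULL
  if (nrow(bvec) != 3L) stop("bvec must have 3 rows")
  if (ncol(bvec) != length(bval))
    stop("format error: bval/bvec column counts differ")
  list(bval = bval, bvec = bvec)
}

#' Write FSL bval/bvec gradient tables
#'
#' Writes the scheme with one leading b=0 column (the convention
#' [read_dwi()] expects for a series that includes its reference volume).
#'
#' @param scheme a [gradient_scheme()].
#' @param path_bval,path_bvec output paths.
#' @param n_b0 number of leading b=0 columns (default 1).
#' @export
write_bval_bvec <- function(scheme, path_bval, path_bvec, n_b0 = 1) {
  bval <- c(rep(0, n_b0), rep(scheme$bvalue, scheme$n_directions))
  bvec <- cbind(matrix(0, 3, n_b0), t(scheme$directions))
  writeLines(paste(format(bval, trim = TRUE), collapse = " "), path_bval)
  writeLines(apply(bvec, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), path_bvec)
  invisible(NULL)
}

#' Write a volume as NIfTI-1
#'
#' Writes a 3D or 4D array with the grid's voxel sizes in the header, as
#' 64-bit floating point so that a write/read roundtrip preserves values
#' bit-exactly.
#'
#' @param data 3D or 4D numeric array whose first three dimensions match
#'   `grid$shape`.
#' @param grid a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(data, grid, path) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L)) || !identical(dim(data)[1:3], grid$shape))
    stop("data shape inconsistent with grid")
  dims <- c(nd, dim(data), rep(1L, 7 - nd))
  hdr <- RNifti::niftiHeader(list(
    dim = dims,
    pixdim = c(-1, grid$voxel_size, rep(1, 4))))
  img <- RNifti::asNifti(data, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(NULL)
}

#' Read a plain volume written by [write_volume()]
#'
#' @param path NIfTI-1 file.
#' @return list with `data` (array) and `grid` (a [volume_grid()]).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  list(data = dat, grid = volume_grid(dim(dat)[1:3], RNifti::pixdim(img)[1:3]))
}

#' Write a DWI series (volume + gradient tables)
#'
#' Stores the b=0 volume first, then the N weighted volumes, alongside
#' matching `.bval`/`.bvec` files.
#'
#' @param dwi a [dwi_series()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, prefix) {
  stack <- array(0, c(dwi$grid$shape, dwi$scheme$n_directions + 1L))
  stack[, , , 1] <- dwi$s0
  stack[, , , -1] <- dwi$dwi
  write_volume(stack, dwi$grid, paste0(prefix, ".nii.gz"))
  write_bval_bvec(dwi$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(NULL)
}
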