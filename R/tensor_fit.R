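#' Diffusion encoding design matrix
#'
#' For each unit encoding direction g the Stejskal-Tanner log-linearization
#' contributes the row (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz), so that
#' row %*% d equals g' D g for the 6-element tensor vector d. A well-spread
#' scheme yields rank 6; the Moore-Penrose pieces used by the fit are cached
#' on the returned object.
#'
#' @param scheme a [gradient_scheme()].
#' @return An object of class `design_matrix`: list with `B` (N x 6),
#'   `pinv` ((B'B)^-1 B', 6 x N) and `scheme`.
#' @export
design_matrix <- function(scheme) {
  g <- scheme$directions
  B <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  colnames(B) <- TENSOR_CHANNELS
  if (qr(B)$rank < 6L)
    stop("degenerate scheme: design matrix rank < 6")
  pinv <- solve(crossprod(B), t(B))
  structure(list(B = B, pinv = pinv, scheme = scheme),
            class = "design_matrix")
}

#' Linear least-squares diffusion tensor fit
#'
#' Per voxel, the signal model S_i = S0 exp(-b g_i' D g_i) is linearized to
#' y_i = ln(S0 / S_i) / b and the tensor vector solves the normal equations
#' d = (B'B)^-1 B' y. Signals are floored at `1e-6 * S0` before the log;
#' voxels with S0 <= 0 receive a zero tensor and are flagged in the QC mask.
#'
#' @param dwi a [dwi_series()] with at least 6 directions.
#' @return a [tensor_field()] (mm^2/s) with attributes `mask` (3D logical,
#'   TRUE where fitted) and `clipped` (3D logical, TRUE where any signal hit
#'   the floor).
#' @export
fit_tensor <- function(dwi) {
  dm <- design_matrix(dwi$scheme)
  b <- dwi$scheme$bvalue
  P <- prod(dwi$grid$shape)
  N <- dwi$scheme$n_directions
  S <- dwi$dwi; dim(S) <- c(P, N)
  s0 <- as.vector(dwi$s0)
  ok <- s0 > 0
  floorS <- 1e-6 * s0
  Sc <- pmax(S, floorS)           # recycles floorS down columns
  clipped <- rowSums(S < floorS) > 0 & ok
  y <- log(s0 / Sc) / b
  y[!ok, ] <- 0
  D <- y %*% t(dm$pinv)
  D[!ok, ] <- 0
  out <- matrix_as_tensor(D, dwi$grid)
  msk <- ok; dim(msk) <- dwi$grid$shape
  clp <- clipped; dim(clp) <- dwi$grid$shape
  attr(out, "mask") <- msk
  attr(out, "clipped") <- clp
  out
}

#' Project a DWI noise series into tensor space
#'
#' First-order perturbation of the log-linearized fit: for S = S_hat + eps,
#' ln(S0/S)/b = ln(S0/S_hat)/b - eps/(b S_hat) + O(eps^2), so the noise
#' contribution to each tensor element is the same pseudoinverse projection
#' applied to y_eps_i = -eps_i / (b * S_hat_i). The operator is linear in
#' eps and satisfies, to first order,
#' `fit_tensor(S_hat + eps) - fit_tensor(S_hat) == fit_noise_tensor(eps, S_hat)`.
#'
#' @param noise 4D array `[nx, ny, nz, N]`, the noise series paired with the
#'   denoised signal.
#' @param denoised a [dwi_series()] of denoised signal S_hat.
#' @return a [tensor_field()] of per-element noise (mm^2/s), with attribute
#'   `mask` FALSE where any S_hat_i fell below `1e-6 * S0` (those voxels are
#'   zeroed).
#' @export
fit_noise_tensor <- function(noise, denoised) {
  noise <- as.array(noise)
  if (!identical(dim(noise), dim(denoised$dwi)))
    stop("noise series shape does not match the denoised series")
  dm <- design_matrix(denoised$scheme)
  b <- denoised$scheme$bvalue
  P <- prod(denoised$grid$shape)
  N <- denoised$scheme$n_directions
  Sh <- denoised$dwi; dim(Sh) <- c(P, N)
  eps <- noise; dim(eps) <- c(P, N)
  s0 <- as.vector(denoised$s0)
  ok <- s0 > 0 & rowSums(Sh < 1e-6 * s0) == 0
  y <- -eps / (b * pmax(Sh, 1e-300))
  y[!ok, ] <- 0
  D <- y %*% t(dm$pinv)
  D[!ok, ] <- 0
  out <- matrix_as_tensor(D, denoised$grid)
  msk <- ok; dim(msk) <- denoised$grid$shape
  attr(out, "mask") <- msk
  out
}
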