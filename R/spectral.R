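# Vectorized spectral decomposition of symmetric 3x3 tensors stored as
# P x 6 rows (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz). The eigenvalue path uses the
# closed-form trigonometric solution; eigenvectors come from cross products
# of rows of (D - lambda1 I), with an eigen() fallback for (near-)degenerate
# voxels.

# Eigenvalues, descending, as a P x 3 matrix.
tensor_eigvals <- function(el) {
  el <- rbind(el)  # accept a single row
  q <- (el[, 1] + el[, 2] + el[, 3]) / 3
  p1 <- el[, 4]^2 + el[, 5]^2 + el[, 6]^2
  p2 <- (el[, 1] - q)^2 + (el[, 2] - q)^2 + (el[, 3] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1e-300) * 64 | p2 == 0
  ps <- ifelse(iso, 1, p)
  b11 <- (el[, 1] - q) / ps; b22 <- (el[, 2] - q) / ps; b33 <- (el[, 3] - q) / ps
  b12 <- el[, 4] / ps; b13 <- el[, 5] / ps; b23 <- el[, 6] / ps
  detb <- b11 * (b22 * b33 - b23^2) -
          b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detb / 2))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- q[iso]
  dimnames(out) <- NULL
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Unit principal eigenvectors as a P x 3 matrix (sign arbitrary).
tensor_principal_evec <- function(el, eigvals = NULL) {
  el <- rbind(el)
  if (is.null(eigvals)) eigvals <- tensor_eigvals(el)
  l1 <- eigvals[, 1]
  # rows of (D - l1 I)
  r1 <- cbind(el[, 1] - l1, el[, 4], el[, 5])
  r2 <- cbind(el[, 4], el[, 2] - l1, el[, 6])
  r3 <- cbind(el[, 5], el[, 6], el[, 3] - l1)
  c12 <- cross3(r1, r2); c13 <- cross3(r1, r3); c23 <- cross3(r2, r3)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- pmax(n12, n13, n23)
  v <- c12
  use13 <- n13 == best; v[use13, ] <- c13[use13, ]
  use23 <- n23 == best & !use13; v[use23, ] <- c23[use23, ]
  scale2 <- rowSums(el^2)
  degen <- best <= (scale2^3) * 1e-24  # near-repeated leading eigenvalue
  for (i in which(degen)) {
    ev <- eigen(tensor_vec_to_mat(el[i, ]), symmetric = TRUE)
    v[i, ] <- ev$vectors[, 1]
  }
  v / pmax(sqrt(rowSums(v^2)), 1e-300)
}

#' Clamp a tensor field to positive semidefiniteness
#'
#' A physical diffusion tensor has non-negative eigenvalues; estimation noise
#' can violate this. Each offending voxel is eigendecomposed, negative
#' eigenvalues are replaced by zero and the tensor is recomposed with its
#' eigenvectors unchanged. Voxels that are already PSD are returned
#' bit-identically, so the operation is idempotent.
#'
#' @param tensors a [tensor_field()].
#' @return a [tensor_field()] with minimum eigenvalue >= 0 everywhere.
#' @export
enforce_psd <- function(tensors) {
  el <- tensor_as_matrix(tensors)
  ev <- tensor_eigvals(el)
  bad <- which(ev[, 3] < 0)
  for (i in bad) {
    e <- eigen(tensor_vec_to_mat(el[i, ]), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    m <- e$vectors %*% (lam * t(e$vectors))
    el[i, ] <- tensor_mat_to_vec(m)
  }
  matrix_as_tensor(el, tensors$grid)
}

# FA from eigenvalue rows; 0 where the tensor vanishes.
fa_from_eigvals <- function(ev) {
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5) * sqrt(num / pmax(den, 1e-300))
  fa[den == 0] <- 0
  fa
}

#' Fractional anisotropy and mean diffusivity maps
#'
#' Closed-form scalar maps from the tensor eigenvalues: mean diffusivity is
#' the eigenvalue mean (mm^2/s); fractional anisotropy is the normalized
#' eigenvalue dispersion, 0 for an isotropic tensor and 1 in the
#' single-nonzero-eigenvalue limit.
#'
#' @param tensors a [tensor_field()] (expected PSD).
#' @return list with 3D arrays `fa` (dimensionless, in `[0, 1]`) and
#'   `md` (mm^2/s).
#' @export
fa_md_maps <- function(tensors) {
  ev <- tensor_eigvals(tensor_as_matrix(tensors))
  fa <- fa_from_eigvals(ev)
  md <- rowMeans(ev)
  dim(fa) <- tensors$grid$shape
  dim(md) <- tensors$grid$shape
  list(fa = fa, md = md)
}
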