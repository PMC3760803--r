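# Shared fixture builders. Everything is generated in code; no stored data.

# Small anisotropic-voxel grid for fast tests.
small_grid <- function(shape = c(12, 12, 3)) {
  volume_grid(shape, c(1, 1, 2.5))
}

# Noise-free DWI of the smooth six-pattern field on a small grid.
small_smooth_dwi <- function(shape = c(12, 12, 3)) {
  synthesize_dwi(make_smooth_tensor_field(small_grid(shape)))
}

# One noisy slice of the reference phantom plus everything needed to judge
# the regularization against ground truth.
phantom_slice_fixture <- function(seed = 11, z = 11) {
  ph <- reference_phantom()
  nf <- make_noise_tensor_field(ph$grid, noise_model(seed = seed))
  noisy <- add_tensor_noise(ph$tensors, nf)
  slice6 <- function(x) {
    s <- x[, , z, , drop = TRUE]
    dim(s) <- c(dim(x)[1:2], 6L)
    s
  }
  list(noisy = slice6(noisy$elements),
       truth = slice6(ph$tensors$elements),
       noise = slice6(nf$elements),
       variance = slice6(local_variance_tensor(nf, 5)$elements),
       labels = attr(ph$tensors, "labels")[, , z],
       grid = ph$grid, z = z)
}

# Brute-force scalar TV (forward differences, Neumann) for oracle checks.
tv_brute <- function(u) {
  nx <- nrow(u); ny <- ncol(u)
  gx <- rbind(u[-1, , drop = FALSE] - u[-nx, , drop = FALSE], rep(0, ny))
  gy <- cbind(u[, -1, drop = FALSE] - u[, -ny, drop = FALSE], rep(0, nx))
  sum(sqrt(gx^2 + gy^2))
}

# Distinct voxels traversed by a polyline: independent enumeration of all
# voxel-boundary crossings along each segment (no supersampling).
voxels_crossed_brute <- function(pts, grid) {
  d <- grid$voxel_size
  shp <- grid$shape
  vox_of <- function(p) round(p / d)
  out <- integer(0)
  add <- function(v) {
    if (all(v >= 0) && all(v < shp))
      out <<- c(out, v[1] + shp[1] * (v[2] + shp[2] * v[3]) + 1)
  }
  add(vox_of(pts[1, ]))
  if (nrow(pts) > 1) for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    # parameter values where the segment crosses a voxel face along any axis
    ts <- c(0, 1)
    for (ax in 1:3) {
      lo <- min(a[ax], b[ax]); hi <- max(a[ax], b[ax])
      edges <- d[ax] * (seq(floor(lo / d[ax]), ceiling(hi / d[ax])) + 0.5)
      edges <- edges[edges > lo & edges < hi]
      if (length(edges) && b[ax] != a[ax])
        ts <- c(ts, (edges - a[ax]) / (b[ax] - a[ax]))
    }
    ts <- sort(unique(ts))
    mid <- (ts[-1] + ts[-length(ts)]) / 2
    for (m in mid) add(vox_of(a + m * (b - a)))
  }
  unique(out)
}
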