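# Deterministic FACT-style streamline tractography: nearest-neighbour
# principal-eigenvector lookup, bidirectional integration from seeds at the
# centres of voxels above the FA threshold, termination on mask exit,
# turning angle or grid exit. No randomness anywhere.

#' Deterministic streamline tractography over a tensor field
#'
#' Seeds are placed at the centres of all voxels with FA >= `fa_threshold`.
#' From each seed two half-tracks are launched along +/- the principal
#' eigenvector and joined. At every step the direction is the principal
#' eigenvector of the tensor in the voxel containing the current position
#' (nearest-neighbour lookup), sign-aligned with the previous step; the
#' track terminates when it leaves the grid, enters a voxel below the FA
#' threshold, or would turn by more than `angle_threshold` degrees.
#' Tracks shorter than `min_length` mm are discarded (the conventional
#' short-track filter of tract viewers); total length is capped at 10x the
#' grid diagonal.
#'
#' @param tensors a [tensor_field()] (PSD).
#' @param fa_threshold seed/termination FA threshold in `[0, 1)`
#'   (default 0.15).
#' @param angle_threshold maximum turning angle between consecutive steps,
#'   degrees (default 45, the fixed tracking threshold).
#' @param step integration step in mm; default half the smallest voxel
#'   dimension.
#' @param min_length minimum retained track length in mm (default 10).
#' @return An object of class `streamline_set`: list with `streamlines`
#'   (list of n x 3 matrices of vertices in mm), `grid` and `parameters`.
#'   An empty set (no seeds) is returned, not an error.
#' @export
track_streamlines <- function(tensors, fa_threshold = 0.15,
                              angle_threshold = 45, step = NULL,
                              min_length = 10) {
  stopifnot(fa_threshold >= 0, fa_threshold < 1)
  grid <- tensors$grid
  d <- grid$voxel_size
  if (is.null(step)) step <- min(d) / 2
  el <- tensor_as_matrix(tensors)
  ev <- tensor_eigvals(el)
  if (min(ev[, 3]) < -1e-6 * max(abs(ev), 1e-300))
    stop("tensors must be PSD; run enforce_psd() first")
  fa <- fa_from_eigvals(ev)
  mask <- fa >= fa_threshold & ev[, 1] > 0
  dir_field <- matrix(0, nrow(el), 3)
  if (any(mask))
    dir_field[mask, ] <- tensor_principal_evec(el[mask, , drop = FALSE],
                                               ev[mask, , drop = FALSE])
  shp <- grid$shape
  cos_thr <- cos(angle_threshold * pi / 180)
  max_len <- 10 * sqrt(sum(((shp - 1) * d)^2))
  max_steps <- ceiling(max_len / step)

  seeds_lin <- which(mask)
  params <- list(step = step, angle_threshold = angle_threshold,
                 fa_threshold = fa_threshold, min_length = min_length)
  if (length(seeds_lin) == 0)
    return(structure(list(streamlines = list(), grid = grid,
                          parameters = params), class = "streamline_set"))
  # 0-based voxel indices of the seeds; centres at index * voxel size
  i0 <- (seeds_lin - 1L) %% shp[1]
  j0 <- ((seeds_lin - 1L) %/% shp[1]) %% shp[2]
  k0 <- (seeds_lin - 1L) %/% (shp[1] * shp[2])
  seed_pos <- cbind(i0 * d[1], j0 * d[2], k0 * d[3])

  # linear (1-based) voxel index of positions; NA outside grid
  pos_to_lin <- function(pos) {
    vi <- round(pos[, 1] / d[1]); vj <- round(pos[, 2] / d[2])
    vk <- round(pos[, 3] / d[3])
    out <- rep(NA_integer_, nrow(pos))
    ok <- vi >= 0 & vi < shp[1] & vj >= 0 & vj < shp[2] & vk >= 0 & vk < shp[3]
    out[ok] <- as.integer(vi[ok] + shp[1] * (vj[ok] + shp[2] * vk[ok]) + 1L)
    out
  }

  # March all tracks of one launch direction simultaneously.
  march <- function(dir0) {
    n <- nrow(seed_pos)
    pos <- seed_pos
    dir <- dir0
    active <- rowSums(dir^2) > 0
    verts <- vector("list", max_steps)
    nv <- 0L
    for (s in seq_len(max_steps)) {
      if (!any(active)) break
      ia <- which(active)
      newpos <- pos[ia, , drop = FALSE] + step * dir[ia, , drop = FALSE]
      lin <- pos_to_lin(newpos)
      ok <- !is.na(lin)
      ok[ok] <- mask[lin[ok]]
      # direction in the new voxel, sign-aligned with the previous step
      nd <- matrix(0, length(ia), 3)
      nd[ok, ] <- dir_field[lin[ok], , drop = FALSE]
      dots <- rowSums(nd * dir[ia, , drop = FALSE])
      flip <- dots < 0
      nd[flip, ] <- -nd[flip, ]
      dots <- abs(dots)
      ok <- ok & dots >= cos_thr
      keep <- ia[ok]
      pos[keep, ] <- newpos[ok, , drop = FALSE]
      dir[keep, ] <- nd[ok, , drop = FALSE]
      active[ia[!ok]] <- FALSE
      if (any(ok)) {
        nv <- nv + 1L
        verts[[nv]] <- cbind(keep, newpos[ok, , drop = FALSE])
      }
    }
    # vertices stacked as (seed id, x, y, z), sorted by id, marching order
    # preserved within id; counts per seed
    if (nv > 0L) {
      allv <- do.call(rbind, verts[seq_len(nv)])
      allv <- allv[order(allv[, 1]), , drop = FALSE]
      counts <- tabulate(allv[, 1], nbins = n)
    } else {
      allv <- matrix(0, 0, 4)
      counts <- integer(n)
    }
    list(allv = allv, counts = counts)
  }

  fwd <- march(dir_field[seeds_lin, , drop = FALSE])
  bwd <- march(-dir_field[seeds_lin, , drop = FALSE])

  lens <- (fwd$counts + bwd$counts) * step
  keep <- which(lens >= min_length)
  f_end <- cumsum(fwd$counts); f_start <- f_end - fwd$counts + 1L
  b_end <- cumsum(bwd$counts); b_start <- b_end - bwd$counts + 1L
  streamlines <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    b <- if (bwd$counts[i] > 0L)
      bwd$allv[b_end[i]:b_start[i], 2:4, drop = FALSE]  # reversed order
    streamlines[[j]] <- rbind(b, seed_pos[i, , drop = FALSE],
                              if (fwd$counts[i] > 0L)
                                fwd$allv[f_start[i]:f_end[i], 2:4,
                                         drop = FALSE])
  }
  structure(list(streamlines = streamlines, grid = grid,
                 parameters = params),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines on %d x %d x %d grid\n",
              length(x$streamlines), x$grid$shape[1], x$grid$shape[2],
              x$grid$shape[3]))
  invisible(x)
}

# Distinct 1-based linear voxel indices intersected by a set of polylines.
# Every segment is supersampled at `oversample` points per smallest voxel
# dimension; the subdivision loop runs over subdivision index, not segment,
# so the whole set is processed with vectorized arithmetic.
streamlines_voxels <- function(streamlines, grid, oversample = 10) {
  streamlines <- streamlines[vapply(streamlines, nrow, 1L) > 0]
  if (length(streamlines) == 0) return(integer(0))
  d <- grid$voxel_size
  shp <- grid$shape
  to_vox <- function(p) {
    vi <- round(p[, 1] / d[1]); vj <- round(p[, 2] / d[2])
    vk <- round(p[, 3] / d[3])
    ok <- vi >= 0 & vi < shp[1] & vj >= 0 & vj < shp[2] &
          vk >= 0 & vk < shp[3]
    vi[ok] + shp[1] * (vj[ok] + shp[2] * vk[ok]) + 1
  }
  all_pts <- do.call(rbind, streamlines)
  n_per <- vapply(streamlines, nrow, 1L)
  last_of_track <- cumsum(n_per)
  a <- all_pts[-last_of_track, , drop = FALSE]     # segment starts
  keep <- rep(TRUE, nrow(all_pts)); keep[c(1, last_of_track[-length(last_of_track)] + 1)] <- FALSE
  b <- all_pts[keep, , drop = FALSE]               # segment ends
  vox <- to_vox(all_pts)
  if (nrow(a) > 0) {
    fine <- min(d) / oversample
    seglen <- sqrt(rowSums((b - a)^2))
    nsub <- pmax(1L, ceiling(seglen / fine))
    for (k in seq_len(max(nsub) - 1L)) {
      sel <- nsub > k
      t <- k / nsub[sel]
      vox <- c(vox, to_vox(a[sel, , drop = FALSE] +
                             t * (b[sel, , drop = FALSE] -
                                  a[sel, , drop = FALSE])))
    }
  }
  unique(vox)
}

streamline_voxels <- function(pts, grid, oversample = 10) {
  streamlines_voxels(list(pts), grid, oversample)
}

#' Tract summary metrics
#'
#' The four evaluation metrics: mean streamline length ML (mm), track count
#' TC, volume V (ml) and voxel count VC (number of distinct voxels
#' intersected by at least one streamline). V = VC x voxel volume in ml, so
#' V/VC is constant. An empty set yields all zeros.
#'
#' @param s a `streamline_set`.
#' @return An object of class `tract_metrics`: list with `ML`, `TC`, `V`,
#'   `VC`.
#' @export
tract_metrics <- function(s) {
  if (length(s$streamlines) == 0)
    return(structure(list(ML = 0, TC = 0L, V = 0, VC = 0L),
                     class = "tract_metrics"))
  lens <- vapply(s$streamlines, function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  vox <- streamlines_voxels(s$streamlines, s$grid)
  structure(list(ML = mean(lens), TC = length(s$streamlines),
                 V = length(vox) * voxel_volume_ml(s$grid),
                 VC = length(vox)),
            class = "tract_metrics")
}

#' @export
print.tract_metrics <- function(x, ...) {
  cat(sprintf("ML = %.1f mm, TC = %d, V = %.3f ml, VC = %d\n",
              x$ML, x$TC, x$V, x$VC))
  invisible(x)
}
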