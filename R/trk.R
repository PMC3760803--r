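# TrackVis .trk streamline file I/O (format version 2, 1000-byte header,
# little endian). Coordinates in the file are "voxel-mm": mm offsets from
# the corner of the volume, where the centre of voxel (0,0,0) sits at half a
# voxel size; the package's internal convention puts that centre at 0, so a
# half-voxel shift is applied on write and removed on read.

trk_offset <- function(grid) grid$voxel_size / 2

#' Write a streamline set as a TrackVis .trk file
#'
#' @param s a `streamline_set`.
#' @param path output path.
#' @export
write_trk <- function(s, path) {
  grid <- s$grid
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(txt, width) {
    raw <- charToRaw(txt)
    writeBin(c(raw[seq_len(min(length(raw), width))],
               raw(width - min(length(raw), width))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(grid$shape), con, size = 2, endian = "little")
  writeBin(as.numeric(grid$voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")   # origin
  writeBin(0L, con, size = 2, endian = "little")           # n_scalars
  wchar("", 200)
  writeBin(0L, con, size = 2, endian = "little")           # n_properties
  wchar("", 200)
  vox2ras <- diag(c(grid$voxel_size, 1))                   # grid-local frame
  writeBin(as.numeric(t(vox2ras)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                  # reserved
  wchar("RAS", 4)                                          # voxel_order
  wchar("", 4)                                             # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                    # pad1
  writeBin(raw(6), con)                                    # invert/swap flags
  writeBin(length(s$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")           # version
  writeBin(1000L, con, size = 4, endian = "little")        # hdr_size
  off <- trk_offset(grid)
  for (pts in s$streamlines) {
    writeBin(nrow(pts), con, size = 4, endian = "little")
    shifted <- sweep(pts, 2, off, `+`)
    writeBin(as.numeric(t(shifted)), con, size = 4, endian = "little")
  }
  invisible(NULL)
}

#' Read a TrackVis .trk file
#'
#' @param path a .trk file written by [write_trk()] or a compatible tool.
#' @return a `streamline_set` (parameters empty).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6))
  if (!startsWith(magic, "TRACK")) stop("not a TrackVis .trk file")
  shape <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "raw", 1000 - 6 - 6 - 12 - 12))   # skip to n_count
  seek(con, 1000 - 12)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 2, size = 4, endian = "little"))
  grid <- volume_grid(shape, voxel_size)
  off <- trk_offset(grid)
  streamlines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    xyz <- readBin(con, "numeric", 3 * np, size = 4, endian = "little")
    streamlines[[i]] <- sweep(matrix(xyz, ncol = 3, byrow = TRUE), 2, off, `-`)
  }
  structure(list(streamlines = streamlines, grid = grid, parameters = list()),
            class = "streamline_set")
}
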