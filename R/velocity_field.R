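#' Construct a velocity field
#'
#' A regular grid of velocity vectors over time, the common currency of all
#' kinematic analyses. Vectors that failed validation are flagged in
#' `valid` (and set to `NA` in `vx`/`vy` when no replacement was made);
#' they are never silently zeroed.
#'
#' @param times numeric vector of length `T`, hours.
#' @param grid_x,grid_y window-center coordinates, micrometres, strictly
#'   increasing.
#' @param vx,vy numeric arrays `T x Ny x Nx`, micrometres per hour.
#' @param valid logical array `T x Ny x Nx`; defaults to finite vectors.
#' @param window_size interrogation window size, micrometres.
#' @param overlap_fraction fraction of window overlap, in `[0, 1)`.
#' @param pixel_size micrometres per pixel of the source images.
#' @param replaced optional logical array flagging vectors replaced by the
#'   median of valid neighbors during outlier handling.
#' @return a `velocity_field`.
#' @export
velocity_field <- function(times, grid_x, grid_y, vx, vy, valid = NULL,
                           window_size = NA_real_, overlap_fraction = 0,
                           pixel_size = NA_real_, replaced = NULL) {
  dims <- c(length(times), length(grid_y), length(grid_x))
  abort_if(!identical(dim(vx), as.integer(dims)) ||
             !identical(dim(vy), as.integer(dims)),
           sprintf("vx/vy must be %d x %d x %d arrays",
                   dims[1], dims[2], dims[3]))
  abort_if(length(grid_x) > 1 && any(diff(grid_x) <= 0),
           "grid_x must be strictly increasing")
  abort_if(length(grid_y) > 1 && any(diff(grid_y) <= 0),
           "grid_y must be strictly increasing")
  abort_if(overlap_fraction < 0 || overlap_fraction >= 1,
           "overlap_fraction must be in [0, 1)")
  if (is.null(valid)) valid <- is.finite(vx) & is.finite(vy)
  abort_if(!identical(dim(valid), as.integer(dims)),
           "valid mask shape mismatch")
  if (is.null(replaced)) replaced <- array(FALSE, dim = dims)
  structure(list(times = as.numeric(times), grid_x = as.numeric(grid_x),
                 grid_y = as.numeric(grid_y), vx = vx, vy = vy,
                 valid = valid, replaced = replaced,
                 window_size = window_size,
                 overlap_fraction = overlap_fraction,
                 pixel_size = pixel_size),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "<velocity_field> %d frames, %d x %d windows, %.1f%% valid\n",
    length(x$times), length(x$grid_y), length(x$grid_x),
    100 * mean(x$valid)))
  invisible(x)
}

#' Extract one frame of a velocity field as matrices
#' @param field a [velocity_field()].
#' @param t_index 1-based frame index.
#' @return list with `vx`, `vy`, `valid` matrices (`Ny x Nx`).
#' @export
field_frame <- function(field, t_index) {
  abort_if(t_index < 1 || t_index > length(field$times),
           "frame index out of range")
  list(vx = field$vx[t_index, , , drop = TRUE],
       vy = field$vy[t_index, , , drop = TRUE],
       valid = field$valid[t_index, , , drop = TRUE])
}

# ---- portable on-disk format -------------------------------------------
# A self-describing archive: one JSON header line (field shapes and scalar
# metadata) followed by little-endian doubles for each array, in header
# order. No community standard exists for PIV grids, so the format is kept
# deliberately minimal and versioned.

#' Write / read a velocity field archive
#'
#' Lossless round-trip of all fields, including the validity and
#' replacement masks.
#'
#' @param field a [velocity_field()].
#' @param path file path (conventionally `.pivz`).
#' @export
write_velocity_field <- function(field, path) {
  abort_if(length(field$times) == 0, "refusing to write an empty field")
  arrays <- c("times", "grid_x", "grid_y", "vx", "vy")
  header <- list(
    format = "flockmetrics-pivz", version = 1L,
    shapes = lapply(field[arrays], function(a) {
      if (is.null(dim(a))) length(a) else dim(a)
    }),
    window_size = field$window_size,
    overlap_fraction = field$overlap_fraction,
    pixel_size = field$pixel_size
  )
  con <- file(path, "wb")
  on.exit(close(con))
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(hjson, "\n")), con)
  for (nm in arrays) {
    writeBin(as.vector(as.numeric(field[[nm]])), con, size = 8,
             endian = "little")
  }
  writeBin(as.vector(as.numeric(field$valid)), con, size = 8,
           endian = "little")
  writeBin(as.vector(as.numeric(field$replaced)), con, size = 8,
           endian = "little")
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  # read header line byte-wise up to newline
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    abort_if(length(b) == 0, "corrupt velocity field archive (no header)")
    if (b == charToRaw("\n")) break
    bytes <- c(bytes, b)
  }
  header <- jsonlite::fromJSON(rawToChar(bytes))
  abort_if(!identical(header$format, "flockmetrics-pivz"),
           "not a velocity field archive")
  shp <- header$shapes
  read_arr <- function(shape) {
    n <- prod(shape)
    v <- readBin(con, "double", n = n, size = 8, endian = "little")
    abort_if(length(v) != n, "velocity field archive truncated")
    if (length(shape) > 1) array(v, dim = shape) else v
  }
  times <- read_arr(shp$times)
  grid_x <- read_arr(shp$grid_x)
  grid_y <- read_arr(shp$grid_y)
  vx <- read_arr(shp$vx)
  vy <- read_arr(shp$vy)
  valid_raw <- readBin(con, "double", n = prod(shp$vx), size = 8,
                       endian = "little")
  replaced_raw <- readBin(con, "double", n = prod(shp$vx), size = 8,
                          endian = "little")
  velocity_field(times, grid_x, grid_y, vx, vy,
                 valid = array(valid_raw != 0, dim = shp$vx),
                 window_size = header$window_size,
                 overlap_fraction = header$overlap_fraction,
                 pixel_size = header$pixel_size,
                 replaced = array(replaced_raw != 0, dim = shp$vx))
}

#' Coarse-grain track velocities onto a regular grid
#'
#' Builds a [velocity_field()] directly from a track table: per frame pair
#' `(f, f+1)`, each cell's centroid velocity is assigned to the grid window
#' containing its position at `f`, and windows average the velocities of
#' the cells they contain. Windows containing no cells are flagged
#' invalid. This provides the velocity-field representation for
#' tracking-only pipelines (e.g. nuclei tracks) without a PIV step.
#'
#' @param tracks a [track_table()].
#' @param box_size extent of the (square) field of view, micrometres.
#' @param window_size grid window size, micrometres (default 50, roughly 5
#'   cell diameters in a confluent epithelial monolayer).
#' @return a [velocity_field()].
#' @export
field_from_tracks <- function(tracks, box_size, window_size = 50) {
  frames <- sort(unique(tracks$frame))
  abort_if(length(frames) < 2, "need at least two frames")
  n_bins <- max(2L, floor(box_size / window_size))
  breaks <- seq(0, box_size, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  use_unwrap <- all(c("x_unwrap", "y_unwrap") %in% names(tracks))
  xs <- if (use_unwrap) tracks$x_unwrap else tracks$x
  ys <- if (use_unwrap) tracks$y_unwrap else tracks$y
  tt <- data.frame(id = tracks$track_id, frame = tracks$frame,
                   t = tracks$t, x = tracks$x, y = tracks$y,
                   xu = xs, yu = ys)
  t_of_frame <- tapply(tt$t, tt$frame, function(v) v[1])
  n_t <- length(frames) - 1L
  vx <- array(NA_real_, dim = c(n_t, n_bins, n_bins))
  vy <- array(NA_real_, dim = c(n_t, n_bins, n_bins))
  by_frame <- split(tt, tt$frame)
  for (k in seq_len(n_t)) {
    a <- by_frame[[as.character(frames[k])]]
    b <- by_frame[[as.character(frames[k + 1])]]
    idx <- match(a$id, b$id)
    ok_row <- !is.na(idx)
    if (!any(ok_row)) next
    a2 <- a[ok_row, ]
    b2 <- b[idx[ok_row], ]
    dt <- b2$t - a2$t
    ux <- (b2$xu - a2$xu) / dt
    uy <- (b2$yu - a2$yu) / dt
    ix <- bin_index(a2$x %% box_size, breaks)
    iy <- bin_index(a2$y %% box_size, breaks)
    ok <- !is.na(ix) & !is.na(iy)
    if (!any(ok)) next
    cell <- (ix[ok] - 1L) * n_bins + iy[ok]
    sx <- tapply(ux[ok], cell, mean)
    sy <- tapply(uy[ok], cell, mean)
    idx <- as.integer(names(sx))
    iy2 <- (idx - 1L) %% n_bins + 1L
    ix2 <- (idx - 1L) %/% n_bins + 1L
    vx[cbind(k, iy2, ix2)] <- as.numeric(sx)
    vy[cbind(k, iy2, ix2)] <- as.numeric(sy)
  }
  velocity_field(times = as.numeric(t_of_frame[as.character(frames[1:n_t])]),
                 grid_x = centers, grid_y = centers, vx = vx, vy = vy,
                 window_size = window_size, overlap_fraction = 0)
}
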