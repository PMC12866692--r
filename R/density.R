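# area of a disc of radius R centered at (cx, cy) clipped to the
# rectangle [0, W] x [0, H]; numeric integration over x of the clipped
# chord (accurate to ~1e-4 relative at n = 400 slices)
clipped_disc_area <- function(cx, cy, R, W, H, n_slices = 400) {
  x_lo <- max(cx - R, 0)
  x_hi <- min(cx + R, W)
  if (x_hi <= x_lo) return(0)
  xs <- seq(x_lo, x_hi, length.out = n_slices + 1)
  xm <- (xs[-1] + xs[-length(xs)]) / 2
  h <- sqrt(pmax(R^2 - (xm - cx)^2, 0))
  chord <- pmin(cy + h, H) - pmax(cy - h, 0)
  sum(pmax(chord, 0)) * (x_hi - x_lo) / n_slices
}

#' Local density field from cell positions
#'
#' The density at each grid point is the number of cells within a disc of
#' radius `R`, divided by the disc area. With `edge_correction = TRUE`
#' (the default; appropriate for bounded fields of view) the divisor is
#' the area of the disc clipped to the field; with `periodic = TRUE`
#' distances use the minimum image and no clipping is needed.
#'
#' @param tracks a [track_table()] (positions in um).
#' @param box field-of-view side, um.
#' @param grid_spacing grid step, um (default `R / 5`).
#' @param R kernel radius, um (default 50).
#' @param edge_correction divide by the clipped disc area.
#' @param periodic use minimum-image distances (synthetic data).
#' @return a `density_field`: list with `times` (h), `grid` (um),
#'   `values` (`T x Ny x Nx`, cells/um^2), `kernel_radius`.
#' @export
local_density <- function(tracks, box, grid_spacing = NULL, R = 50,
                          edge_correction = TRUE, periodic = FALSE) {
  abort_if(R <= 0, "R must be > 0")
  grid_spacing <- grid_spacing %||% (R / 5)
  centers <- seq(grid_spacing / 2, box - grid_spacing / 2,
                 by = grid_spacing)
  ng <- length(centers)
  frames <- sort(unique(tracks$frame))
  t_of_frame <- as.numeric(tapply(tracks$t, tracks$frame,
                                  function(v) v[1]))
  values <- array(0, dim = c(length(frames), ng, ng))
  gx <- rep(centers, each = ng)
  gy <- rep(centers, times = ng)
  areas <- if (edge_correction && !periodic) {
    vapply(seq_along(gx), function(k) {
      clipped_disc_area(gx[k], gy[k], R, box, box)
    }, numeric(1))
  } else {
    rep(pi * R^2, length(gx))
  }
  for (fidx in seq_along(frames)) {
    fr <- tracks[tracks$frame == frames[fidx], ]
    if (nrow(fr) == 0) next
    dx <- outer(gx, fr$x, "-")
    dy <- outer(gy, fr$y, "-")
    if (periodic) {
      dx <- dx - box * round(dx / box)
      dy <- dy - box * round(dy / box)
    }
    counts <- rowSums(dx^2 + dy^2 <= R^2)
    values[fidx, , ] <- matrix(counts / areas, ng, ng) # y rows, x cols
  }
  structure(list(times = t_of_frame, grid = centers, values = values,
                 kernel_radius = R, box = box),
            class = "density_field")
}

#' Density time series at a region of interest
#'
#' The density value at the grid point nearest `center`, per frame.
#'
#' @param field a `density_field` from [local_density()].
#' @param center `c(x, y)`, um.
#' @return a tibble with `t` and `density`.
#' @export
roi_density_series <- function(field, center) {
  abort_if(center[1] < 0 || center[1] > field$box ||
             center[2] < 0 || center[2] > field$box,
           "ROI center outside the field")
  ix <- which.min(abs(field$grid - center[1]))
  iy <- which.min(abs(field$grid - center[2]))
  tibble::tibble(t = field$times, density = field$values[, iy, ix])
}

#' Density kymograph
#'
#' Collapses the density field along one axis: the mean over the
#' orthogonal axis, per position bin and frame, giving a position x time
#' matrix in which a traveling density band appears as a sloped ridge.
#'
#' @param field a `density_field`.
#' @param axis `"x"` (columns of the output are x positions) or `"y"`.
#' @return matrix `position x time` (rows = positions along `axis`).
#' @export
density_kymograph <- function(field, axis = c("x", "y")) {
  axis <- match.arg(axis)
  n_t <- length(field$times)
  ng <- length(field$grid)
  out <- matrix(0, ng, n_t)
  for (k in seq_len(n_t)) {
    m <- field$values[k, , ]
    out[, k] <- if (axis == "x") colMeans(m) else rowMeans(m)
  }
  rownames(out) <- signif(field$grid, 6)
  out
}

#' Temporal density fluctuation map
#'
#' The standard deviation (over time, `ddof = 1`) of the local density at
#' every grid point; spatially uniform dynamics give a flat map, while
#' traveling density waves light up along their path.
#'
#' @param field a `density_field` with at least two frames.
#' @return matrix `Ny x Nx`, cells/um^2.
#' @export
density_fluctuation_map <- function(field) {
  n_t <- length(field$times)
  abort_if(n_t < 2, "need at least two frames")
  apply(field$values, c(2, 3), sd)
}
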