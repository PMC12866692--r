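# windows usable for statistics: validated vectors plus flagged
# median-replacements (which carry finite values)
usable_mask <- function(frame) {
  frame$valid & is.finite(frame$vx) & is.finite(frame$vy)
}

frame_vectors <- function(field, t_index) {
  fr <- field_frame(field, t_index)
  ok <- fr$valid & is.finite(fr$vx) & is.finite(fr$vy)
  rep_ok <- field$replaced[t_index, , ] & is.finite(fr$vx) &
    is.finite(fr$vy)
  use <- ok | rep_ok
  list(vx = fr$vx[use], vy = fr$vy[use], n = sum(use))
}

#' Center-of-mass velocity of a velocity-field frame
#'
#' The spatial average of the window velocities,
#' \eqn{V_{cm}(t) = \langle v_i(t) \rangle_i}.
#'
#' @param field a [velocity_field()].
#' @param t_index 1-based frame index.
#' @return a length-2 vector `(vx, vy)` in um/h, or `c(NA, NA)` when the
#'   frame has no usable windows (undefined values propagate as `NA`,
#'   never as zeros).
#' @export
center_of_mass_velocity <- function(field, t_index) {
  v <- frame_vectors(field, t_index)
  if (v$n == 0) return(c(NA_real_, NA_real_))
  c(mean(v$vx), mean(v$vy))
}

#' Root-mean-square velocity of a velocity-field frame
#'
#' \eqn{V_{RMS}(t) = \sqrt{\langle |v_i|^2 \rangle_i}}. With
#' `drift_corrected = TRUE` the center-of-mass velocity is subtracted
#' from every window first; the default is off, matching the convention
#' of headline motility curves.
#'
#' @inheritParams center_of_mass_velocity
#' @param drift_corrected subtract `V_cm(t)` before averaging.
#' @return scalar um/h, `NA` if no usable windows.
#' @export
root_mean_square_velocity <- function(field, t_index,
                                      drift_corrected = FALSE) {
  v <- frame_vectors(field, t_index)
  if (v$n == 0) return(NA_real_)
  vx <- v$vx
  vy <- v$vy
  if (drift_corrected) {
    vx <- vx - mean(vx)
    vy <- vy - mean(vy)
  }
  sqrt(mean(vx^2 + vy^2))
}

#' Velocity order parameter
#'
#' Quantifies velocity alignment across the field. The default variant is
#' \eqn{\psi = |\langle v_i \rangle_i| / \sqrt{\langle |v_i|^2 \rangle_i}},
#' which equals 1 only when all windows move with the same speed and
#' direction (Cauchy-Schwarz); `variant = "magnitude_ratio"` computes
#' \eqn{|\langle v \rangle| / \langle |v| \rangle}, which reaches 1 for
#' any common direction regardless of speed dispersion. Both lie in
#' `[0, 1]`.
#'
#' @inheritParams center_of_mass_velocity
#' @param variant `"eq_norm"` (default, RMS normalization) or
#'   `"magnitude_ratio"` (mean-speed normalization).
#' @return scalar in `[0, 1]`; `NA` when undefined (no usable windows or
#'   all speeds zero).
#' @export
order_parameter <- function(field, t_index,
                            variant = c("eq_norm", "magnitude_ratio")) {
  variant <- match.arg(variant)
  v <- frame_vectors(field, t_index)
  if (v$n == 0) return(NA_real_)
  denom <- switch(variant,
                  eq_norm = sqrt(mean(v$vx^2 + v$vy^2)),
                  magnitude_ratio = mean(sqrt(v$vx^2 + v$vy^2)))
  if (denom <= 0) return(NA_real_)
  num <- sqrt(mean(v$vx)^2 + mean(v$vy)^2)
  num / denom
}

#' Track-based RMS velocity of cell centers of mass
#'
#' Per-cell velocity is the frame-to-frame displacement of the cell
#' centroid divided by the frame interval; the return value is the RMS
#' over all cells present in both frames. This is the tracking-based
#' counterpart of [root_mean_square_velocity()], capturing local velocity
#' fluctuations at single-cell resolution.
#'
#' @param tracks a [track_table()].
#' @param frame reference frame number (velocity measured to the next
#'   available frame of each track).
#' @return scalar um/h, `NA` if no track spans the frame pair.
#' @export
track_rms_cm_velocity <- function(tracks, frame) {
  use_unwrap <- all(c("x_unwrap", "y_unwrap") %in% names(tracks))
  xs <- if (use_unwrap) tracks$x_unwrap else tracks$x
  ys <- if (use_unwrap) tracks$y_unwrap else tracks$y
  a <- tracks$frame == frame
  frames <- sort(unique(tracks$frame))
  nxt <- frames[frames > frame]
  if (length(nxt) == 0) return(NA_real_)
  b <- tracks$frame == nxt[1]
  ids <- intersect(tracks$track_id[a], tracks$track_id[b])
  if (length(ids) == 0) return(NA_real_)
  ia <- match(ids, tracks$track_id[a])
  ib <- match(ids, tracks$track_id[b])
  dt <- tracks$t[b][ib] - tracks$t[a][ia]
  vx <- (xs[b][ib] - xs[a][ia]) / dt
  vy <- (ys[b][ib] - ys[a][ia]) / dt
  sqrt(mean(vx^2 + vy^2))
}

#' Per-frame motility time series
#'
#' Computes `V_cm`, `V_rms` (plain and drift-corrected), the order
#' parameter (both variants) and the number of usable windows for every
#' frame of a velocity field; optionally the track-based `V_rms_cm`.
#'
#' @param field a [velocity_field()].
#' @param tracks optional [track_table()] for `V_rms_cm`.
#' @return a tibble with one row per field frame.
#' @export
motility_time_series <- function(field, tracks = NULL) {
  n_t <- length(field$times)
  out <- tibble::tibble(
    t = field$times,
    v_cm_x = NA_real_, v_cm_y = NA_real_,
    v_rms = NA_real_, v_rms_drift_corrected = NA_real_,
    psi = NA_real_, psi_magnitude_ratio = NA_real_,
    n_valid_windows = 0L)
  for (k in seq_len(n_t)) {
    cm <- center_of_mass_velocity(field, k)
    out$v_cm_x[k] <- cm[1]
    out$v_cm_y[k] <- cm[2]
    out$v_rms[k] <- root_mean_square_velocity(field, k)
    out$v_rms_drift_corrected[k] <-
      root_mean_square_velocity(field, k, drift_corrected = TRUE)
    out$psi[k] <- order_parameter(field, k)
    out$psi_magnitude_ratio[k] <-
      order_parameter(field, k, variant = "magnitude_ratio")
    out$n_valid_windows[k] <- frame_vectors(field, k)$n
  }
  if (!is.null(tracks)) {
    frames <- sort(unique(tracks$frame))
    t_of_frame <- tapply(tracks$t, tracks$frame, function(v) v[1])
    v_rms_cm <- vapply(frames[-length(frames)], function(f) {
      track_rms_cm_velocity(tracks, f)
    }, numeric(1))
    idx <- match(round(out$t, 9),
                 round(as.numeric(t_of_frame[-length(frames)]), 9))
    out$v_rms_cm <- v_rms_cm[idx]
  }
  out
}

#' Mean of a time series over a framecut window
#'
#' Averages series values over frames with `t0 <= t < t1`, skipping
#' undefined (`NA`) entries. Framecut windows restrict summary statistics
#' to the steady-state portion of a time-lapse (conventionally 15-40 h).
#'
#' @param t times, h.
#' @param x values.
#' @param t0,t1 window bounds, h.
#' @return scalar mean.
#' @export
framecut_mean <- function(t, x, t0, t1) {
  abort_if(t0 >= t1, "framecut requires t0 < t1")
  sel <- t >= t0 & t < t1
  abort_if(!any(sel), "framecut window does not overlap the series")
  vals <- x[sel]
  vals <- vals[is.finite(vals)]
  abort_if(length(vals) == 0, "framecut window contains no defined values")
  mean(vals)
}

#' Locate the motility peak and its analysis window
#'
#' Finds the time of maximum motility on a moving-average-smoothed series
#' and returns a window of length `window_length` centered on it, clipped
#' to the series support. Ties break to the earliest time. The spatial
#' velocity correlation is conventionally evaluated inside this window.
#'
#' @param t times, h.
#' @param x series (e.g. `V_rms`), may contain `NA`.
#' @param smoothing_window moving-average length, frames.
#' @param window_length returned window length, h (default 10).
#' @return list with `t_peak` and `window = c(lo, hi)`.
#' @export
find_motility_peak <- function(t, x, smoothing_window = 5,
                               window_length = 10) {
  abort_if(length(x) < smoothing_window,
           "series shorter than the smoothing window")
  abort_if(all(!is.finite(x)), "series has no defined values")
  sm <- moving_average(x, smoothing_window)
  i_peak <- which(sm == max(sm, na.rm = TRUE))[1]
  t_peak <- t[i_peak]
  lo <- max(min(t), t_peak - window_length / 2)
  hi <- min(max(t), t_peak + window_length / 2)
  list(t_peak = t_peak, window = c(lo, hi))
}
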