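#' PIV parameters
#'
#' Defaults follow common practice for epithelial monolayers: 50 um
#' interrogation windows (about five cells each) with 50% overlap.
#' Outlier validation uses the normalized-median test
#' (epsilon = 0.1, threshold 2.0), the PIV community default; vectors that
#' fail it (or the signal-to-noise floor) are masked invalid and replaced
#' by the median of their valid neighbors, with the replacement flagged.
#'
#' @param window_size interrogation window, micrometres.
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param subpixel `"gaussian3"` (3-point Gaussian peak fit),
#'   `"parabolic"`, or `"none"`.
#' @param outlier_threshold normalized-median residual threshold.
#' @param outlier_epsilon normalized-median regularization, px.
#' @param min_snr minimum primary/secondary correlation peak ratio.
#' @param snr_exclusion_px half-width of the square exclusion zone around
#'   the primary peak when searching for the secondary peak (about the
#'   correlation-peak radius; larger for smooth, blob-like textures).
#' @param max_displacement_fraction largest displacement searched, as a
#'   fraction of the window (keeps the circular correlation unambiguous).
#' @return a `piv_params` list.
#' @export
piv_params <- function(window_size = 50, overlap_fraction = 0.5,
                       subpixel = c("gaussian3", "parabolic", "none"),
                       outlier_threshold = 2, outlier_epsilon = 0.1,
                       min_snr = 1.3, snr_exclusion_px = 3,
                       max_displacement_fraction = 1 / 3) {
  abort_if(overlap_fraction < 0 || overlap_fraction >= 1,
           "overlap_fraction must be in [0, 1)")
  structure(list(window_size = window_size,
                 overlap_fraction = overlap_fraction,
                 subpixel = match.arg(subpixel),
                 outlier_threshold = outlier_threshold,
                 outlier_epsilon = outlier_epsilon,
                 min_snr = min_snr, snr_exclusion_px = snr_exclusion_px,
                 max_displacement_fraction = max_displacement_fraction),
            class = "piv_params")
}

#' Interrogation-window geometry
#'
#' Window start positions advance by `window * (1 - overlap)` pixels;
#' windows that would not fully fit inside the frame are dropped (padding
#' would produce spurious low velocities at borders). Centers are in
#' continuous pixel coordinates (pixel `i` spans `[i - 1, i]`).
#'
#' @param frame_dim `c(height, width)` of the frames, px.
#' @param window_px window side, px.
#' @param overlap_fraction overlap in `[0, 1)`.
#' @return list with `starts_x`, `starts_y` (1-based), `centers_x`,
#'   `centers_y` (continuous px).
#' @export
piv_window_geometry <- function(frame_dim, window_px, overlap_fraction) {
  abort_if(window_px > min(frame_dim),
           "interrogation window does not fit in the frame")
  step <- max(1L, as.integer(round(window_px * (1 - overlap_fraction))))
  starts <- function(n) {
    s <- seq(1L, n, by = step)
    s[s + window_px - 1L <= n]
  }
  sy <- starts(frame_dim[1])
  sx <- starts(frame_dim[2])
  list(starts_x = sx, starts_y = sy,
       centers_x = (sx - 1) + window_px / 2,
       centers_y = (sy - 1) + window_px / 2)
}

# zero-normalized linear cross-correlation of two equal-size windows via
# zero-padded FFT, each lag normalized by its overlap area (circular
# correlation without padding under-weights nonzero lags when the window
# content is not periodic, biasing displacements toward zero). Returns a
# 2n x 2n map in wrap layout (lag 0 at [1, 1]) plus the lag values.
cross_correlation_map <- function(w1, w2) {
  n <- nrow(w1)
  a <- w1 - mean(w1)
  b <- w2 - mean(w2)
  denom <- sqrt(mean(a^2) * mean(b^2))
  if (denom <= 0) return(NULL)
  P <- 2L * n
  A <- matrix(0, P, P)
  B <- matrix(0, P, P)
  A[1:n, 1:n] <- a
  B[1:n, 1:n] <- b
  cc_raw <- Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / P^2
  lag <- c(0:(P / 2), -(P / 2 - 1):-1)
  n_overlap <- outer(pmax(n - abs(lag), 0), pmax(n - abs(lag), 0))
  cc <- cc_raw / (n_overlap * denom)
  cc[n_overlap == 0] <- -Inf
  list(cc = cc, lag = lag)
}

# log-Gaussian or parabolic 3-point subpixel refinement along one axis
subpixel_offset <- function(cm, c0, cp, method) {
  if (method == "none") return(0)
  if (method == "gaussian3" && cm > 0 && c0 > 0 && cp > 0) {
    lm <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- lm - 2 * l0 + lp
    if (den < 0) return(0.5 * (lm - lp) / den)
  }
  den <- cm - 2 * c0 + cp
  if (den < 0) 0.5 * (cm - cp) / den else 0
}

#' Compute a PIV velocity field from an image stack
#'
#' Single-pass zero-normalized cross-correlation between consecutive
#' frames in each interrogation window, with optional 3-point Gaussian
#' subpixel peak refinement. Displacements are converted to um/h via the
#' stack calibration. Vectors failing the normalized-median outlier test
#' or the signal-to-noise floor are masked invalid and replaced by the
#' median of their valid neighbors (replacement flagged in `$replaced`).
#'
#' @param stack an [image_stack()] with at least two frames.
#' @param params a [piv_params()].
#' @return a [velocity_field()] with `T - 1` frames; frame `k` holds the
#'   velocity between stack frames `k` and `k + 1`.
#' @export
compute_piv <- function(stack, params = piv_params()) {
  d <- dim(stack$frames)
  abort_if(d[1] < 2, "PIV needs at least two frames")
  window_px <- as.integer(round(params$window_size / stack$pixel_size))
  abort_if(window_px < 8, "interrogation window must be >= 8 px")
  geom <- piv_window_geometry(d[2:3], window_px,
                              params$overlap_fraction)
  ny <- length(geom$starts_y)
  nx <- length(geom$starts_x)
  n_t <- d[1] - 1L
  u <- array(NA_real_, dim = c(n_t, ny, nx)) # px displacement
  v <- array(NA_real_, dim = c(n_t, ny, nx))
  valid <- array(FALSE, dim = c(n_t, ny, nx))
  max_disp <- max(1, floor(window_px * params$max_displacement_fraction))
  for (t in seq_len(n_t)) {
    f1 <- stack$frames[t, , ]
    f2 <- stack$frames[t + 1, , ]
    for (iy in seq_len(ny)) {
      for (ix in seq_len(nx)) {
        ry <- geom$starts_y[iy]:(geom$starts_y[iy] + window_px - 1L)
        rx <- geom$starts_x[ix]:(geom$starts_x[ix] + window_px - 1L)
        res <- cross_correlation_map(f1[ry, rx], f2[ry, rx])
        if (is.null(res)) next # constant window: invalid, not NaN
        cc <- res$cc
        sv_full <- res$lag
        pp <- length(sv_full)
        allowed <- abs(sv_full) <= max_disp
        cc_allowed <- cc[allowed, allowed]
        sv <- sv_full[allowed]
        pk <- which(cc_allowed == max(cc_allowed), arr.ind = TRUE)[1, ]
        dy <- sv[pk[1]]
        dx <- sv[pk[2]]
        # SNR: primary over the secondary peak outside an exclusion
        # zone the size of the correlation peak
        ez <- params$snr_exclusion_px
        cc_sec <- cc_allowed
        cc_sec[abs(sv - dy) <= ez, abs(sv - dx) <= ez] <- -Inf
        second <- max(cc_sec)
        snr <- if (is.finite(second) && second > 0) {
          max(cc_allowed) / second
        } else {
          Inf
        }
        if (snr < params$min_snr) next
        # subpixel refinement on the full map
        iy0 <- which(sv_full == dy)
        ix0 <- which(sv_full == dx)
        wrap <- function(i) ((i - 1) %% pp) + 1
        ddy <- subpixel_offset(cc[wrap(iy0 - 1), ix0], cc[iy0, ix0],
                               cc[wrap(iy0 + 1), ix0], params$subpixel)
        ddx <- subpixel_offset(cc[iy0, wrap(ix0 - 1)], cc[iy0, ix0],
                               cc[iy0, wrap(ix0 + 1)], params$subpixel)
        u[t, iy, ix] <- dx + ddx
        v[t, iy, ix] <- dy + ddy
        valid[t, iy, ix] <- TRUE
      }
    }
    # normalized-median outlier test on the frame's vector grid
    res <- normalized_median_test(u[t, , ], v[t, , ], valid[t, , ],
                                  params$outlier_threshold,
                                  params$outlier_epsilon)
    valid[t, , ] <- valid[t, , ] & !res$outlier
    u[t, , ][res$outlier] <- NA_real_
    v[t, , ][res$outlier] <- NA_real_
  }
  # replace invalid vectors by the median of valid neighbors, flagged
  replaced <- array(FALSE, dim = dim(valid))
  for (t in seq_len(n_t)) {
    fill <- fill_invalid_median(u[t, , ], v[t, , ], valid[t, , ])
    u[t, , ] <- fill$u
    v[t, , ] <- fill$v
    replaced[t, , ] <- fill$replaced
  }
  scale <- stack$pixel_size / stack$frame_interval
  velocity_field(
    times = (seq_len(n_t) - 1) * stack$frame_interval,
    grid_x = geom$centers_x * stack$pixel_size,
    grid_y = geom$centers_y * stack$pixel_size,
    vx = u * scale, vy = v * scale, valid = valid,
    window_size = window_px * stack$pixel_size,
    overlap_fraction = params$overlap_fraction,
    pixel_size = stack$pixel_size, replaced = replaced)
}

# Westerweel-Scarano universal outlier detection on one frame
normalized_median_test <- function(u, v, valid, threshold, eps) {
  ny <- nrow(u)
  nx <- ncol(u)
  outlier <- matrix(FALSE, ny, nx)
  if (ny * nx < 3) return(list(outlier = outlier))
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (!valid[iy, ix]) next
      ys <- max(1, iy - 1):min(ny, iy + 1)
      xs <- max(1, ix - 1):min(nx, ix + 1)
      sel <- valid[ys, xs]
      sel[which(ys == iy), which(xs == ix)] <- FALSE
      if (sum(sel) < 2) next
      ru <- nm_residual(u[iy, ix], u[ys, xs][sel], eps)
      rv <- nm_residual(v[iy, ix], v[ys, xs][sel], eps)
      if (sqrt(ru^2 + rv^2) > threshold) outlier[iy, ix] <- TRUE
    }
  }
  list(outlier = outlier)
}

nm_residual <- function(val, nbrs, eps) {
  m <- median(nbrs)
  rm_ <- median(abs(nbrs - m))
  abs(val - m) / (rm_ + eps)
}

fill_invalid_median <- function(u, v, valid) {
  ny <- nrow(u)
  nx <- ncol(u)
  replaced <- matrix(FALSE, ny, nx)
  u_out <- u
  v_out <- v
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (valid[iy, ix]) next
      ys <- max(1, iy - 1):min(ny, iy + 1)
      xs <- max(1, ix - 1):min(nx, ix + 1)
      sel <- valid[ys, xs]
      if (sum(sel) >= 2) {
        u_out[iy, ix] <- median(u[ys, xs][sel])
        v_out[iy, ix] <- median(v[ys, xs][sel])
        replaced[iy, ix] <- TRUE
      }
    }
  }
  list(u = u_out, v = v_out, replaced = replaced)
}
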