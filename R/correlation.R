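#' Two-dimensional spatial velocity autocorrelation of one frame
#'
#' Computes the equal-time velocity autocorrelation map
#' \eqn{C(\delta) = \langle v(x) \cdot v(x + \delta) \rangle_x} with the
#' Fourier-transform method: the inverse transform of the summed power
#' spectra of the two velocity components, under the periodic (circular)
#' convention, so the result matches a direct average over all circular
#' shifts exactly. Invalid vectors are inpainted with the median of their
#' valid neighbors before transforming; frames with more than 30% invalid
#' vectors are rejected as unreliable.
#'
#' @param vx,vy velocity component matrices (`Ny x Nx`).
#' @param valid optional logical matrix; defaults to finite entries.
#' @param drift_correct subtract the spatial mean velocity first
#'   (default `TRUE`: the correlation is then that of the velocity
#'   fluctuations).
#' @return a matrix `Ny x Nx` whose `[1, 1]` entry is the zero-lag value,
#'   with lags wrapping periodically; attribute `inpainted_fraction`.
#' @export
spatial_correlation_2d <- function(vx, vy, valid = NULL,
                                   drift_correct = TRUE) {
  if (is.null(valid)) valid <- is.finite(vx) & is.finite(vy)
  frac_bad <- 1 - mean(valid)
  abort_if(frac_bad > 0.30,
           sprintf("%.0f%% of vectors invalid; inpainting unreliable",
                   100 * frac_bad))
  if (frac_bad > 0) {
    inp <- inpaint_median(vx, vy, valid)
    vx <- inp$vx
    vy <- inp$vy
  }
  if (drift_correct) {
    vx <- vx - mean(vx)
    vy <- vy - mean(vy)
  }
  n <- length(vx)
  cmap <- Re(fft(Mod(fft(vx))^2 + Mod(fft(vy))^2, inverse = TRUE)) / n^2
  attr(cmap, "inpainted_fraction") <- frac_bad
  attr(cmap, "mean_v") <- c(mean(vx), mean(vy))
  cmap
}

inpaint_median <- function(vx, vy, valid) {
  ny <- nrow(vx)
  nx <- ncol(vx)
  for (pass in 1:10) {
    if (all(valid)) break
    todo <- which(!valid, arr.ind = TRUE)
    newv <- valid
    for (k in seq_len(nrow(todo))) {
      iy <- todo[k, 1]
      ix <- todo[k, 2]
      ys <- max(1, iy - 1):min(ny, iy + 1)
      xs <- max(1, ix - 1):min(nx, ix + 1)
      sel <- valid[ys, xs]
      if (any(sel)) {
        vx[iy, ix] <- median(vx[ys, xs][sel])
        vy[iy, ix] <- median(vy[ys, xs][sel])
        newv[iy, ix] <- TRUE
      }
    }
    valid <- newv
  }
  list(vx = vx, vy = vy)
}

#' Radially average a 2D correlation map
#'
#' Lags are taken with the minimum-image convention and converted to
#' micrometres via the window spacing; map values are averaged in
#' annuli centered on multiples of `bin_width` (nearest-center
#' assignment, so the zero lag lands in a bin centered exactly at 0).
#' Empty bins are dropped.
#'
#' @param cmap output of [spatial_correlation_2d()].
#' @param bin_width annulus width, um.
#' @param spacing_x,spacing_y physical distance between adjacent windows,
#'   um.
#' @return a tibble with `r` (bin centers), `C`, `n_pairs`.
#' @export
radial_average <- function(cmap, bin_width, spacing_x = 1,
                           spacing_y = spacing_x) {
  abort_if(bin_width <= 0, "bin_width must be > 0")
  ny <- nrow(cmap)
  nx <- ncol(cmap)
  kx <- 0:(nx - 1)
  kx[kx > nx / 2] <- kx[kx > nx / 2] - nx
  ky <- 0:(ny - 1)
  ky[ky > ny / 2] <- ky[ky > ny / 2] - ny
  lx <- matrix(rep(kx * spacing_x, each = ny), ny)
  ly <- matrix(rep(ky * spacing_y, times = nx), ny)
  r <- sqrt(lx^2 + ly^2)
  idx <- as.integer(round(as.vector(r) / bin_width))
  vals <- tapply(as.vector(cmap), idx, mean)
  cnts <- tapply(rep(1, length(idx)), idx, sum)
  bins <- as.integer(names(vals))
  tibble::tibble(
    r = bins * bin_width,
    C = as.numeric(vals),
    n_pairs = as.integer(cnts))
}

#' Mean-variance correction and normalization of a correlation curve
#'
#' Subtracts the squared mean velocity (the contribution of coherent
#' drift) from the raw radially averaged correlation, then normalizes by
#' the corrected zero-lag value so the curve starts at 1. When the
#' velocity field was drift-corrected before transforming, the
#' subtraction is the identity.
#'
#' @param curve tibble from [radial_average()] (first bin must contain
#'   the zero lag).
#' @param mean_v the spatial mean velocity `(vx, vy)` of the field the
#'   curve was computed from.
#' @return the curve with added columns `C_corrected`, `C_normalized`,
#'   and attribute `converged` (`FALSE` when the corrected zero-lag value
#'   is not positive, e.g. a uniform field with no fluctuations).
#' @export
correct_and_normalize <- function(curve, mean_v = c(0, 0)) {
  drift2 <- sum(mean_v^2)
  out <- curve
  out$C_corrected <- curve$C - drift2
  c0 <- out$C_corrected[1]
  if (!is.finite(c0) || c0 <= 0) {
    out$C_normalized <- NA_real_
    attr(out, "converged") <- FALSE
  } else {
    out$C_normalized <- out$C_corrected / c0
    attr(out, "converged") <- TRUE
  }
  out
}

#' Fit a stretched exponential to a normalized correlation curve
#'
#' Least-squares fit of
#' \eqn{C(r) = \exp(-(r / L_{corr})^{\gamma})}
#' over `r` in `[r_min, r_max]`, excluding the zero-lag bin
#' (self-correlation). `L` is initialized at the linearly interpolated
#' 1/e crossing of the curve (or `r_max / 2` if the curve never crosses),
#' `gamma` at 1; bounds are `L > 0` and `gamma` in `(0, 2]`. The fitted
#' decay length `L_corr` measures how far velocity fluctuations remain
#' spatially correlated.
#'
#' @param r,C_normalized the curve.
#' @param r_min,r_max fit range, um; defaults to the first positive bin
#'   and half the (square) grid extent, beyond which periodic wraparound
#'   aliases the curve.
#' @return list with `L_corr`, `gamma`, `rmse`, `r_range_used`,
#'   `converged`, and `message` on failure. Never silently falls back.
#' @export
fit_correlation_length <- function(r, C_normalized, r_min = NULL,
                                   r_max = NULL) {
  ok <- is.finite(r) & is.finite(C_normalized)
  r <- r[ok]
  C <- C_normalized[ok]
  r_min <- r_min %||% min(r[r > 0])
  r_max <- r_max %||% (max(r) / sqrt(2))
  sel <- r >= r_min & r <= r_max & r > 0
  not_conv <- function(msg) {
    list(L_corr = NA_real_, gamma = NA_real_, rmse = NA_real_,
         r_range_used = c(r_min, r_max), converged = FALSE,
         message = msg)
  }
  if (sum(sel) < 5) return(not_conv("fewer than 5 bins in fit range"))
  rf <- r[sel]
  cf <- C[sel]
  # initialize L at the 1/e crossing; when the curve is already below
  # 1/e at the first bin, invert the model there instead
  below <- which(cf < exp(-1))
  L0 <- if (length(below) > 0 && below[1] > 1) {
    i <- below[1]
    rf[i - 1] + (rf[i] - rf[i - 1]) *
      (cf[i - 1] - exp(-1)) / (cf[i - 1] - cf[i])
  } else if (length(below) > 0 && cf[1] > 0) {
    rf[1] / (-log(max(cf[1], 1e-3)))
  } else {
    r_max / 2
  }
  L0 <- min(max(L0, min(rf) / 4), r_max)
  fit <- NULL
  last_err <- "fit not attempted"
  for (start_L in unique(c(L0, L0 / 4, 4 * L0))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        cf ~ exp(-(rf / L)^g),
        start = list(L = start_L, g = 1),
        lower = c(L = 1e-6, g = 1e-3), upper = c(L = Inf, g = 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(cand, "error")) {
      if (is.null(fit) ||
          sum(residuals(cand)^2) < sum(residuals(fit)^2)) {
        fit <- cand
      }
    } else {
      last_err <- conditionMessage(cand)
    }
  }
  if (is.null(fit)) return(not_conv(last_err))
  est <- coef(fit)
  rmse <- sqrt(mean(residuals(fit)^2))
  list(L_corr = unname(est["L"]), gamma = unname(est["g"]),
       rmse = rmse, r_range_used = c(r_min, r_max), converged = TRUE,
       message = NULL)
}

#' Velocity correlation curve over a time window
#'
#' Averages the per-frame 2D correlation maps over the requested frames
#' (before radial averaging and fitting, so all frames contribute at
#' every lag), radially averages, applies the mean-variance correction,
#' normalizes, and fits the stretched exponential.
#'
#' @param field a [velocity_field()].
#' @param frames 1-based frame indices (default: all frames).
#' @param drift_correct per-frame drift correction (default `TRUE`).
#' @param bin_width radial bin width, um; defaults to the window spacing.
#' @param r_max fit range limit, um.
#' @return a `correlation_curve`: tibble with `r, C, C_corrected,
#'   C_normalized, n_pairs` and attribute `fit`.
#' @export
correlation_over_window <- function(field, frames = NULL,
                                    drift_correct = TRUE,
                                    bin_width = NULL, r_max = NULL) {
  frames <- frames %||% seq_along(field$times)
  abort_if(length(frames) < 1, "need at least one frame")
  spacing_x <- if (length(field$grid_x) > 1) {
    diff(field$grid_x)[1]
  } else {
    field$window_size
  }
  spacing_y <- if (length(field$grid_y) > 1) {
    diff(field$grid_y)[1]
  } else {
    field$window_size
  }
  bin_width <- bin_width %||% (spacing_x / 2)
  acc <- NULL
  mean_vs <- matrix(NA_real_, nrow = length(frames), ncol = 2)
  n_used <- 0L
  last_err <- NULL
  for (k in seq_along(frames)) {
    fr <- field_frame(field, frames[k])
    use <- fr$valid | (field$replaced[frames[k], , ] &
                         is.finite(fr$vx) & is.finite(fr$vy))
    cmap <- tryCatch(
      spatial_correlation_2d(fr$vx, fr$vy, valid = use,
                             drift_correct = drift_correct),
      error = function(e) e)
    if (inherits(cmap, "error")) {
      # frames with too many invalid windows are skipped, not fatal
      last_err <- conditionMessage(cmap)
      next
    }
    mean_vs[k, ] <- attr(cmap, "mean_v")
    acc <- if (is.null(acc)) cmap else acc + cmap
    n_used <- n_used + 1L
  }
  abort_if(n_used == 0L,
           paste0("no usable frames in the correlation window (",
                  last_err %||% "all frames invalid", ")"))
  cmap_mean <- acc / n_used
  mean_vs <- mean_vs[is.finite(mean_vs[, 1]), , drop = FALSE]
  curve <- radial_average(cmap_mean, bin_width, spacing_x, spacing_y)
  mean_v <- sqrt(colMeans(mean_vs^2)) # frame-averaged drift magnitude
  curve <- correct_and_normalize(curve, mean_v = mean_v)
  r_max <- r_max %||% (min(length(field$grid_x) * spacing_x,
                           length(field$grid_y) * spacing_y) / 2)
  fit <- if (isTRUE(attr(curve, "converged"))) {
    fit_correlation_length(curve$r, curve$C_normalized, r_max = r_max)
  } else {
    list(L_corr = NA_real_, gamma = NA_real_, rmse = NA_real_,
         r_range_used = c(NA_real_, NA_real_), converged = FALSE,
         message = "degenerate field: no velocity fluctuations")
  }
  attr(curve, "fit") <- fit
  attr(curve, "n_frames_used") <- n_used
  class(curve) <- c("correlation_curve", class(curve))
  curve
}

#' @export
print.correlation_curve <- function(x, ...) {
  fit <- attr(x, "fit")
  if (isTRUE(fit$converged)) {
    cat(sprintf(
      "<correlation_curve> %d bins; L_corr = %.2f um, gamma = %.3f (rmse %.3g)\n",
      nrow(x), fit$L_corr, fit$gamma, fit$rmse))
  } else {
    cat("<correlation_curve> fit did not converge:",
        fit$message %||% "", "\n")
  }
  NextMethod()
}
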