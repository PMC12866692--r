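# minimal enclosing circle of 2D points: convex hull then exhaustive
# search over pair (diameter) and triple (circumcircle) candidates
min_enclosing_circle <- function(x, y) {
  if (length(x) == 1) return(list(cx = x, cy = y, r = 0))
  h <- grDevices::chull(x, y)
  px <- x[h]
  py <- y[h]
  n <- length(px)
  best <- NULL
  contains_all <- function(cx, cy, r) {
    all((px - cx)^2 + (py - cy)^2 <= r^2 * (1 + 1e-9) + 1e-9)
  }
  consider <- function(cx, cy, r) {
    if ((is.null(best) || r < best$r) && contains_all(cx, cy, r)) {
      best <<- list(cx = cx, cy = cy, r = r)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      consider((px[i] + px[j]) / 2, (py[i] + py[j]) / 2,
               sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2) / 2)
      for (k in seq_len(n)) {
        if (k <= j) next
        ax <- px[i]; ay <- py[i]
        bx <- px[j]; by <- py[j]
        cx <- px[k]; cy <- py[k]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
                 (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
                 (cx^2 + cy^2) * (bx - ax)) / d
        consider(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
      }
    }
  }
  best %||% list(cx = mean(px), cy = mean(py), r = 0)
}

#' Detect the bleached region in a FRAP stack
#'
#' Applies the automatic detection recipe: isolate the bleach frame,
#' median filter (radius 10 px), invert (`65535 - I`), threshold at an
#' inverted intensity of at least 65200, find connected components, keep
#' those with area between 2000 and 4500 um^2, fit the minimal enclosing
#' circle to each, and shrink its area by 20% (radius times `sqrt(0.8)`)
#' to avoid measuring partially bleached cells at the rim. Exactly one
#' region is expected; multiple candidates are all returned with
#' `multiple = TRUE` so a supervisor can choose.
#'
#' @param stack an [image_stack()] (16-bit intensities).
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @param area_range acceptable component area, um^2.
#' @param threshold inverted-intensity threshold (16-bit counts).
#' @param median_radius median filter radius, px.
#' @return list with `rois` (list of `list(cx, cy, r)` in px, radius
#'   already shrunk) and `multiple` flag.
#' @export
detect_bleach_region <- function(stack, bleach_frame,
                                 area_range = c(2000, 4500),
                                 threshold = 65200, median_radius = 10) {
  d <- dim(stack$frames)
  abort_if(bleach_frame < 1 || bleach_frame > d[1],
           "bleach_frame outside the stack")
  img <- stack$frames[bleach_frame, , ] / 65535
  med <- as.matrix(EBImage::medianFilter(img, size = median_radius))
  inv <- 1 - med
  bin <- inv >= threshold / 65535
  lab <- EBImage::bwlabel(bin)
  n_lab <- max(lab)
  px_area <- stack$pixel_size^2
  rois <- list()
  areas_seen <- numeric(0)
  for (lb in seq_len(n_lab)) {
    sel <- which(lab == lb, arr.ind = TRUE)
    area_um2 <- nrow(sel) * px_area
    areas_seen <- c(areas_seen, area_um2)
    if (area_um2 < area_range[1] || area_um2 > area_range[2]) next
    mec <- min_enclosing_circle(sel[, 2], sel[, 1]) # (x = col, y = row)
    rois[[length(rois) + 1]] <- list(cx = mec$cx, cy = mec$cy,
                                     r = mec$r * sqrt(0.8))
  }
  if (length(rois) == 0) {
    stop(sprintf(
      paste0("no bleach region detected: %d components above threshold ",
             "%d (max inverted intensity %.0f), areas [%s] um^2 outside ",
             "range [%g, %g]"),
      n_lab, threshold, max(inv) * 65535,
      paste(signif(areas_seen, 3), collapse = ", "),
      area_range[1], area_range[2]), call. = FALSE)
  }
  list(rois = rois, multiple = length(rois) > 1)
}

region_mean_series <- function(frames, mask) {
  vapply(seq_len(dim(frames)[1]), function(k) {
    mean(frames[k, , ][mask])
  }, numeric(1))
}

disc_mask <- function(d, cx, cy, r) {
  xs <- matrix(rep(seq_len(d[3]), each = d[2]), d[2])
  ys <- matrix(rep(seq_len(d[2]), times = d[3]), d[2])
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Background- and photobleaching-corrected FRAP recovery curve
#'
#' Double normalization: the bleached-region signal is background
#' subtracted, divided by the background-subtracted reference (unbleached)
#' signal to cancel acquisition photobleaching, and scaled so the
#' pre-bleach mean equals one:
#' \deqn{N(t) = \frac{I_{roi}(t) - bg(t)}{I_{ref}(t) - bg(t)} \cdot
#'   \frac{\bar I_{ref}^{pre} - \bar{bg}^{pre}}
#'        {\bar I_{roi}^{pre} - \bar{bg}^{pre}}}
#'
#' @param stack an [image_stack()].
#' @param roi bleach disc, `list(cx, cy, r)` in px (from
#'   [detect_bleach_region()]).
#' @param bleach_frame 1-based first post-bleach frame (>= 3 so at least
#'   two pre-bleach frames exist).
#' @param background_roi optional `list(x0, x1, y0, y1)` px box; default
#'   is a corner box far from the bleach disc. The string `"none"`
#'   disables background subtraction (synthetic stacks with no
#'   cell-free region).
#' @param reference_roi optional disc `list(cx, cy, r)`; default is a
#'   far-field annulus between 2.5 and 4 disc radii, clipped to the
#'   frame.
#' @param method `"double"` (default) or `"unreferenced"` (background
#'   subtraction and pre-bleach scaling only; no photobleaching
#'   correction).
#' @return a `frap_curve` tibble: `t_s, raw, background, reference,
#'   normalized`; attributes `pre_bleach_mean`, `bleach_frame`.
#' @export
normalize_recovery <- function(stack, roi, bleach_frame,
                               background_roi = NULL,
                               reference_roi = NULL,
                               method = c("double", "unreferenced")) {
  method <- match.arg(method)
  d <- dim(stack$frames)
  abort_if(bleach_frame < 3 || bleach_frame > d[1],
           "need at least 2 pre-bleach frames")
  roi_mask <- disc_mask(d, roi$cx, roi$cy, roi$r)
  abort_if(!any(roi_mask), "bleach ROI contains no pixels")
  no_background <- identical(background_roi, "none")
  if (no_background) background_roi <- NULL
  if (is.null(background_roi)) {
    bw <- max(4L, round(min(d[2:3]) / 10))
    # corner farthest from the bleach center
    corner_x <- if (roi$cx > d[3] / 2) 1L else d[3] - bw + 1L
    corner_y <- if (roi$cy > d[2] / 2) 1L else d[2] - bw + 1L
    background_roi <- list(x0 = corner_x, x1 = corner_x + bw - 1L,
                           y0 = corner_y, y1 = corner_y + bw - 1L)
  }
  bg_mask <- matrix(FALSE, d[2], d[3])
  if (!no_background) {
    bg_mask[background_roi$y0:background_roi$y1,
            background_roi$x0:background_roi$x1] <- TRUE
  }
  if (is.null(reference_roi)) {
    xs <- matrix(rep(seq_len(d[3]), each = d[2]), d[2])
    ys <- matrix(rep(seq_len(d[2]), times = d[3]), d[2])
    rr <- sqrt((xs - roi$cx)^2 + (ys - roi$cy)^2)
    ref_mask <- rr >= 2.5 * roi$r & rr <= 4 * roi$r
  } else {
    ref_mask <- disc_mask(d, reference_roi$cx, reference_roi$cy,
                          reference_roi$r)
  }
  ref_mask <- ref_mask & !bg_mask & !roi_mask
  abort_if(!any(ref_mask), "reference region empty")
  i_roi <- region_mean_series(stack$frames, roi_mask)
  i_bg <- if (no_background) {
    rep(0, d[1])
  } else {
    region_mean_series(stack$frames, bg_mask)
  }
  i_ref <- region_mean_series(stack$frames, ref_mask)
  abort_if(any(i_ref <= i_bg),
           "reference signal at or below background; choose other ROIs")
  pre <- seq_len(bleach_frame - 1)
  if (method == "double") {
    ratio <- (i_roi - i_bg) / (i_ref - i_bg)
    scale <- (mean(i_ref[pre]) - mean(i_bg[pre])) /
      (mean(i_roi[pre]) - mean(i_bg[pre]))
    normalized <- ratio * scale
  } else {
    normalized <- (i_roi - i_bg) / (mean(i_roi[pre]) - mean(i_bg[pre]))
  }
  t_s <- (seq_len(d[1]) - 1) * stack$frame_interval * 3600
  out <- tibble::tibble(t_s = t_s, raw = i_roi, background = i_bg,
                        reference = i_ref, normalized = normalized)
  attr(out, "pre_bleach_mean") <- mean(normalized[pre])
  attr(out, "bleach_frame") <- bleach_frame
  class(out) <- c("frap_curve", class(out))
  out
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Post-bleach, the normalized curve is fitted with
#' `N(t) = plateau - A exp(-k (t - t_bleach))`. The bleach depth is
#' estimated from the first post-bleach point, `d = 1 - N(t_bleach)`, and
#' the mobile fraction follows as `f = (plateau - (1 - d)) / d`.
#'
#' @param curve a `frap_curve` from [normalize_recovery()].
#' @return list with `plateau`, `k` (per second), `bleach_depth`,
#'   `mobile_fraction`, `converged`.
#' @export
fit_frap_recovery <- function(curve) {
  bf <- attr(curve, "bleach_frame")
  abort_if(is.null(bf), "curve lacks a bleach_frame attribute")
  post <- curve[seq(bf, nrow(curve)), ]
  tt <- post$t_s - post$t_s[1]
  nn <- post$normalized
  n0 <- nn[1]
  d_est <- 1 - n0
  p0 <- tail(nn, 1)
  a0 <- max(p0 - n0, 1e-3)
  half_idx <- which(nn >= n0 + (p0 - n0) / 2)[1]
  k0 <- if (!is.na(half_idx) && tt[half_idx] > 0) {
    log(2) / tt[half_idx]
  } else {
    1 / max(tt[length(tt)], 1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(nn ~ p - A * exp(-k * tt),
                      start = list(p = p0, A = a0, k = k0),
                      lower = c(p = 0, A = 0, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(plateau = NA_real_, k = NA_real_, bleach_depth = d_est,
                mobile_fraction = NA_real_, converged = FALSE))
  }
  est <- coef(fit)
  plateau <- unname(est["p"])
  f <- if (d_est > 0) (plateau - (1 - d_est)) / d_est else NA_real_
  list(plateau = plateau, k = unname(est["k"]), bleach_depth = d_est,
       mobile_fraction = f, converged = TRUE)
}

#' Normalized spreading (wetting) curve
#'
#' Areas are normalized to the area at the first time point,
#' `A(t) / A(t0)`. Input is either a data frame of areas over time or a
#' [label_mask_stack()], in which case the area per frame is the labeled
#' (non-zero) pixel count times the pixel area.
#'
#' @param areas data.frame with `t` and `area`, or a
#'   [label_mask_stack()].
#' @return tibble with `t`, `area`, `area_normalized`.
#' @export
wetting_curve <- function(areas) {
  if (inherits(areas, "label_mask_stack")) {
    a <- vapply(seq_len(dim(areas$frames)[1]), function(k) {
      sum(areas$frames[k, , ] > 0) * areas$pixel_size^2
    }, numeric(1))
    areas <- data.frame(t = seq_along(a) - 1, area = a)
  }
  abort_if(!all(c("t", "area") %in% names(areas)),
           "areas must have columns t and area")
  abort_if(areas$area[1] <= 0, "initial area must be > 0")
  tibble::tibble(t = areas$t, area = areas$area,
                 area_normalized = areas$area / areas$area[1])
}
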