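# pairwise distance matrix, optionally with periodic minimum image
pair_dists <- function(x, y, box = NULL) {
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  if (!is.null(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
  }
  sqrt(dx^2 + dy^2)
}

#' Radial distribution function of a 2D point pattern
#'
#' Standard pair-correlation `g(r)` normalized by the ideal-gas
#' expectation at the sample density, so `g -> 1` at large `r` for a
#' homogeneous pattern. With `periodic = TRUE` distances use the
#' minimum-image convention in a square box; otherwise edge effects are
#' handled by a guard region (only points at least `r_max` from the
#' boundary serve as reference points).
#'
#' @param x,y point coordinates, um.
#' @param box box side, um (square). For non-periodic data, the bounding
#'   extent of the field of view.
#' @param bin_width bin width, um (> 0).
#' @param periodic minimum-image distances (synthetic data) or
#'   guard-region edge correction (bounded fields of view).
#' @param r_max largest distance tabulated; defaults to `box / 2`
#'   (periodic) or `box / 4` (guard).
#' @return an `rdf_curve`: tibble with `r` (bin centers), `g`, `n_pairs`.
#' @export
radial_distribution <- function(x, y, box, bin_width, periodic = TRUE,
                                r_max = NULL) {
  abort_if(bin_width <= 0, "bin_width must be > 0")
  n <- length(x)
  abort_if(n < 10, "need at least 10 points for an RDF")
  r_max <- r_max %||% (if (periodic) box / 2 else box / 4)
  rho <- n / box^2
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  if (periodic) {
    d <- pair_dists(x, y, box = box)
    dv <- d[upper.tri(d)]
    idx <- bin_index(dv, breaks)
    counts <- tapply(rep(2, length(idx)), idx, sum) # ordered pairs
    n_ref <- n
  } else {
    ref <- x >= r_max & x <= box - r_max & y >= r_max & y <= box - r_max
    abort_if(!any(ref), "guard region empty; reduce r_max")
    d <- pair_dists(x, y)
    d <- d[ref, , drop = FALSE]
    d[cbind(seq_len(sum(ref)), which(ref))] <- NA # self distances
    dv <- as.vector(d)
    dv <- dv[is.finite(dv)]
    idx <- bin_index(dv, breaks)
    counts <- tapply(rep(1, length(idx)), idx, sum)
    n_ref <- sum(ref)
  }
  bins <- as.integer(names(counts))
  full <- seq_len(length(breaks) - 1)
  cnt <- setNames(rep(0, length(full)), full)
  cnt[as.character(bins)] <- counts
  lo <- breaks[full]
  hi <- breaks[full + 1]
  area <- pi * (hi^2 - lo^2)
  g <- as.numeric(cnt) / (n_ref * rho * area)
  keep <- hi <= r_max + bin_width / 2
  out <- tibble::tibble(r = ((lo + hi) / 2)[keep], g = g[keep],
                        n_pairs = as.integer(cnt)[keep])
  class(out) <- c("rdf_curve", class(out))
  out
}

#' Neighbor threshold from the first RDF valley
#'
#' The neighbor distance threshold is the position of the first local
#' minimum of the (smoothed) `g(r)` after its first peak. The peak must
#' rise above 1.2, and the valley must dip either below 1 or below 75%
#' of the peak height (together rejecting both sampling noise around the
#' ideal-gas level and shoulder artifacts, while accepting the shallow
#' first valley of strongly overlapping soft-disc packings); an RDF
#' without such structure is an error advising a manual threshold.
#'
#' @param rdf an `rdf_curve` from [radial_distribution()].
#' @param smoothing moving-average window in bins (default 3).
#' @return the threshold radius, um.
#' @export
first_valley_threshold <- function(rdf, smoothing = 3) {
  g <- moving_average(rdf$g, smoothing)
  r <- rdf$r
  n <- length(g)
  abort_if(n < 5, "RDF has too few bins")
  peak <- NA_integer_
  for (i in 2:(n - 1)) {
    if (g[i] > g[i - 1] && g[i] >= g[i + 1] && g[i] > 1.2) {
      peak <- i
      break
    }
  }
  abort_if(is.na(peak),
           "no RDF peak found; supply a manual neighbor threshold")
  depth_ok <- function(v) v < max(1, 0.75 * g[peak])
  for (i in (peak + 1):(n - 1)) {
    if (g[i] <= g[i - 1] && g[i] < g[i + 1] && depth_ok(g[i])) {
      return(r[i])
    }
  }
  stop("no RDF valley after the first peak; supply a manual neighbor ",
       "threshold", call. = FALSE)
}

#' Assign neighbors at one frame by distance threshold
#'
#' Cells strictly closer than `r_thresh` are neighbors (a pair exactly at
#' the threshold is not).
#'
#' @param tracks a [track_table()].
#' @param frame frame number.
#' @param r_thresh neighbor distance threshold, um (> 0).
#' @param box box side for periodic minimum-image distances, or `NULL`
#'   for plain Euclidean distances.
#' @return list with `edges` (tibble `i, j` of track ids, both
#'   orientations) and `n_neighbors` (named vector per track id).
#' @export
assign_neighbors <- function(tracks, frame, r_thresh, box = NULL) {
  abort_if(r_thresh <= 0, "r_thresh must be > 0")
  fr <- tracks[tracks$frame == frame, ]
  ids <- fr$track_id
  d <- pair_dists(fr$x, fr$y, box = box)
  diag(d) <- Inf
  adj <- d < r_thresh
  idx <- which(adj, arr.ind = TRUE)
  edges <- tibble::tibble(i = ids[idx[, 1]], j = ids[idx[, 2]])
  nn <- rowSums(adj)
  names(nn) <- ids
  list(edges = edges, n_neighbors = nn)
}

#' Interpolate short track gaps
#'
#' Fills gaps of at most `max_gap` frames by linear interpolation of all
#' numeric columns (matching common gap-closing tracker settings); longer
#' gaps are left open, which breaks neighbor pairs across them.
#'
#' @param tracks a [track_table()].
#' @param max_gap largest gap filled, frames.
#' @return a [track_table()] with interpolated rows added.
#' @export
fill_track_gaps <- function(tracks, max_gap = 3) {
  frames_all <- sort(unique(tracks$frame))
  t_of_frame <- tapply(tracks$t, tracks$frame, function(v) v[1])
  pieces <- list()
  num_cols <- setdiff(names(tracks)[vapply(tracks, is.numeric,
                                           logical(1))],
                      c("track_id", "frame", "t"))
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    gaps <- which(diff(tr$frame) > 1)
    for (gidx in gaps) {
      span <- tr$frame[gidx + 1] - tr$frame[gidx] - 1
      if (span > max_gap) next
      new_frames <- (tr$frame[gidx] + 1):(tr$frame[gidx + 1] - 1)
      w <- (new_frames - tr$frame[gidx]) /
        (tr$frame[gidx + 1] - tr$frame[gidx])
      add <- tr[rep(gidx, length(new_frames)), ]
      add$frame <- new_frames
      add$t <- as.numeric(t_of_frame[as.character(new_frames)])
      miss <- is.na(add$t)
      if (any(miss)) {
        add$t[miss] <- tr$t[gidx] + w[miss] * (tr$t[gidx + 1] - tr$t[gidx])
      }
      for (cc in num_cols) {
        add[[cc]] <- tr[[cc]][gidx] + w * (tr[[cc]][gidx + 1] -
                                             tr[[cc]][gidx])
      }
      pieces[[length(pieces) + 1]] <- add
    }
  }
  if (length(pieces) == 0) return(tracks)
  out <- rbind(as.data.frame(tracks), do.call(rbind, pieces))
  res <- track_table(out)
  for (a in c("box_size", "config")) attr(res, a) <- attr(tracks, a)
  res
}

#' Neighbor-exchange distance curve d(dt)
#'
#' For each reference time `t`, neighbors are assigned by the distance
#' threshold; `d(dt)` is the average distance at `t + dt` between each
#' cell and the neighbors it had at `t`, double-normalized per the
#' probability-map convention: cells weighted `1/N(t)` and each cell's
#' neighbors weighted `1/n_i(t)`, then averaged over all valid reference
#' times. Cells with no neighbors at `t` drop out of the average (the
#' realized weights are renormalized, which equals the plain
#' double-normalized sum whenever every cell has at least one neighbor,
#' as in a confluent monolayer). `Dd(dt) = d(dt) - d(0)` starts at zero
#' and its linear growth
#' rate quantifies neighbor exchange: zero for a solid (neighbors
#' retained), positive and roughly linear for a fluid.
#'
#' @param tracks a [track_table()]; unwrapped coordinates are used for
#'   the lagged distances when available.
#' @param r_thresh neighbor threshold, um (see
#'   [first_valley_threshold()]).
#' @param dt_max largest time delay, h.
#' @param box box side for periodic neighbor assignment, or `NULL`.
#' @param stride reference-time stride in frames (default 1: every
#'   frame).
#' @param max_gap track gaps up to this many frames are interpolated;
#'   pairs broken by longer gaps are dropped and counted.
#' @return an `exchange_curve`: tibble with `dt` (h), `d` (um),
#'   `delta_d` (um), `n_pairs`; attributes `slope` (um/h), `slope_ci`
#'   (95%), `n_dropped`.
#' @export
neighbor_distance_curve <- function(tracks, r_thresh, dt_max, box = NULL,
                                    stride = 1L, max_gap = 3) {
  tracks <- fill_track_gaps(tracks, max_gap = max_gap)
  frames <- sort(unique(tracks$frame))
  t_of_frame <- as.numeric(tapply(tracks$t, tracks$frame,
                                  function(v) v[1]))
  frame_interval <- if (length(frames) > 1) diff(t_of_frame)[1] else 1
  lag_max <- floor(dt_max / frame_interval + 1e-9)
  abort_if(lag_max < 1, "dt_max shorter than one frame interval")
  abort_if(length(frames) <= lag_max, "tracks too short for dt_max")
  use_unwrap <- all(c("x_unwrap", "y_unwrap") %in% names(tracks))
  xs <- if (use_unwrap) tracks$x_unwrap else tracks$x
  ys <- if (use_unwrap) tracks$y_unwrap else tracks$y
  # position lookup: frame index x track id
  ids <- sort(unique(tracks$track_id))
  fi <- match(tracks$frame, frames)
  ci <- match(tracks$track_id, ids)
  X <- matrix(NA_real_, nrow = length(frames), ncol = length(ids))
  Y <- X
  X[cbind(fi, ci)] <- xs
  Y[cbind(fi, ci)] <- ys
  # each delay uses every reference time that still has lag frames of
  # track ahead of it (pairs ending earlier are dropped and counted)
  refs <- seq(1L, length(frames), by = stride)
  lags <- 0:lag_max
  acc <- matrix(0, nrow = length(refs), ncol = length(lags))
  wsum <- matrix(0, nrow = length(refs), ncol = length(lags))
  npair <- matrix(0L, nrow = length(refs), ncol = length(lags))
  n_dropped <- 0L
  for (a in seq_along(refs)) {
    f <- refs[a]
    nb <- assign_neighbors(tracks, frames[f], r_thresh, box = box)
    if (nrow(nb$edges) == 0) next
    n_t <- sum(tracks$frame == frames[f])
    ii <- match(nb$edges$i, ids)
    jj <- match(nb$edges$j, ids)
    ni <- as.numeric(nb$n_neighbors[as.character(nb$edges$i)])
    w <- 1 / (n_t * ni)
    for (l in seq_along(lags)) {
      fl <- f + lags[l]
      if (fl > length(frames)) next
      xi <- X[fl, ii]
      yi <- Y[fl, ii]
      xj <- X[fl, jj]
      yj <- Y[fl, jj]
      ok <- is.finite(xi) & is.finite(xj) & is.finite(yi) & is.finite(yj)
      n_dropped <- n_dropped + sum(!ok)
      if (!any(ok)) next
      dd <- sqrt((xi[ok] - xj[ok])^2 + (yi[ok] - yj[ok])^2)
      acc[a, l] <- sum(w[ok] * dd)
      wsum[a, l] <- sum(w[ok])
      npair[a, l] <- sum(ok)
    }
  }
  # per-reference-time double-normalized mean, then average over t
  d_of_lag <- vapply(seq_along(lags), function(l) {
    per_t <- acc[, l] / wsum[, l]
    mean(per_t[is.finite(per_t)])
  }, numeric(1))
  dt_h <- lags * frame_interval
  out <- tibble::tibble(dt = dt_h, d = d_of_lag,
                        delta_d = d_of_lag - d_of_lag[1],
                        n_pairs = colSums(npair))
  fitdf <- out[is.finite(out$delta_d), ]
  slope <- NA_real_
  slope_ci <- c(NA_real_, NA_real_)
  if (nrow(fitdf) >= 2) {
    fit <- lm(delta_d ~ dt, data = fitdf)
    slope <- unname(coef(fit)["dt"])
    ci <- tryCatch(suppressWarnings(stats::confint(fit)["dt", ]),
                   error = function(e) c(NA_real_, NA_real_))
    slope_ci <- as.numeric(ci)
  }
  attr(out, "slope") <- slope
  attr(out, "slope_ci") <- slope_ci
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("exchange_curve", class(out))
  out
}

#' Neighbor displacement probability map P(r, dt)
#'
#' The probability of finding a cell at relative displacement `(x, y)`
#' from where it stood relative to a reference cell, a delay `dt` after
#' being that cell's neighbor: a 2D histogram of
#' `r_ij(t + dt) - r_ij(t)` over all neighbor pairs `(i, j)` assigned at
#' `t`, each weighted `1/(N(t) n_i(t))`, averaged over reference times
#' and normalized to unit integral.
#'
#' @inheritParams neighbor_distance_curve
#' @param dt time delay, h.
#' @param bin_width histogram bin width, um.
#' @param extent half-width of the map, um.
#' @return a `displacement_map`: list with `x`, `y` (bin centers), `P`
#'   (matrix, y rows), `dt`, `bin_width`.
#' @export
neighbor_displacement_map <- function(tracks, r_thresh, dt, bin_width,
                                      extent = NULL, box = NULL,
                                      stride = 1L) {
  frames <- sort(unique(tracks$frame))
  t_of_frame <- as.numeric(tapply(tracks$t, tracks$frame,
                                  function(v) v[1]))
  frame_interval <- if (length(frames) > 1) diff(t_of_frame)[1] else 1
  lag <- as.integer(round(dt / frame_interval))
  abort_if(lag < 0 || lag >= length(frames),
           "dt outside the track support")
  use_unwrap <- all(c("x_unwrap", "y_unwrap") %in% names(tracks))
  xs <- if (use_unwrap) tracks$x_unwrap else tracks$x
  ys <- if (use_unwrap) tracks$y_unwrap else tracks$y
  ids <- sort(unique(tracks$track_id))
  fi <- match(tracks$frame, frames)
  ci <- match(tracks$track_id, ids)
  X <- matrix(NA_real_, nrow = length(frames), ncol = length(ids))
  Y <- X
  X[cbind(fi, ci)] <- xs
  Y[cbind(fi, ci)] <- ys
  extent <- extent %||% max(3 * r_thresh, 10 * bin_width)
  breaks <- seq(-extent, extent, by = bin_width)
  nb_bins <- length(breaks) - 1
  P <- matrix(0, nb_bins, nb_bins)
  refs <- seq(1L, length(frames) - lag, by = stride)
  total_w <- 0
  any_pairs <- FALSE
  for (f in refs) {
    nb <- assign_neighbors(tracks, frames[f], r_thresh, box = box)
    if (nrow(nb$edges) == 0) next
    n_t <- sum(tracks$frame == frames[f])
    ii <- match(nb$edges$i, ids)
    jj <- match(nb$edges$j, ids)
    ni <- as.numeric(nb$n_neighbors[as.character(nb$edges$i)])
    w <- 1 / (n_t * ni)
    dx <- (X[f + lag, jj] - X[f + lag, ii]) - (X[f, jj] - X[f, ii])
    dy <- (Y[f + lag, jj] - Y[f + lag, ii]) - (Y[f, jj] - Y[f, ii])
    ok <- is.finite(dx) & is.finite(dy)
    if (!any(ok)) next
    any_pairs <- TRUE
    bx <- bin_index(dx[ok], breaks)
    by <- bin_index(dy[ok], breaks)
    inside <- !is.na(bx) & !is.na(by)
    ww <- w[ok][inside]
    for (k in which(inside)) {
      P[by[k], bx[k]] <- P[by[k], bx[k]] + w[ok][k]
    }
    total_w <- total_w + sum(ww)
  }
  abort_if(!any_pairs, "no neighbor pairs found for this dt")
  P <- P / (sum(P) * bin_width^2) # unit integral
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(x = centers, y = centers, P = P, dt = dt,
                 bin_width = bin_width),
            class = "displacement_map")
}
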