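# shared fixture builders; everything is generated in code at test time

# wrap vx/vy matrices (Ny x Nx) into a single-frame velocity field with
# unit window spacing unless given
mat_field <- function(vx, vy, spacing = 10, window_size = spacing) {
  ny <- nrow(vx)
  nx <- ncol(vx)
  velocity_field(times = 0,
                 grid_x = seq_len(nx) * spacing,
                 grid_y = seq_len(ny) * spacing,
                 vx = array(vx, c(1, ny, nx)),
                 vy = array(vy, c(1, ny, nx)),
                 window_size = window_size)
}

# direct circular-shift correlation oracle: C(dy, dx) =
# mean_x v(x) . v(x + d), brute force over all shifts
direct_corr2d <- function(vx, vy) {
  ny <- nrow(vx)
  nx <- ncol(vx)
  out <- matrix(0, ny, nx)
  for (dy in 0:(ny - 1)) {
    for (dx in 0:(nx - 1)) {
      sx <- vx[((seq_len(ny) - 1 + dy) %% ny) + 1,
               ((seq_len(nx) - 1 + dx) %% nx) + 1]
      sy <- vy[((seq_len(ny) - 1 + dy) %% ny) + 1,
               ((seq_len(nx) - 1 + dx) %% nx) + 1]
      out[dy + 1, dx + 1] <- mean(vx * sx + vy * sy)
    }
  }
  out
}

# circularly shift matrix content by (dy rows, dx cols)
shift_mat <- function(m, dy, dx) {
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

# smooth random texture in [0, 60000], periodic
random_texture <- function(n, passes = 4) {
  m <- matrix(runif(n * n), n)
  for (i in seq_len(passes)) {
    m <- (m + m[c(2:n, 1), ] + m[c(n, 1:(n - 1)), ] +
            m[, c(2:n, 1)] + m[, c(n, 1:(n - 1))]) / 5
  }
  (m - min(m)) / (max(m) - min(m)) * 60000
}

raster_grid <- function(n) {
  list(xs = matrix(rep(seq_len(n) - 0.5, each = n), n),   # xs[i,j] = j-0.5
       ys = matrix(rep(seq_len(n) - 0.5, times = n), n))  # ys[i,j] = i-0.5
}

raster_disc <- function(n, cx, cy, r) {
  g <- raster_grid(n); xs <- g$xs; ys <- g$ys
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= r^2), n)
}

raster_rect <- function(n, cx, cy, hw, hh) {
  g <- raster_grid(n); xs <- g$xs; ys <- g$ys
  matrix(as.integer(abs(xs - cx) <= hw & abs(ys - cy) <= hh), n)
}

raster_ellipse <- function(n, cx, cy, a, b, angle = 0) {
  g <- raster_grid(n); xs <- g$xs; ys <- g$ys
  xr <- (xs - cx) * cos(angle) + (ys - cy) * sin(angle)
  yr <- -(xs - cx) * sin(angle) + (ys - cy) * cos(angle)
  matrix(as.integer((xr / a)^2 + (yr / b)^2 <= 1), n)
}

raster_triangle <- function(n, cx, cy, s) {
  g <- raster_grid(n); xs <- g$xs; ys <- g$ys
  v <- rbind(c(cx, cy - s / sqrt(3)),
             c(cx - s / 2, cy + s / (2 * sqrt(3))),
             c(cx + s / 2, cy + s / (2 * sqrt(3))))
  sgn <- function(p1, p2) {
    (xs - p2[1]) * (p1[2] - p2[2]) - (p1[1] - p2[1]) * (ys - p2[2])
  }
  d1 <- sgn(v[1, ], v[2, ])
  d2 <- sgn(v[2, ], v[3, ])
  d3 <- sgn(v[3, ], v[1, ])
  inside <- !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
  matrix(as.integer(inside), n)
}

# hexagonal (triangular) lattice points with spacing a inside [0, box]^2
hex_lattice <- function(a, box) {
  rows <- floor(box / (a * sqrt(3) / 2))
  pts <- NULL
  for (r in 0:rows) {
    y <- r * a * sqrt(3) / 2
    offset <- if (r %% 2 == 0) 0 else a / 2
    xs <- seq(offset, box, by = a)
    pts <- rbind(pts, cbind(xs, y))
  }
  pts <- pts[pts[, 1] <= box & pts[, 2] <= box, ]
  colnames(pts) <- c("x", "y")
  pts
}

# Gaussian random velocity field whose periodic correlation is the
# minimum-image exponential exp(-r/L): spectral synthesis with the
# discrete spectrum S = FFT(target correlation), so the periodic
# estimator recovers the target exactly in expectation (using the
# continuum spectrum (1 + (kL)^2)^(-3/2) instead biases L upward once L
# is no longer small against the box)
grf_exponential <- function(n, L, spacing = 1) {
  lag <- c(0:(n / 2), -(n / 2 - 1):-1) * spacing
  r <- sqrt(outer(lag^2, rep(1, n)) + outer(rep(1, n), lag^2))
  S <- Re(fft(exp(-r / L)))
  S[S < 0] <- 0
  gen <- function() {
    wn <- matrix(rnorm(n * n), n)
    f <- fft(wn) * sqrt(S)
    Re(fft(f, inverse = TRUE)) / (n * n)
  }
  list(vx = gen(), vy = gen())
}

# tiny deterministic track table
toy_tracks <- function() {
  track_table(data.frame(
    track_id = rep(1:3, each = 4),
    frame = rep(0:3, times = 3),
    t = rep(0:3, times = 3) / 12,
    x = c(10, 11, 12, 13, 50, 50, 50, 50, 30, 31, 32, 33),
    y = c(10, 10, 10, 10, 50, 51, 52, 53, 30, 30, 30, 30)))
}
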