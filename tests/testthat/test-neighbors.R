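test_that("RDF matches lattice geometry and CSR expectations", {
  # hexagonal lattice: first peak at a, gap until a*sqrt(3)
  a <- 20
  pts <- hex_lattice(a, 400)
  # bin width 3 keeps each lattice shell inside one bin (a width that
  # puts a break exactly at a shell distance splits it across two bins)
  rdf <- radial_distribution(pts[, 1], pts[, 2], box = 400,
                             bin_width = 3, periodic = FALSE)
  peak_r <- rdf$r[which.max(rdf$g)]
  expect_equal(peak_r, a, tolerance = 0.08)
  gap <- rdf$r > a * 1.1 & rdf$r < a * sqrt(3) * 0.93
  expect_true(all(rdf$g[gap] < 0.1))
  thr <- first_valley_threshold(rdf)
  expect_gt(thr, a)
  expect_lt(thr, a * sqrt(3))

  # Poisson points: g ~ 1 beyond two mean spacings
  set.seed(31)
  n <- 2000
  box <- 1000
  x <- runif(n, 0, box)
  y <- runif(n, 0, box)
  rdf2 <- radial_distribution(x, y, box = box, bin_width = 5,
                              periodic = TRUE)
  far <- rdf2$r > 2 * box / sqrt(n)
  expect_true(all(abs(rdf2$g[far] - 1) < 0.1))
  # an ideal gas has no valley below 1
  expect_error(first_valley_threshold(rdf2), "threshold")

  expect_error(radial_distribution(x, y, box, bin_width = 0), "bin_width")
})

test_that("an isolated close pair gives a single nonzero RDF bin", {
  # fewer than 10 points is rejected
  expect_error(radial_distribution(c(0, 7), c(0, 0), box = 100,
                                   bin_width = 1), "10 points")
  # 10 points, exactly one pair within r_max, at distance 7
  xx <- c(0, 7, seq(30, 95, length.out = 8))
  yy <- c(0, 0, rep(seq(40, 80, length.out = 4), 2))
  r3 <- radial_distribution(xx, yy, box = 200, bin_width = 1,
                            periodic = TRUE, r_max = 10)
  nz <- which(r3$n_pairs > 0)
  expect_length(nz, 1)
  expect_equal(r3$r[nz], 7, tolerance = 0.5)
})

test_that("neighbor assignment uses a strict threshold", {
  tr <- track_table(data.frame(
    track_id = 1:3, frame = 0, t = 0,
    x = c(0, 10, 50), y = c(0, 0, 0)))
  nb <- assign_neighbors(tr, 0, r_thresh = 10)
  expect_equal(unname(nb$n_neighbors), c(0, 0, 0)) # exactly at 10: not neighbors
  nb2 <- assign_neighbors(tr, 0, r_thresh = 10.001)
  expect_equal(unname(nb2$n_neighbors), c(1, 1, 0))

  # hexagonal interior cell has 6 neighbors
  pts <- hex_lattice(20, 200)
  trh <- track_table(data.frame(track_id = seq_len(nrow(pts)), frame = 0,
                                t = 0, x = pts[, 1], y = pts[, 2]))
  nbh <- assign_neighbors(trh, 0, r_thresh = 25)
  interior <- pts[, 1] > 30 & pts[, 1] < 170 & pts[, 2] > 30 &
    pts[, 2] < 170
  expect_true(all(nbh$n_neighbors[interior] == 6))
})

test_that("neighbor-exchange curve vanishes under rigid motion", {
  set.seed(33)
  n <- 60
  x0 <- runif(n, 0, 100)
  y0 <- runif(n, 0, 100)
  frames <- 0:10
  # rigid translation
  tr_t <- track_table(data.frame(
    track_id = rep(seq_len(n), each = length(frames)),
    frame = rep(frames, n),
    t = rep(frames, n) / 12,
    x = rep(x0, each = length(frames)) + rep(frames, n) * 2,
    y = rep(y0, each = length(frames)) - rep(frames, n) * 1))
  ex_t <- neighbor_distance_curve(tr_t, r_thresh = 15, dt_max = 10 / 12)
  expect_true(all(abs(ex_t$delta_d) < 1e-12))
  expect_equal(attr(ex_t, "slope"), 0, tolerance = 1e-12)

  # rigid rotation about the box center
  ang <- rep(frames, n) * 0.15
  xc <- rep(x0, each = length(frames)) - 50
  yc <- rep(y0, each = length(frames)) - 50
  tr_r <- track_table(data.frame(
    track_id = rep(seq_len(n), each = length(frames)),
    frame = rep(frames, n),
    t = rep(frames, n) / 12,
    x = 50 + xc * cos(ang) - yc * sin(ang),
    y = 50 + xc * sin(ang) + yc * cos(ang)))
  ex_r <- neighbor_distance_curve(tr_r, r_thresh = 15, dt_max = 10 / 12)
  expect_true(all(abs(ex_r$delta_d) < 1e-12))

  # n_pairs never increases with delay
  expect_true(all(diff(ex_t$n_pairs) <= 0))
})

test_that("exchange statistic matches a brute-force oracle on random walks", {
  set.seed(34)
  n <- 200
  frames <- 0:6
  sigma <- 1.5
  x <- matrix(0, length(frames), n)
  y <- matrix(0, length(frames), n)
  x[1, ] <- runif(n, 0, 150)
  y[1, ] <- runif(n, 0, 150)
  for (f in 2:length(frames)) {
    x[f, ] <- x[f - 1, ] + rnorm(n, sd = sigma)
    y[f, ] <- y[f - 1, ] + rnorm(n, sd = sigma)
  }
  tr <- track_table(data.frame(
    track_id = rep(seq_len(n), each = length(frames)),
    frame = rep(frames, n), t = rep(frames, n) / 12,
    x = as.vector(apply(x, 2, identity)),
    y = as.vector(apply(y, 2, identity))))
  r_thresh <- 12
  ex <- neighbor_distance_curve(tr, r_thresh, dt_max = 0.5, stride = 1L)

  # independent O(N^2) oracle straight from the definition: per
  # reference time, average neighbor distance per cell (1/n_i sum_j),
  # averaged over the cells that have neighbors, then over t
  lags <- 0:6
  d_oracle <- rep(NA_real_, length(lags))
  for (l in seq_along(lags)) {
    per_t <- numeric(0)
    for (f0 in seq_len(length(frames) - lags[l])) {
      fl <- f0 + lags[l]
      acc <- 0
      n_with <- 0
      for (i in seq_len(n)) {
        dists0 <- sqrt((x[f0, ] - x[f0, i])^2 + (y[f0, ] - y[f0, i])^2)
        nbrs <- which(dists0 < r_thresh & seq_len(n) != i)
        if (length(nbrs) == 0) next
        dl <- sqrt((x[fl, nbrs] - x[fl, i])^2 +
                     (y[fl, nbrs] - y[fl, i])^2)
        acc <- acc + mean(dl)
        n_with <- n_with + 1
      }
      per_t <- c(per_t, acc / n_with)
    }
    d_oracle[l] <- mean(per_t)
  }
  expect_equal(ex$d, d_oracle, tolerance = 1e-12)
  expect_equal(ex$delta_d, d_oracle - d_oracle[1], tolerance = 1e-12)
  # monotone growth for independent walkers
  expect_true(all(diff(ex$delta_d) > 0))
})

test_that("displacement map concentrates and normalizes correctly", {
  set.seed(35)
  n <- 40
  frames <- 0:5
  x0 <- runif(n, 0, 80)
  y0 <- runif(n, 0, 80)
  tr <- track_table(data.frame(
    track_id = rep(seq_len(n), each = length(frames)),
    frame = rep(frames, n), t = rep(frames, n) / 12,
    x = rep(x0, each = length(frames)) + rep(frames, n) * 3,
    y = rep(y0, each = length(frames))))
  # dt = 0: all mass in the central bin
  m0 <- neighbor_displacement_map(tr, r_thresh = 15, dt = 0,
                                  bin_width = 2)
  center <- which(m0$x == 0)
  expect_equal(sum(m0$P > 0), 1)
  expect_gt(m0$P[center, center], 0)
  # unit integral
  expect_equal(sum(m0$P) * m0$bin_width^2, 1)

  # rigid translation: central bin for every dt
  m1 <- neighbor_displacement_map(tr, r_thresh = 15, dt = 5 / 12,
                                  bin_width = 2)
  expect_equal(sum(m1$P > 0), 1)
  expect_gt(m1$P[center, center], 0)
})

test_that("displacement map of isotropic walkers is isotropic", {
  set.seed(36)
  n <- 150
  frames <- 0:8
  x <- matrix(0, length(frames), n)
  y <- matrix(0, length(frames), n)
  x[1, ] <- runif(n, 0, 120)
  y[1, ] <- runif(n, 0, 120)
  for (f in 2:length(frames)) {
    x[f, ] <- x[f - 1, ] + rnorm(n, sd = 2)
    y[f, ] <- y[f - 1, ] + rnorm(n, sd = 2)
  }
  tr <- track_table(data.frame(
    track_id = rep(seq_len(n), each = length(frames)),
    frame = rep(frames, n), t = rep(frames, n) / 12,
    x = as.vector(apply(x, 2, identity)),
    y = as.vector(apply(y, 2, identity))))
  m <- neighbor_displacement_map(tr, r_thresh = 12, dt = 8 / 12,
                                 bin_width = 2, extent = 12)
  # fold the map into quadrant counts; isotropy -> equal expected mass
  xs <- m$x
  qmass <- c(sum(m$P[xs > 0, xs > 0]), sum(m$P[xs > 0, xs < 0]),
             sum(m$P[xs < 0, xs > 0]), sum(m$P[xs < 0, xs < 0]))
  test <- chisq.test(qmass * 1000)
  expect_gt(test$p.value, 0.01)
})

test_that("track gap filling interpolates short gaps only", {
  tr <- track_table(data.frame(
    track_id = c(1, 1, 1, 2, 2),
    frame = c(0, 1, 4, 0, 6),
    t = c(0, 1, 4, 0, 6) / 12,
    x = c(0, 1, 4, 10, 16), y = c(0, 0, 0, 5, 5)))
  filled <- fill_track_gaps(tr, max_gap = 3)
  t1 <- filled[filled$track_id == 1, ]
  expect_equal(t1$frame, 0:4)
  expect_equal(t1$x, 0:4) # linear interpolation
  # 5-frame gap in track 2 stays open
  expect_equal(nrow(filled[filled$track_id == 2, ]), 2)
})
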