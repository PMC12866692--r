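test_that("center-of-mass velocity is the mean over usable windows", {
  f <- mat_field(matrix(c(1, 3), 1), matrix(0, 1, 2))
  expect_equal(center_of_mass_velocity(f, 1), c(2, 0))

  # uniform field returns its own vector
  fu <- mat_field(matrix(2.5, 3, 3), matrix(-1, 3, 3))
  expect_equal(center_of_mass_velocity(fu, 1), c(2.5, -1))

  # invalid windows excluded from the mean
  vx <- matrix(c(1, 100, 1, 100), 2)
  vy <- matrix(0, 2, 2)
  f2 <- velocity_field(0, c(10, 20), c(10, 20),
                       array(vx, c(1, 2, 2)), array(vy, c(1, 2, 2)),
                       valid = array(c(TRUE, FALSE, TRUE, FALSE),
                                     c(1, 2, 2)))
  expect_equal(center_of_mass_velocity(f2, 1), c(1, 0))

  # no usable windows -> NA marker, not zero
  f3 <- velocity_field(0, c(10, 20), c(10, 20),
                       array(NA_real_, c(1, 2, 2)),
                       array(NA_real_, c(1, 2, 2)))
  expect_true(all(is.na(center_of_mass_velocity(f3, 1))))
})

test_that("V_rms matches closed forms and drift correction", {
  fu <- mat_field(matrix(3, 4, 4), matrix(4, 4, 4)) # speed 5 everywhere
  expect_equal(root_mean_square_velocity(fu, 1), 5)
  expect_equal(root_mean_square_velocity(fu, 1, drift_corrected = TRUE), 0)

  f <- mat_field(matrix(c(1, -1), 1), matrix(0, 1, 2))
  expect_equal(root_mean_square_velocity(f, 1), 1)
  expect_equal(center_of_mass_velocity(f, 1), c(0, 0))

  # Gaussian components sigma per axis -> V_rms ~ sigma * sqrt(2)
  set.seed(11)
  sigma <- 4
  n <- 100
  fg <- mat_field(matrix(rnorm(n^2, sd = sigma), n),
                  matrix(rnorm(n^2, sd = sigma), n))
  expect_equal(root_mean_square_velocity(fg, 1), sigma * sqrt(2),
               tolerance = 0.02)
})

test_that("order parameter limits and closed forms hold", {
  fu <- mat_field(matrix(7, 8, 8), matrix(0, 8, 8))
  expect_equal(order_parameter(fu, 1), 1, tolerance = 1e-12)
  expect_equal(order_parameter(fu, 1, variant = "magnitude_ratio"), 1,
               tolerance = 1e-12)

  f0 <- mat_field(matrix(c(1, -1), 1), matrix(0, 1, 2))
  expect_equal(order_parameter(f0, 1), 0)

  # two orthogonal unit vectors: |(0.5, 0.5)| / 1 = sqrt(2)/2
  fo <- mat_field(matrix(c(1, 0), 1), matrix(c(0, 1), 1))
  expect_equal(order_parameter(fo, 1), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(order_parameter(fo, 1, variant = "magnitude_ratio"),
               sqrt(2) / 2, tolerance = 1e-12)

  # all-zero speeds -> undefined marker
  fz <- mat_field(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(is.na(order_parameter(fz, 1)))
})

test_that("order parameter is bounded and variants are ordered", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:20, 1)
    speeds <- exp(rnorm(n^2, sd = 2)) # heavy-tailed speeds
    ang <- runif(n^2, 0, 2 * pi)
    f <- mat_field(matrix(speeds * cos(ang), n),
                   matrix(speeds * sin(ang), n))
    p1 <- order_parameter(f, 1)
    p2 <- order_parameter(f, 1, variant = "magnitude_ratio")
    expect_gte(p1, 0)
    expect_lte(p1, 1 + 1e-12)
    expect_lte(p2, 1 + 1e-12)
    # RMS normalization is the stricter of the two (Cauchy-Schwarz)
    expect_lte(p1, p2 + 1e-12)
    # |V_cm| <= V_rms always
    expect_lte(sqrt(sum(center_of_mass_velocity(f, 1)^2)),
               root_mean_square_velocity(f, 1) + 1e-12)
  }
})

test_that("window enumeration order does not affect frame statistics", {
  set.seed(8)
  vx <- matrix(rnorm(36), 6)
  vy <- matrix(rnorm(36), 6)
  f <- mat_field(vx, vy)
  # permuting rows and columns (a relabeling of windows) leaves the
  # scalar observables unchanged
  pr <- sample(6)
  pc <- sample(6)
  fp <- mat_field(vx[pr, pc], vy[pr, pc])
  expect_equal(order_parameter(fp, 1), order_parameter(f, 1))
  expect_equal(root_mean_square_velocity(fp, 1),
               root_mean_square_velocity(f, 1))
  expect_equal(center_of_mass_velocity(fp, 1),
               center_of_mass_velocity(f, 1))
})

test_that("track-based RMS center-of-mass velocity matches displacements", {
  # all cells displace 1 um in one 0.1 h frame -> 10 um/h
  tr <- track_table(data.frame(
    track_id = rep(1:4, each = 2), frame = rep(0:1, 4),
    t = rep(c(0, 0.1), 4),
    x = as.vector(rbind(c(0, 10, 20, 30), c(1, 11, 21, 31))),
    y = rep(c(5, 5), 4)))
  expect_equal(track_rms_cm_velocity(tr, 0), 10)

  static <- track_table(data.frame(
    track_id = rep(1:3, each = 2), frame = rep(0:1, 3),
    t = rep(c(0, 0.1), 3), x = rep(1:3, each = 2),
    y = rep(4:6, each = 2)))
  expect_equal(track_rms_cm_velocity(static, 0), 0)
})

test_that("framecut mean respects the half-open window and skips NA", {
  t <- 0:3
  expect_equal(framecut_mean(t, rep(7, 4), 0, 4), 7)
  expect_equal(framecut_mean(t, c(1, 2, 3, 4), 2, 4), 3.5)
  expect_equal(framecut_mean(t, c(1, NA, 3, 4), 0, 4), 8 / 3)
  expect_error(framecut_mean(t, 1:4, 10, 20), "overlap")
  expect_error(framecut_mean(t, 1:4, 3, 2), "t0 < t1")
})

test_that("motility peak detection finds maxima with earliest-tie rule", {
  t <- seq(0, 20, by = 0.5)
  tri <- pmax(0, 10 - abs(t - 10)) # unimodal, peak at t = 10
  pk <- find_motility_peak(t, tri, smoothing_window = 1)
  expect_equal(pk$t_peak, 10)
  expect_equal(pk$window, c(5, 15))

  plateau <- c(0, 1, 5, 5, 5, 5, 1, 0)
  pk2 <- find_motility_peak(seq_along(plateau), plateau,
                            smoothing_window = 1, window_length = 2)
  expect_equal(pk2$t_peak, 3) # earliest of the tied maxima

  # noisy series: median location error within the smoothing span
  set.seed(3)
  t3 <- seq(0, 40, by = 0.25)
  base <- exp(-((t3 - 18) / 6)^2)
  errs <- vapply(1:25, function(i) {
    noisy <- base + rnorm(length(t3), sd = 0.08)
    abs(find_motility_peak(t3, noisy, smoothing_window = 9)$t_peak - 18)
  }, numeric(1))
  expect_lte(median(errs), 9 * 0.25)
})
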