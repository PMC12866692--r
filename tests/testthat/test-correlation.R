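test_that("FFT correlation equals the direct circular-shift oracle", {
  set.seed(21)
  for (dims in list(c(4, 4), c(8, 8), c(8, 12), c(16, 16), c(5, 7))) {
    vx <- matrix(rnorm(prod(dims)), dims[1])
    vy <- matrix(rnorm(prod(dims)), dims[1])
    cm <- spatial_correlation_2d(vx, vy, drift_correct = FALSE)
    oracle <- direct_corr2d(vx, vy)
    expect_lt(max(abs(cm - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("white-noise correlation vanishes away from zero lag", {
  set.seed(22)
  n <- 64
  acc <- matrix(0, n, n)
  n_frames <- 20
  for (i in seq_len(n_frames)) {
    acc <- acc + spatial_correlation_2d(matrix(rnorm(n^2), n),
                                        matrix(rnorm(n^2), n),
                                        drift_correct = FALSE)
  }
  cm <- acc / n_frames
  off <- cm / cm[1, 1]
  off[1, 1] <- NA
  # mean-zero with sd ~ 1/sqrt(n_frames * N): allow 5 sigma on the max
  expect_lt(max(abs(off), na.rm = TRUE), 5 / sqrt(n_frames * 2))
  expect_lt(abs(mean(off, na.rm = TRUE)), 0.001)
})

test_that("uniform field with drift correction is flagged degenerate", {
  f <- mat_field(matrix(5, 8, 8), matrix(2, 8, 8), spacing = 10)
  curve <- correlation_over_window(f)
  expect_false(attr(curve, "fit")$converged)
  expect_false(attr(curve, "converged"))
})

test_that("too many invalid vectors are rejected, fewer are inpainted", {
  set.seed(23)
  vx <- matrix(rnorm(64), 8)
  vy <- matrix(rnorm(64), 8)
  bad <- matrix(TRUE, 8, 8)
  bad[sample(64, 25)] <- FALSE # 39% invalid
  expect_error(spatial_correlation_2d(vx, vy, valid = bad), "invalid")
  ok <- matrix(TRUE, 8, 8)
  ok[sample(64, 10)] <- FALSE # 16% invalid: inpainted
  cm <- spatial_correlation_2d(vx, vy, valid = ok)
  expect_true(all(is.finite(cm)))
  expect_equal(attr(cm, "inpainted_fraction"), 10 / 64)
})

test_that("radial average reduces closed-form maps correctly", {
  # zero-lag bin holds exactly the zero-lag value
  set.seed(24)
  vx <- matrix(rnorm(144), 12)
  vy <- matrix(rnorm(144), 12)
  cm <- spatial_correlation_2d(vx, vy, drift_correct = FALSE)
  cur <- radial_average(cm, bin_width = 1, spacing_x = 1)
  expect_equal(cur$C[cur$r == 0], cm[1, 1])

  # isotropic Gaussian map: radial profile matches the generator
  n <- 32
  kx <- c(0:(n / 2), -(n / 2 - 1):-1)
  r2 <- outer(kx^2, kx^2, "+")
  gmap <- exp(-r2 / (2 * 5^2))
  cur2 <- radial_average(matrix(gmap[1:n, 1:n], n), bin_width = 1)
  sel <- cur2$r <= 10
  expect_equal(cur2$C[sel], exp(-cur2$r[sel]^2 / 50), tolerance = 0.02)

  # pure-x sinusoid: radial average equals the analytic angular mean
  # of cos(k x) over the annulus (Bessel J0), tested at small r
  lam <- 16
  cmap <- matrix(cos(2 * pi * kx / lam), n, n, byrow = TRUE)
  cur3 <- radial_average(cmap, bin_width = 1)
  k <- 2 * pi / lam
  sel3 <- cur3$r > 0 & cur3$r <= 6
  expect_lt(max(abs(cur3$C[sel3] - besselJ(k * cur3$r[sel3], 0))), 0.06)
})

test_that("mean-variance correction removes a constant drift", {
  set.seed(25)
  n <- 24
  g <- grf_exponential(n, L = 4)
  drift <- c(3, -2)
  cm_fluct <- spatial_correlation_2d(g$vx, g$vy, drift_correct = FALSE)
  cm_drift <- spatial_correlation_2d(g$vx + drift[1], g$vy + drift[2],
                                     drift_correct = FALSE)
  cur_f <- correct_and_normalize(
    radial_average(cm_fluct, 1),
    mean_v = c(mean(g$vx), mean(g$vy)))
  cur_d <- correct_and_normalize(
    radial_average(cm_drift, 1),
    mean_v = c(mean(g$vx) + drift[1], mean(g$vy) + drift[2]))
  expect_equal(cur_d$C_corrected, cur_f$C_corrected, tolerance = 1e-8)
  expect_equal(cur_d$C_normalized[1], 1)

  # drift-corrected field: correction is the identity
  cur0 <- correct_and_normalize(radial_average(cm_fluct, 1),
                                mean_v = c(0, 0))
  expect_equal(cur0$C_corrected, cur0$C)
})

test_that("stretched-exponential fit recovers exact and noisy curves", {
  r <- seq(0, 100, by = 2)
  fit <- fit_correlation_length(r, exp(-r / 20), r_max = 100)
  expect_true(fit$converged)
  expect_equal(fit$L_corr, 20, tolerance = 1e-6)
  expect_equal(fit$gamma, 1, tolerance = 1e-6)

  # noisy stretched exponential: median recovery within stated bands
  set.seed(26)
  Ls <- numeric(20)
  gs <- numeric(20)
  for (i in 1:20) {
    cn <- exp(-(r / 35)^0.7) + rnorm(length(r), sd = 0.01)
    f <- fit_correlation_length(r, cn, r_max = 100)
    Ls[i] <- f$L_corr
    gs[i] <- f$gamma
  }
  expect_lt(abs(median(Ls) - 35) / 35, 0.15)
  expect_lt(abs(median(gs) - 0.7), 0.15)

  # fit failure surfaces as a not-converged record
  bad <- fit_correlation_length(c(0, 1, 2), c(1, 0.5, 0.2))
  expect_false(bad$converged)
  expect_match(bad$message, "bins")
})

test_that("correlation curve is invariant to velocity scale and rotation", {
  set.seed(27)
  n <- 16
  g <- grf_exponential(n, L = 3)
  f1 <- mat_field(g$vx, g$vy, spacing = 5)
  f2 <- mat_field(7 * g$vx, 7 * g$vy, spacing = 5)
  c1 <- correlation_over_window(f1)
  c2 <- correlation_over_window(f2)
  expect_equal(c2$C_normalized, c1$C_normalized, tolerance = 1e-10)

  # 90 degree rotation: x' = -y, y' = x and the grid rotates with it
  vx_r <- t(apply(-g$vy, 2, rev))
  vy_r <- t(apply(g$vx, 2, rev))
  f3 <- mat_field(vx_r, vy_r, spacing = 5)
  c3 <- correlation_over_window(f3)
  expect_equal(c3$C_normalized, c1$C_normalized, tolerance = 1e-8)
})

test_that("frame averaging equals single frame for identical frames", {
  set.seed(28)
  n <- 12
  g <- grf_exponential(n, L = 3)
  vx3 <- aperm(array(g$vx, c(n, n, 3)), c(3, 1, 2))
  vy3 <- aperm(array(g$vy, c(n, n, 3)), c(3, 1, 2))
  f3 <- velocity_field(times = (0:2) / 12, grid_x = (1:n) * 5,
                       grid_y = (1:n) * 5, vx = vx3, vy = vy3,
                       window_size = 5)
  f1 <- mat_field(g$vx, g$vy, spacing = 5)
  c3 <- correlation_over_window(f3)
  c1 <- correlation_over_window(f1)
  expect_equal(c3$C_normalized, c1$C_normalized, tolerance = 1e-12)
})
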