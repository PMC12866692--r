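small_cfg <- function(...) {
  defaults <- list(n_cells = 64, box_size = 75, duration = 1, seed = 5)
  args <- modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_cells = 1), "n_cells")
  expect_error(simulation_config(box_size = 10), "box_size")
  expect_error(simulation_config(dt = 1, frame_interval = 1 / 12), "dt")
  # packing fraction bounds
  expect_error(simulation_config(n_cells = 10, box_size = 200),
               "packing fraction")
  expect_error(make_regime_config("no_such_state"), "valid regimes")
})

test_that("presets carry the documented regime structure", {
  expect_lt(make_regime_config("jammed_solid")$v0, 1)
  expect_equal(make_regime_config("disordered_fluid")$J, 0)
  fs <- make_regime_config("flocking_solid")
  expect_gt(fs$k_bond, 0)
  expect_gt(fs$J, 1)
  ff <- make_regime_config("flocking_fluid")
  expect_equal(ff$k_bond, 0)
  expect_gt(ff$J, 1)
})

test_that("simulation is deterministic and respects zero propulsion", {
  cfg <- small_cfg()
  t1 <- simulate_monolayer(cfg)
  t2 <- simulate_monolayer(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  # different seed changes trajectories
  t3 <- simulate_monolayer(small_cfg(seed = 6))
  expect_false(identical(t1$x, t3$x))

  # v0 = 0, D_r = 0: only repulsive relaxation; late-time motion tiny
  cfg0 <- small_cfg(n_cells = 44, v0 = 0, D_r = 0, J = 0, duration = 2)
  tr0 <- simulate_monolayer(cfg0)
  last2 <- tr0[tr0$frame >= max(tr0$frame) - 1, ]
  v <- track_rms_cm_velocity(track_table(as.data.frame(last2)),
                             max(tr0$frame) - 1)
  expect_lt(v, 0.05)
})

test_that("pure relaxation dissipates to mechanical equilibrium", {
  # moderate packing so the energy landscape has no slow avalanche
  # cascades; the jittered lattice settles into force balance
  cfg <- small_cfg(n_cells = 44, v0 = 0, D_r = 0, J = 0, duration = 2)
  tr <- simulate_monolayer(cfg)
  frames <- sort(unique(tr$frame))
  disp <- vapply(seq_len(length(frames) - 1), function(k) {
    a <- tr[tr$frame == frames[k], ]
    b <- tr[tr$frame == frames[k + 1], ]
    sum(sqrt((b$x_unwrap - a$x_unwrap)^2 + (b$y_unwrap - a$y_unwrap)^2))
  }, numeric(1))
  # per-frame displacement decays below tolerance ...
  expect_lt(disp[length(disp)] / cfg$n_cells, 0.01)
  expect_lt(disp[length(disp)], disp[1] / 100)
  # ... and monotonically once the initial rearrangement has passed
  late <- disp[5:length(disp)]
  expect_true(all(diff(late) <= 1e-9))
})

test_that("a stiff bonded network with alignment never exchanges neighbors", {
  cfg <- small_cfg(v0 = 15, J = 6, D_r = 0, k_bond = 40, dt = 1 / 960,
                   duration = 2.5)
  tr <- simulate_monolayer(cfg)
  # after the initial alignment transient the network drifts rigidly
  late <- track_table(as.data.frame(tr[tr$t >= 1, ]))
  attr(late, "box_size") <- attr(tr, "box_size")
  ex <- neighbor_distance_curve(late, r_thresh = 13, dt_max = 1,
                                box = attr(tr, "box_size"))
  expect_true(all(abs(ex$delta_d) < cfg$cell_radius / 100))
})

test_that("alignment order decreases with rotational noise (Vicsek limit)", {
  # free Vicsek particles: no repulsion, no bonds
  psi_of <- function(Dr, seed) {
    cfg <- simulation_config(n_cells = 80, box_size = 85, v0 = 20,
                             J = 4, D_r = Dr, k_rep = 0, r_align = 25,
                             duration = 3, seed = seed)
    tr <- simulate_monolayer(cfg)
    th <- tr$theta[tr$frame >= max(tr$frame) / 2]
    sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  }
  psis <- sapply(1:10, function(s) {
    c(low = psi_of(0.2, s), mid = psi_of(2, s), high = psi_of(12, s))
  })
  expect_gt(mean(psis["low", ]), mean(psis["mid", ]))
  expect_gt(mean(psis["mid", ]), mean(psis["high", ]))
  # paired one-sided comparisons across seeds
  expect_lt(wilcox.test(psis["mid", ], psis["low", ], paired = TRUE,
                        alternative = "less")$p.value, 0.05)
  expect_lt(wilcox.test(psis["high", ], psis["mid", ], paired = TRUE,
                        alternative = "less")$p.value, 0.05)
})

test_that("rendered frames track the cells and wrap periodically", {
  # one static cell, zero noise: argmax at the same pixel every frame
  tr <- track_table(data.frame(track_id = 1, frame = 0:2, t = (0:2) / 12,
                               x = 20.5, y = 30.5))
  attr(tr, "box_size") <- 64
  stk <- render_frames(tr, pixel_size = 1, psf_sigma = 2,
                       noise_level = 0)
  pos <- t(vapply(1:3, function(k) {
    which(stk$frames[k, , ] == max(stk$frames[k, , ]), arr.ind = TRUE)[1, ]
  }, numeric(2)))
  expect_true(all(pos[, 1] == pos[1, 1]))
  expect_true(all(pos[, 2] == pos[1, 2]))

  # rigid translation by integer pixels: frames are circular shifts
  set.seed(51)
  n <- 30
  x0 <- runif(n, 0, 64)
  y0 <- runif(n, 0, 64)
  tr2 <- track_table(data.frame(
    track_id = rep(seq_len(n), each = 2), frame = rep(0:1, n),
    t = rep(0:1, n) / 12,
    x = (rep(x0, each = 2) + rep(0:1, n) * 3) %% 64,
    y = rep(y0, each = 2)))
  attr(tr2, "box_size") <- 64
  stk2 <- render_frames(tr2, pixel_size = 1, psf_sigma = 2,
                        noise_level = 0)
  expect_equal(stk2$frames[2, , ], shift_mat(stk2$frames[1, , ], 0, 3),
               tolerance = 1e-10)

  expect_error(render_frames(tr2, pixel_size = -1), "pixel_size")
})

test_that("PIV on rendered flocking stack matches track ground truth", {
  cfg <- make_regime_config("flocking_fluid", seed = 52, n_cells = 150,
                            duration = 1.5)
  tr <- simulate_monolayer(cfg)
  late_frames <- max(tr$frame) - (4:0)
  late <- track_table(as.data.frame(tr[tr$frame %in% late_frames, ]))
  attr(late, "box_size") <- attr(tr, "box_size")
  stk <- render_frames(late, pixel_size = 1, psf_sigma = 3,
                       noise_level = 20, seed = 52)
  vf <- compute_piv(stk, piv_params(window_size = 32))
  mot <- motility_time_series(vf)
  piv_speed <- mean(mot$v_rms, na.rm = TRUE)
  truth <- mean(vapply(head(late_frames, -1), function(f) {
    track_rms_cm_velocity(late, f)
  }, numeric(1)))
  expect_lt(abs(piv_speed - truth) / truth, 0.2)
})

test_that("FRAP generator reproduces its closed-form intensity curves", {
  # immobile pool only: curve stays at 1 - d after the bleach
  g0 <- simulate_frap_stack(mobile_fraction = 0, bleach_depth = 0.8,
                            background = 0, n_frames = 30, noise_sd = 0)
  roi <- list(cx = g0$truth$center[1], cy = g0$truth$center[2],
              r = g0$truth$radius_px * 0.9)
  cur0 <- normalize_recovery(g0$stack, roi, g0$truth$bleach_frame,
                             background_roi = "none")
  post <- seq(g0$truth$bleach_frame, nrow(cur0))
  expect_equal(cur0$normalized[post], rep(0.2, length(post)),
               tolerance = 1e-6)

  # fully mobile, no decay: curve returns to 1
  g1 <- simulate_frap_stack(mobile_fraction = 1, bleach_depth = 1,
                            recovery_rate = 0.02, n_frames = 200,
                            noise_sd = 0)
  roi1 <- list(cx = g1$truth$center[1], cy = g1$truth$center[2],
               r = g1$truth$radius_px * 0.9)
  cur1 <- normalize_recovery(g1$stack, roi1, g1$truth$bleach_frame,
                              background_roi = "none")
  expect_equal(tail(cur1$normalized, 1), 1, tolerance = 0.01)

  expect_error(simulate_frap_stack(bleach_frame = 100, n_frames = 50),
               "bleach_frame")
})

test_that("wetting generator obeys its growth models", {
  w <- simulate_wetting_areas(A0 = 500, growth_model = "linear",
                              params = list(g = 0.5), n_frames = 10,
                              noise = 0)
  expect_equal(wetting_curve(w)$area_normalized, 1 + 0.5 * w$t)
  w0 <- simulate_wetting_areas(A0 = 500, params = list(g = 0),
                               n_frames = 10, noise = 0)
  expect_equal(wetting_curve(w0)$area_normalized, rep(1, 10))

  # lognormal noise is mean-corrected: ensemble mean tracks the model
  set.seed(53)
  curves <- vapply(1:1000, function(s) {
    simulate_wetting_areas(A0 = 100, params = list(g = 0.2),
                           n_frames = 5, noise = 0.05, seed = s)$area
  }, numeric(5))
  expect_equal(rowMeans(curves), 100 * (1 + 0.2 * (0:4)),
               tolerance = 0.02)
  expect_error(simulate_wetting_areas(A0 = -1), "A0")
})
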