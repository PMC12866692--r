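#' Simulation configuration for the synthetic monolayer
#'
#' Parameterizes the overdamped self-propelled-particle model used to
#' generate ground-truth monolayer dynamics. Units are micrometres and
#' hours throughout, matching the velocity scales (3-30 um/h) of epithelial
#' streaming experiments.
#'
#' @param n_cells number of cells (>= 2).
#' @param box_size side of the square periodic box, um (> 4 cell radii).
#' @param cell_radius soft-disc cell radius `a`, um.
#' @param v0 mean self-propulsion speed, um/h.
#' @param v0_sd relative cell-to-cell spread of the propulsion speed
#'   (lognormal, mean-preserving; 0 disables). Motility heterogeneity is
#'   a robust feature of epithelial cells and lets an aligned flock
#'   exchange neighbors: cells moving in a common direction at different
#'   speeds slide past each other.
#' @param J alignment relaxation rate toward the local mean heading, 1/h.
#' @param D_r rotational diffusion coefficient, rad^2/h.
#' @param k_rep repulsion stiffness (force per um of overlap, with unit
#'   mobility this is 1/h).
#' @param k_bond harmonic bond stiffness; 0 disables the bond network.
#' @param r_align alignment interaction radius, um.
#' @param dt integration step, h (must divide `frame_interval`).
#' @param duration simulated time, h.
#' @param frame_interval sampling interval of the output tracks, h
#'   (default 5 min).
#' @param seed integer master seed; sub-streams for initialization and
#'   noise are derived from it.
#' @param regime_label one of `"jammed_solid"`, `"disordered_fluid"`,
#'   `"flocking_fluid"`, `"flocking_solid"`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_cells = 400, box_size = 187,
                              cell_radius = 5, v0 = 20, v0_sd = 0,
                              J = 0, D_r = 1,
                              k_rep = 25, k_bond = 0, r_align = 15,
                              dt = 1 / 120, duration = 12,
                              frame_interval = 1 / 12, seed = 1L,
                              regime_label = NA_character_) {
  abort_if(v0_sd < 0, "v0_sd must be >= 0")
  abort_if(n_cells < 2, "n_cells must be >= 2")
  abort_if(box_size <= 4 * cell_radius, "box_size must exceed 4 cell radii")
  abort_if(dt >= frame_interval, "dt must be smaller than frame_interval")
  phi <- n_cells * pi * cell_radius^2 / box_size^2
  abort_if(phi <= 0.5 || phi >= 1.2,
           sprintf("packing fraction %.2f outside (0.5, 1.2)", phi))
  record_every <- frame_interval / dt
  abort_if(abs(record_every - round(record_every)) > 1e-9,
           "frame_interval must be an integer multiple of dt")
  structure(list(n_cells = as.integer(n_cells), box_size = box_size,
                 cell_radius = cell_radius, v0 = v0, v0_sd = v0_sd,
                 J = J, D_r = D_r,
                 k_rep = k_rep, k_bond = k_bond, r_align = r_align,
                 dt = dt, duration = duration,
                 frame_interval = frame_interval, seed = as.integer(seed),
                 regime_label = regime_label),
            class = "simulation_config")
}

#' Preset configurations for the four dynamic tissue states
#'
#' Returns a documented constant parameter set per regime. Presets are
#' design constants, not fitted values: the jammed solid has negligible
#' propulsion; the disordered fluid propels fast with no alignment and
#' fast rotational diffusion; the flocking fluid adds strong alignment
#' with weak noise; the flocking solid keeps strong alignment but tethers
#' each cell to its initial contact neighbors with harmonic bonds, which
#' suppresses rearrangement while allowing the bonded network to drift
#' coherently.
#'
#' @param regime one of `"jammed_solid"`, `"disordered_fluid"`,
#'   `"flocking_fluid"`, `"flocking_solid"`.
#' @param seed integer master seed.
#' @param n_cells,duration optional overrides of the preset size.
#' @return a [simulation_config()].
#' @export
make_regime_config <- function(regime, seed = 1L, n_cells = 400,
                               duration = 12) {
  regimes <- c("jammed_solid", "disordered_fluid", "flocking_fluid",
               "flocking_solid")
  abort_if(!is.character(regime) || !(regime %in% regimes),
           paste0("unknown regime '", regime, "'; valid regimes: ",
                  paste(regimes, collapse = ", ")))
  # keep packing fraction ~0.9 as n_cells changes
  box <- sqrt(n_cells * pi * 5^2 / 0.9)
  base <- list(n_cells = n_cells, box_size = box, cell_radius = 5,
               k_rep = 25, r_align = 25, dt = 1 / 120,
               duration = duration, frame_interval = 1 / 12, seed = seed,
               regime_label = regime)
  pars <- switch(regime,
    jammed_solid     = list(v0 = 0.5, J = 1,  D_r = 1,   k_bond = 0),
    disordered_fluid = list(v0 = 20,  J = 0,  D_r = 6,   k_bond = 0),
    flocking_fluid   = list(v0 = 30,  J = 10, D_r = 1.5, k_bond = 0,
                            k_rep = 10),
    flocking_solid   = list(v0 = 20,  J = 4,  D_r = 0.4, k_bond = 30,
                            dt = 1 / 960))
  do.call(simulation_config, modifyList(base, pars))
}

init_positions <- function(config) {
  # near-triangular lattice with jitter: the mechanically stable packing
  # of soft discs (a square lattice sits on an unstable equilibrium and
  # buckles during relaxation)
  n <- config$n_cells
  box <- config$box_size
  m <- ceiling(sqrt(n / (sqrt(3) / 2)))
  n_rows <- ceiling(n / m)
  dx <- box / m
  dy <- box / n_rows
  idx <- seq_len(n) - 1L
  row <- idx %/% m
  col <- idx %% m
  gx <- (col + 0.5 + 0.5 * (row %% 2)) * dx
  gy <- (row + 0.5) * dy
  jitter <- 0.2 * config$cell_radius
  list(x = (gx + runif(n, -jitter, jitter)) %% box,
       y = (gy + runif(n, -jitter, jitter)) %% box,
       theta = runif(n, 0, 2 * pi))
}

initial_bonds <- function(x, y, box, cutoff) {
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  dx <- dx - box * round(dx / box)
  dy <- dy - box * round(dy / box)
  r <- sqrt(dx^2 + dy^2)
  pairs <- which(upper.tri(r) & r < cutoff, arr.ind = TRUE)
  list(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
       r0 = r[pairs])
}

#' Simulate a monolayer and return its track table
#'
#' Integrates the overdamped dynamics described in [simulation_config()]
#' and samples positions every `frame_interval`. Positions are stored both
#' wrapped into the periodic box (`x`, `y`) and unwrapped (`x_unwrap`,
#' `y_unwrap`) so that per-track displacement statistics are exact.
#' Identical `(config, seed)` give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return a [track_table()] with columns `track_id, frame, t, x, y,
#'   theta, x_unwrap, y_unwrap` and attributes `box_size`, `config`.
#' @export
simulate_monolayer <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_steps <- round(config$duration / config$dt)
  record_every <- as.integer(round(config$frame_interval / config$dt))
  init <- with_seed(derive_seed(config$seed, "init"),
                    init_positions(config))
  v0_vec <- if (config$v0_sd > 0) {
    with_seed(derive_seed(config$seed, "speeds"), {
      s <- sqrt(log(1 + config$v0_sd^2))
      config$v0 * exp(s * rnorm(config$n_cells) - s^2 / 2)
    })
  } else {
    rep(config$v0, config$n_cells)
  }
  noise <- with_seed(derive_seed(config$seed, "noise"),
                     matrix(rnorm(n_steps * config$n_cells),
                            nrow = n_steps))
  bonds <- if (config$k_bond > 0) {
    initial_bonds(init$x, init$y, config$box_size,
                  cutoff = 2.6 * config$cell_radius)
  } else {
    list(i = integer(0), j = integer(0), r0 = numeric(0))
  }
  res <- simulate_core(init$x, init$y, init$theta,
                       box = config$box_size, a = config$cell_radius,
                       v0 = v0_vec, J = config$J, Dr = config$D_r,
                       k_rep = config$k_rep, k_bond = config$k_bond,
                       r_align = config$r_align, mu = 1,
                       dt = config$dt, n_steps = n_steps,
                       record_every = record_every, noise = noise,
                       bond_i = bonds$i, bond_j = bonds$j,
                       bond_r0 = bonds$r0)
  n_frames <- nrow(res$x)
  n <- config$n_cells
  df <- data.frame(
    track_id = rep(seq_len(n), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = n),
    t = rep((seq_len(n_frames) - 1L) * config$frame_interval, times = n),
    x = as.vector(res$x), y = as.vector(res$y),
    theta = as.vector(res$theta),
    x_unwrap = as.vector(res$x_unwrap),
    y_unwrap = as.vector(res$y_unwrap)
  )
  out <- track_table(df)
  attr(out, "box_size") <- config$box_size
  attr(out, "config") <- config
  out
}

#' Render tracks into a synthetic fluorescence image stack
#'
#' Each cell becomes an isotropic Gaussian blob (a stand-in for a labeled
#' nucleus) at its wrapped position; Poisson shot noise and additive
#' Gaussian read noise are applied and the result clipped to the 16-bit
#' range.
#'
#' @param tracks a [track_table()].
#' @param pixel_size micrometres per pixel (> 0).
#' @param psf_sigma blob width, um.
#' @param amplitude peak intensity per cell, counts.
#' @param noise_level Gaussian read-noise SD in counts; Poisson noise is
#'   applied whenever `noise_level > 0`.
#' @param background constant background offset, counts.
#' @param box_size field of view, um; defaults to the tracks' box.
#' @param seed integer seed for the noise stream.
#' @return an [image_stack()].
#' @export
render_frames <- function(tracks, pixel_size = 1, psf_sigma = 3,
                          amplitude = 8000, noise_level = 0,
                          background = 200, box_size = NULL, seed = 1L) {
  abort_if(pixel_size <= 0, "pixel_size must be > 0")
  abort_if(nrow(tracks) == 0, "tracks must be non-empty")
  box <- box_size %||% attr(tracks, "box_size") %||%
    max(tracks$x, tracks$y)
  npx <- ceiling(box / pixel_size)
  frames <- sort(unique(tracks$frame))
  stack <- array(0, dim = c(length(frames), npx, npx))
  sig_px <- psf_sigma / pixel_size
  halfw <- max(2L, ceiling(3 * sig_px))
  kcoord <- seq(-halfw, halfw)
  frame_interval <- if (length(frames) > 1) {
    diff(sort(unique(tracks$t)))[1]
  } else {
    1 / 12
  }
  by_frame <- split(tracks, tracks$frame)
  for (k in seq_along(frames)) {
    img <- matrix(0, npx, npx)
    fr <- by_frame[[as.character(frames[k])]]
    # pixel centers at (i - 0.5) * pixel_size
    cx <- fr$x / pixel_size + 0.5
    cy <- fr$y / pixel_size + 0.5
    for (c_i in seq_len(nrow(fr))) {
      ix <- round(cx[c_i])
      iy <- round(cy[c_i])
      xs <- ix + kcoord
      ys <- iy + kcoord
      gx <- exp(-((xs - cx[c_i])^2) / (2 * sig_px^2))
      gy <- exp(-((ys - cy[c_i])^2) / (2 * sig_px^2))
      blob <- amplitude * outer(gy, gx)
      # periodic wrap of blob support
      ys_w <- ((ys - 1) %% npx) + 1
      xs_w <- ((xs - 1) %% npx) + 1
      img[ys_w, xs_w] <- img[ys_w, xs_w] + blob
    }
    stack[k, , ] <- img + background
  }
  if (noise_level > 0) {
    stack <- with_seed(derive_seed(seed, "render"), {
      shot <- array(rpois(length(stack), lambda = pmax(stack, 0)),
                    dim = dim(stack))
      shot + array(rnorm(length(stack), sd = noise_level),
                   dim = dim(stack))
    })
  }
  stack <- pmin(pmax(stack, 0), 65535)
  image_stack(stack, pixel_size = pixel_size,
              frame_interval = frame_interval)
}
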