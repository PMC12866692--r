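#' Simulate a FRAP image stack with known ground truth
#'
#' Generates a synthetic photobleaching movie: a bright field of
#' dye-loaded cells, a circular region bleached at `bleach_frame`, and a
#' recovery governed by a single-exponential mobile fraction, with
#' optional acquisition photobleaching applied to the whole field. The
#' mean intensity inside the bleached disc follows
#' \deqn{I(t) = bg + (pre - bg) [(1 - d) + d f (1 - e^{-k t})] e^{-\lambda t}}
#' for time `t` after the bleach, where `d` is the bleach depth, `f` the
#' mobile fraction, `k` the recovery rate and `lambda` the acquisition
#' bleach rate; outside the disc the intensity is
#' `(pre - bg) e^{-lambda t} + bg`.
#'
#' @param radius_px bleach-disc radius in pixels.
#' @param bleach_depth `d` in `[0, 1]`; 1 bleaches to background.
#' @param mobile_fraction `f` in `[0, 1]`.
#' @param recovery_rate `k`, per second (> 0).
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @param acquisition_bleach_rate `lambda`, per second.
#' @param background camera background, counts.
#' @param pre_intensity pre-bleach intensity, counts.
#' @param n_frames,size_px,frame_interval_s stack geometry and timing.
#' @param pixel_size micrometres per pixel.
#' @param noise_sd Gaussian noise SD, counts.
#' @param seed integer seed.
#' @return list with `stack` (an [image_stack()]; `frame_interval` is in
#'   hours) and `truth` (generator parameters plus disc center).
#' @export
simulate_frap_stack <- function(radius_px = 20, bleach_depth = 1,
                                mobile_fraction = 0.6,
                                recovery_rate = 0.01, bleach_frame = 6,
                                acquisition_bleach_rate = 0,
                                background = 100, pre_intensity = 30000,
                                n_frames = 60, size_px = 128,
                                frame_interval_s = 10, pixel_size = 1,
                                noise_sd = 0, seed = 1L) {
  abort_if(mobile_fraction < 0 || mobile_fraction > 1,
           "mobile_fraction must be in [0, 1]")
  abort_if(recovery_rate <= 0, "recovery_rate must be > 0")
  abort_if(bleach_frame < 2 || bleach_frame > n_frames,
           "bleach_frame outside the stack")
  cx <- size_px / 2 + 0.5
  cy <- size_px / 2 + 0.5
  xs <- matrix(rep(seq_len(size_px), each = size_px), size_px)
  ys <- matrix(rep(seq_len(size_px), times = size_px), size_px)
  in_disc <- (xs - cx)^2 + (ys - cy)^2 <= radius_px^2
  times_s <- (seq_len(n_frames) - 1) * frame_interval_s
  t_post <- times_s - times_s[bleach_frame]
  d <- bleach_depth
  f <- mobile_fraction
  lam <- acquisition_bleach_rate
  decay <- exp(-lam * times_s)
  out_val <- (pre_intensity - background) * decay + background
  in_val <- ifelse(
    t_post < 0,
    out_val,
    background + (pre_intensity - background) *
      ((1 - d) + d * f * (1 - exp(-recovery_rate * pmax(t_post, 0)))) *
      decay)
  frames <- array(0, dim = c(n_frames, size_px, size_px))
  for (k in seq_len(n_frames)) {
    img <- matrix(out_val[k], size_px, size_px)
    img[in_disc] <- in_val[k]
    frames[k, , ] <- img
  }
  if (noise_sd > 0) {
    frames <- frames + with_seed(derive_seed(seed, "frap"),
                                 array(rnorm(length(frames),
                                             sd = noise_sd),
                                       dim = dim(frames)))
  }
  frames <- pmin(pmax(frames, 0), 65535)
  list(stack = image_stack(frames, pixel_size = pixel_size,
                           frame_interval = frame_interval_s / 3600),
       truth = list(center = c(x = cx, y = cy), radius_px = radius_px,
                    bleach_depth = d, mobile_fraction = f,
                    recovery_rate = recovery_rate,
                    bleach_frame = bleach_frame,
                    acquisition_bleach_rate = lam,
                    background = background,
                    pre_intensity = pre_intensity,
                    times_s = times_s))
}

#' Simulate a wetting (spheroid spreading) area series
#'
#' Produces a monotone-in-expectation spreading-area time series with
#' multiplicative lognormal noise. The lognormal factor is mean-corrected
#' (`exp(sigma * z - sigma^2 / 2)`) so the expectation equals the
#' noiseless model.
#'
#' @param A0 initial spheroid area (> 0), um^2.
#' @param growth_model `"linear"` (`A0 (1 + g t)`) or `"exponential"`
#'   (`A0 exp(g t)`).
#' @param params list with growth rate `g` (per hour).
#' @param n_frames number of time points.
#' @param frame_interval hours between points.
#' @param noise lognormal sigma of the multiplicative noise.
#' @param seed integer seed.
#' @return a tibble with columns `t` (h) and `area` (um^2).
#' @export
simulate_wetting_areas <- function(A0, growth_model = c("linear",
                                                        "exponential"),
                                   params = list(g = 0.1), n_frames = 49,
                                   frame_interval = 1, noise = 0,
                                   seed = 1L) {
  abort_if(A0 <= 0, "A0 must be > 0")
  growth_model <- match.arg(growth_model)
  t <- (seq_len(n_frames) - 1) * frame_interval
  g <- params$g %||% 0.1
  base <- switch(growth_model,
                 linear = A0 * (1 + g * t),
                 exponential = A0 * exp(g * t))
  area <- if (noise > 0) {
    fac <- with_seed(derive_seed(seed, "wetting"),
                     exp(noise * rnorm(n_frames) - noise^2 / 2))
    base * fac
  } else {
    base
  }
  tibble::tibble(t = t, area = area)
}
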