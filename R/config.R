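#' Default analysis configuration
#'
#' Defaults mirror the acquisition conventions of a typical monolayer
#' streaming experiment: 50 um PIV windows with 50% overlap (about five
#' cells per interrogation window), a 5 min frame interval, a 50 um local
#' density kernel, and framecut bounds of 15-40 h for steady-state
#' summaries.
#'
#' @return a named list of configuration values.
#' @export
default_config <- function() {
  list(
    pixel_size = 0.65,          # um / px
    frame_interval = 1 / 12,    # h (5 min)
    window_size = 50,           # um, PIV interrogation window
    overlap_fraction = 0.5,
    framecut = c(15, 40),       # h
    density_radius = 50,        # um
    rdf_bin_width = 1,          # um
    peak_window = 10,           # h, correlation window around motility peak
    v_rms_low = 2,              # um/h, jammed vs fluid threshold
    l_corr_low = 14,            # um, disordered vs flocking threshold
    exchange_slope_high = 0.15, # um/h, solid vs fluid neighbor exchange
    si_sd_low = 0.25,           # shape-index SD secondary criterion
    seed = 1L
  )
}

#' Load an analysis configuration from a key-value (YAML) file
#'
#' Absent keys take the documented defaults (see [default_config()]).
#' Unknown keys trigger a warning; invalid values (wrong sign, malformed
#' ranges) are errors.
#'
#' @param path path to a YAML key-value file, or `NULL` for pure defaults.
#' @return a validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    abort_if(!file.exists(path), paste0("config file not found: ", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      warning("ignoring unknown config key(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
      user <- user[setdiff(names(user), unknown)]
    }
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (key in c("pixel_size", "frame_interval", "window_size",
                "density_radius", "rdf_bin_width", "peak_window")) {
    abort_if(!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1 ||
               cfg[[key]] <= 0,
             paste0("config: ", key, " must be a positive number"))
  }
  abort_if(cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1,
           "config: overlap_fraction must be in [0, 1)")
  fc <- cfg$framecut
  abort_if(length(fc) != 2 || !is.numeric(fc) || fc[1] >= fc[2],
           "config: framecut must be two numbers t0 < t1")
  cfg
}
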