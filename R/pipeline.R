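#' Aggregate replicate time series
#'
#' Averages several per-field-of-view (or per-seed) series at each time
#' point, matching times to the first series' time base by nearest
#' frame. Returns per-time mean, SD (`ddof = 1`) and n, mirroring the
#' convention of averaging motility time courses across fields of view
#' before framecut statistics.
#'
#' @param series_list list of data.frames with columns `t` and
#'   `value_col`.
#' @param value_col name of the value column.
#' @return tibble with `t, mean, sd, n`.
#' @export
aggregate_replicates <- function(series_list, value_col = "value") {
  abort_if(length(series_list) < 1, "need at least one series")
  base_t <- series_list[[1]]$t
  span <- range(base_t)
  vals <- matrix(NA_real_, nrow = length(base_t),
                 ncol = length(series_list))
  step <- if (length(base_t) > 1) median(diff(base_t)) else 1
  for (k in seq_along(series_list)) {
    s <- series_list[[k]]
    abort_if(min(s$t) > span[2] + step / 2 ||
               max(s$t) < span[1] - step / 2,
             "series time bases are disjoint")
    idx <- vapply(base_t, function(tt) which.min(abs(s$t - tt)),
                  integer(1))
    near <- abs(s$t[idx] - base_t) <= step / 2 + 1e-9
    vals[near, k] <- s[[value_col]][idx[near]]
  }
  tibble::tibble(
    t = base_t,
    mean = rowMeans(vals, na.rm = TRUE),
    sd = apply(vals, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) sd(v) else NA_real_
    }),
    n = apply(vals, 1, function(v) sum(is.finite(v))))
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(list(ok = TRUE, value = fun()),
                  error = function(e) list(ok = FALSE,
                                           value = conditionMessage(e)))
  report$stages[[name]] <- if (res$ok) "ok" else {
    paste0("failed: ", res$value)
  }
  report[[name]] <- if (res$ok) res$value else NULL
  report
}

#' Run the full monolayer analysis pipeline
#'
#' Orchestrates: PIV (if images are given) or track coarse-graining,
#' kinematics, motility-peak window, velocity correlation and its
#' stretched-exponential fit, RDF neighbor threshold and exchange curve,
#' local density statistics, shape statistics (if masks are given), and
#' the four-state classification. Partial inputs produce partial reports
#' with explicit gaps; a failed stage marks its section and downstream
#' dependents are skipped.
#'
#' @param tracks optional [track_table()].
#' @param stack optional [image_stack()] for PIV.
#' @param masks optional [label_mask_stack()] for shape statistics.
#' @param config configuration list (see [load_config()]).
#' @param box_size field-of-view side, um; defaults to the tracks'
#'   `box_size` attribute.
#' @param periodic treat the box as periodic (synthetic data).
#' @param output_dir optional directory; when given, tidy CSV/JSON
#'   outputs and a run manifest are written there.
#' @return a `pipeline_report` list with per-stage results, a `metrics`
#'   bundle, and the `state` call.
#' @export
run_pipeline <- function(tracks = NULL, stack = NULL, masks = NULL,
                         config = default_config(), box_size = NULL,
                         periodic = !is.null(attr(tracks, "box_size")),
                         output_dir = NULL) {
  abort_if(is.null(tracks) && is.null(stack),
           "need tracks and/or an image stack")
  report <- list(stages = list(), config = config)
  box <- box_size %||% attr(tracks, "box_size") %||%
    (if (!is.null(stack)) dim(stack$frames)[3] * stack$pixel_size else
       max(tracks$x, tracks$y))

  # velocity field: PIV from images when available, else coarse-grained
  # track velocities
  report <- run_stage(report, "field", function() {
    if (!is.null(stack)) {
      compute_piv(stack, piv_params(
        window_size = config$window_size,
        overlap_fraction = config$overlap_fraction))
    } else {
      field_from_tracks(tracks, box,
                        window_size = min(config$window_size, box / 12))
    }
  })
  field <- report$field

  report <- run_stage(report, "motility", function() {
    abort_if(is.null(field), "no velocity field")
    motility_time_series(field, tracks = tracks)
  })
  mot <- report$motility

  fc <- config$framecut
  if (!is.null(mot)) {
    # clip the framecut to the series support; fall back to the last
    # half of short runs
    if (fc[1] >= max(mot$t)) {
      fc <- c(max(mot$t) / 2, max(mot$t) + 1e-9)
    } else {
      fc <- c(fc[1], min(fc[2], max(mot$t) + 1e-9))
    }
  }

  report <- run_stage(report, "framecut_summary", function() {
    abort_if(is.null(mot), "no motility series")
    list(framecut = fc,
         v_rms = framecut_mean(mot$t, mot$v_rms, fc[1], fc[2]),
         v_rms_cm = if ("v_rms_cm" %in% names(mot)) {
           framecut_mean(mot$t, mot$v_rms_cm, fc[1], fc[2])
         } else {
           NA_real_
         },
         psi = framecut_mean(mot$t, mot$psi, fc[1], fc[2]))
  })

  report <- run_stage(report, "correlation", function() {
    abort_if(is.null(field), "no velocity field")
    pk <- find_motility_peak(mot$t, mot$v_rms,
                             window_length = config$peak_window)
    frames <- which(field$times >= pk$window[1] &
                      field$times <= pk$window[2])
    correlation_over_window(field, frames = frames)
  })

  report <- run_stage(report, "neighbors", function() {
    abort_if(is.null(tracks), "no tracks (not computed: tracking-based)")
    # average the RDF over a few frames spread through the run before
    # locating its first valley (single-frame RDFs of evolving packings
    # are noisy)
    frames_all <- sort(unique(tracks$frame))
    picks <- unique(frames_all[pmax(1, round(seq(0.3, 0.9,
                                                 length.out = 5) *
                                               length(frames_all)))])
    rdfs <- lapply(picks, function(f) {
      fr <- tracks[tracks$frame == f, ]
      radial_distribution(fr$x, fr$y, box,
                          bin_width = config$rdf_bin_width,
                          periodic = periodic)
    })
    rdf <- rdfs[[1]]
    rdf$g <- rowMeans(vapply(rdfs, function(d) d$g,
                             numeric(nrow(rdf))))
    r_thresh <- first_valley_threshold(rdf)
    dt_max <- min(2, max(tracks$t) / 4)
    ex <- neighbor_distance_curve(tracks, r_thresh, dt_max,
                                  box = if (periodic) box else NULL,
                                  stride = 2L)
    list(rdf = rdf, r_thresh = r_thresh, exchange = ex,
         slope = attr(ex, "slope"))
  })

  report <- run_stage(report, "density", function() {
    abort_if(is.null(tracks), "no tracks (not computed: tracking-based)")
    # density statistics on a frame subsample (temporal SD needs far
    # fewer frames than the kinematics)
    frames_all <- sort(unique(tracks$frame))
    sub <- tracks[tracks$frame %in%
                    frames_all[seq(1, length(frames_all), by = 4)], ]
    sub <- track_table(as.data.frame(sub))
    fld <- local_density(sub, box, R = config$density_radius,
                         periodic = periodic,
                         edge_correction = !periodic)
    list(field = fld, fluctuation_map = density_fluctuation_map(fld))
  })

  report <- run_stage(report, "shape", function() {
    abort_if(is.null(masks), "no masks (not computed: no segmentation)")
    shp <- shapes_from_mask(masks)
    shape_distribution_stats(shp)
  })

  fit <- attr(report$correlation, "fit")
  metrics <- list(
    v_rms = report$framecut_summary$v_rms %||% NA_real_,
    v_rms_cm = report$framecut_summary$v_rms_cm %||% NA_real_,
    psi = report$framecut_summary$psi %||% NA_real_,
    l_corr = if (!is.null(fit) && isTRUE(fit$converged)) {
      fit$L_corr
    } else {
      NA_real_
    },
    gamma = if (!is.null(fit)) fit$gamma else NA_real_,
    exchange_slope = report$neighbors$slope %||% NA_real_,
    si_sd = report$shape$sd_si %||% NA_real_)
  report$metrics <- metrics

  report <- run_stage(report, "state", function() {
    classify_state(metrics, state_thresholds(
      v_rms_low = config$v_rms_low,
      l_corr_low = config$l_corr_low,
      exchange_slope_high = config$exchange_slope_high,
      si_sd_low = config$si_sd_low))
  })

  report$ok <- !any(grepl("^failed", unlist(report$stages)))
  class(report) <- "pipeline_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-18s %s\n", nm, x$stages[[nm]]))
  }
  if (!is.null(x$state)) {
    cat(sprintf("  state: %s\n", x$state$state))
  }
  invisible(x)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$motility)) {
    write.csv(report$motility, file.path(output_dir, "motility.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$correlation)) {
    write.csv(as.data.frame(report$correlation),
              file.path(output_dir, "corr.csv"), row.names = FALSE)
  }
  if (!is.null(report$neighbors)) {
    write.csv(as.data.frame(report$neighbors$exchange),
              file.path(output_dir, "exchange.csv"), row.names = FALSE)
  }
  summary <- list(
    stages = report$stages,
    metrics = report$metrics,
    state = if (!is.null(report$state)) {
      list(state = report$state$state,
           rationale = report$state$rationale)
    } else {
      NULL
    },
    config = report$config)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("flockmetrics")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = report$config,
    stages = report$stages)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(output_dir)
}
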