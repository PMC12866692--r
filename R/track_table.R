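#' Construct and validate a track table
#'
#' The track table is the common currency of all tracking-based analyses:
#' one row per cell detection, identified by `(track_id, frame)`, with
#' positions in micrometres and time in hours. Optional columns carry the
#' heading angle, ellipse shape descriptors, fluorescence channel and (for
#' synthetic data with periodic boundaries) unwrapped coordinates.
#'
#' @param df a data.frame with at least `track_id`, `frame`, `t`, `x`, `y`.
#' @return a `track_table` (a tibble subclass).
#' @examples
#' tt <- track_table(data.frame(
#'   track_id = c(1, 1, 2, 2), frame = c(0, 1, 0, 1),
#'   t = c(0, 1 / 12, 0, 1 / 12), x = c(0, 1, 5, 5), y = c(0, 0, 2, 3)
#' ))
#' @export
track_table <- function(df) {
  required <- c("track_id", "frame", "t", "x", "y")
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0,
           paste0("track table is missing column(s): ",
                  paste(missing, collapse = ", ")))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  key <- paste(df$track_id, df$frame)
  dup <- which(duplicated(key))
  abort_if(length(dup) > 0,
           sprintf("duplicated (track_id, frame) pair: track %s, frame %s",
                   df$track_id[dup[1]], df$frame[dup[1]]))
  abort_if(!all(is.finite(df$x)) || !all(is.finite(df$y)),
           "track table contains non-finite coordinates")
  bad_t <- tapply(df$t, df$track_id, function(tt) any(diff(tt) <= 0))
  abort_if(any(unlist(bad_t), na.rm = TRUE),
           "time must be strictly increasing within each track")
  out <- tibble::as_tibble(df)
  class(out) <- c("track_table", class(out))
  out
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d detections, %d tracks, %d frames\n",
              nrow(x), length(unique(x$track_id)),
              length(unique(x$frame))))
  NextMethod()
}

#' Read a cell track table from CSV
#'
#' Two dialects are supported. `"native"` expects columns
#' `track_id, frame` and positions either already calibrated
#' (`x_um, y_um`, optionally `t_h`) or in pixels (`x, y`), in which case
#' `pixel_size` converts them to micrometres and `frame_interval` sets the
#' time base. `"trackmate"` reads TrackMate spot/track CSV exports
#' (`TRACK_ID, FRAME, POSITION_X, POSITION_Y, ...`), skipping the
#' extra human-readable header rows by detection (TrackMate exports repeat
#' the header as names/units rows), not by a fixed count.
#'
#' @param path path to a CSV file.
#' @param dialect `"native"` or `"trackmate"`.
#' @param pixel_size micrometres per pixel, used when positions are in
#'   pixels. TrackMate exports positions in calibrated units already, so it
#'   is ignored for that dialect unless `force_pixel_units = TRUE`.
#' @param frame_interval hours between frames, used when no time column is
#'   present.
#' @param force_pixel_units treat TrackMate positions as pixels.
#' @return a [track_table()].
#' @export
read_tracks_csv <- function(path, dialect = c("native", "trackmate"),
                            pixel_size = 1, frame_interval = 1 / 12,
                            force_pixel_units = FALSE) {
  dialect <- match.arg(dialect)
  abort_if(!file.exists(path), paste0("file not found: ", path))
  if (dialect == "native") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    abort_if(!all(c("track_id", "frame") %in% names(df)),
             "native track CSV must have columns track_id, frame")
    if (all(c("x_um", "y_um") %in% names(df))) {
      x <- df$x_um
      y <- df$y_um
    } else if (all(c("x", "y") %in% names(df))) {
      x <- df$x * pixel_size
      y <- df$y * pixel_size
    } else {
      stop("native track CSV must have columns x_um/y_um or x/y",
           call. = FALSE)
    }
    t <- if ("t_h" %in% names(df)) df$t_h else df$frame * frame_interval
    out <- data.frame(track_id = df$track_id, frame = df$frame,
                      t = t, x = x, y = y)
    for (extra in c("theta_rad", "area_um2", "perimeter_um", "major_um",
                    "minor_um", "channel", "x_unwrap", "y_unwrap")) {
      if (extra %in% names(df)) {
        nm <- sub("_(rad|um2|um)$", "", extra)
        out[[nm]] <- df[[extra]]
      }
    }
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
    need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
    missing <- setdiff(need, names(raw))
    abort_if(length(missing) > 0,
             paste0("TrackMate CSV is missing column(s): ",
                    paste(missing, collapse = ", ")))
    # drop the repeated-name / units / shortname header rows: keep rows whose
    # FRAME parses as a number
    keep <- suppressWarnings(!is.na(as.numeric(raw$FRAME)))
    raw <- raw[keep, , drop = FALSE]
    scale <- if (force_pixel_units) pixel_size else 1
    out <- data.frame(
      track_id = as.integer(as.numeric(raw$TRACK_ID)),
      frame = as.integer(as.numeric(raw$FRAME)),
      x = as.numeric(raw$POSITION_X) * scale,
      y = as.numeric(raw$POSITION_Y) * scale
    )
    out$t <- if ("POSITION_T" %in% names(raw)) {
      as.numeric(raw$POSITION_T)
    } else {
      out$frame * frame_interval
    }
    if ("ELLIPSE_ASPECTRATIO" %in% names(raw)) {
      out$aspect_ratio <- as.numeric(raw$ELLIPSE_ASPECTRATIO)
    }
    if ("AREA" %in% names(raw)) out$area <- as.numeric(raw$AREA)
  }
  track_table(out)
}

#' Write a track table to CSV
#'
#' Columns are written with unit-suffixed names (`t_h`, `x_um`, `y_um`,
#' `theta_rad`, ...) so the file round-trips through
#' [read_tracks_csv()] with `dialect = "native"`.
#'
#' @param tracks a [track_table()].
#' @param path output path.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    t_h = tracks$t, x_um = tracks$x, y_um = tracks$y)
  ren <- c(theta = "theta_rad", area = "area_um2",
           perimeter = "perimeter_um", major = "major_um",
           minor = "minor_um", channel = "channel",
           x_unwrap = "x_unwrap", y_unwrap = "y_unwrap")
  for (nm in names(ren)) {
    if (nm %in% names(tracks)) out[[ren[[nm]]]] <- tracks[[nm]]
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
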