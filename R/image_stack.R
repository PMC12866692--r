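#' Construct an image stack
#'
#' A thin container for time-lapse microscopy data: a `T x H x W` array of
#' intensities in the 16-bit range, plus the physical calibration needed by
#' downstream analysis (pixel size in micrometres, frame interval in hours).
#'
#' @param frames numeric array `T x H x W`, values in `[0, 65535]`.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval hours between frames (> 0).
#' @return an `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  abort_if(length(dim(frames)) != 3, "frames must be a T x H x W array")
  abort_if(dim(frames)[1] < 1, "stack must contain at least one frame")
  abort_if(pixel_size <= 0, "pixel_size must be > 0")
  abort_if(frame_interval <= 0, "frame_interval must be > 0")
  rng <- range(frames)
  abort_if(rng[1] < 0 || rng[2] > 65535,
           "intensities must lie in [0, 65535]")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frames of %d x %d px (%.3g um/px, %.3g h/frame)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Read / write an image stack as multi-page TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFF. Physical calibration
#' (pixel size, frame interval) is written to a small JSON sidecar file
#' (`<path>.meta.json`); on read, explicit arguments take precedence,
#' then the sidecar, then defaults (1 um/px, 5 min/frame).
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @param pixel_size,frame_interval calibration overrides on read.
#' @return `read_image_stack` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(i) {
    stack$frames[i, , , drop = TRUE] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size,
         frame_interval_h = stack$frame_interval),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size = NULL,
                             frame_interval = NULL) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    frame_interval <- frame_interval %||% meta$frame_interval_h
  }
  pixel_size <- pixel_size %||% 1
  frame_interval <- frame_interval %||% (1 / 12)
  h <- nrow(pages[[1]])
  w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[i, , ] <- round(pg * 65535)
  }
  image_stack(frames, pixel_size, frame_interval)
}

#' Construct a label mask stack
#'
#' Integer-labeled segmentation masks (`0` = background), as produced by
#' external segmentation tools.
#'
#' @param frames integer array `T x H x W` of labels.
#' @param pixel_size micrometres per pixel.
#' @export
label_mask_stack <- function(frames, pixel_size) {
  if (length(dim(frames)) == 2) {
    frames <- array(frames, dim = c(1, dim(frames)))
  }
  abort_if(length(dim(frames)) != 3, "frames must be T x H x W")
  abort_if(any(frames < 0), "labels must be non-negative")
  abort_if(pixel_size <= 0, "pixel_size must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size),
            class = "label_mask_stack")
}

#' Read a label mask stack from a 16-bit TIFF
#' @param path file path.
#' @param pixel_size micrometres per pixel.
#' @export
read_label_masks <- function(path, pixel_size = 1) {
  stk <- read_image_stack(path, pixel_size = pixel_size,
                          frame_interval = 1)
  label_mask_stack(array(as.integer(round(stk$frames)),
                         dim = dim(stk$frames)),
                   pixel_size = pixel_size)
}
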