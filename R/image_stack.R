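## Two-channel image stacks: container, pixel/µm conversion, TIFF I/O.

#' Construct an image stack
#'
#' @param frames list of arrays `[ny, nx, n_channels]` (row = y, increasing
#'   upward in the µm frame; column = x), non-negative intensities.
#' @param pixel_size_um pixel size, µm/px (> 0).
#' @param frame_interval_s frame interval, s.
#' @param channels channel labels, default `c("membrane", "bacteria")`.
#' @param origin_um (x, y) of the lower-left corner of pixel (1, 1), µm.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s = 1,
                        channels = c("membrane", "bacteria"),
                        origin_um = c(0, 0)) {
  stopifnot(length(frames) >= 1, pixel_size_um > 0)
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("negative intensities")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, channels = channels,
                 origin_um = origin_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames, %dx%d px, %d channel(s) [%s], %.3g um/px, dt = %g s\n",
              length(x$frames), d[1], d[2], d[3],
              paste(x$channels, collapse = ", "),
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Pixel/micrometre coordinate conversion
#'
#' Pixel centres map to µm as `x_um = origin_x + (col - 0.5) * pixel_size`
#' (and likewise row to y); the conversions round-trip exactly.
#'
#' @param stack an [image_stack()].
#' @param col,row pixel coordinates (possibly fractional).
#' @param x_um,y_um µm coordinates.
#' @return `px_to_um`: data.frame `x_um`, `y_um`; `um_to_px`: data.frame
#'   `col`, `row`.
#' @export
px_to_um <- function(stack, col, row) {
  data.frame(x_um = stack$origin_um[1] + (col - 0.5) * stack$pixel_size_um,
             y_um = stack$origin_um[2] + (row - 0.5) * stack$pixel_size_um)
}

#' @rdname px_to_um
#' @export
um_to_px <- function(stack, x_um, y_um) {
  data.frame(col = (x_um - stack$origin_um[1]) / stack$pixel_size_um + 0.5,
             row = (y_um - stack$origin_um[2]) / stack$pixel_size_um + 0.5)
}

#' Write / read an image stack as multi-page TIFF plus JSON metadata
#'
#' Pages are ordered frame-major then channel
#' (`frame1/ch1, frame1/ch2, frame2/ch1, ...`); intensities are stored as
#' 32-bit float on a [0, 1] scale (divided by the 8-bit-style scale factor
#' 255, recorded in the metadata). Acquisition metadata (pixel size, frame
#' interval, channels, origin) goes to a `<path>.json` sidecar.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_image_stack`: `path`, invisibly. `read_image_stack`: the
#'   stack.
#' @export
write_image_stack <- function(stack, path) {
  scale <- max(255, max(vapply(stack$frames, max, numeric(1))))
  pages <- unlist(lapply(stack$frames, function(f)
    lapply(seq_len(dim(f)[3]), function(ch) f[, , ch] / scale)),
    recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         channels = stack$channels, origin_um = stack$origin_um,
         intensity_scale = scale,
         n_frames = length(stack$frames)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  nfr <- length(pages) / nch
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  frames <- lapply(seq_len(nfr), function(i) {
    a <- array(0, c(dim(pages[[1]]), nch))
    for (ch in seq_len(nch)) a[, , ch] <- pages[[(i - 1) * nch + ch]] * scale
    a
  })
  image_stack(frames, meta$pixel_size_um, meta$frame_interval_s,
              meta$channels, meta$origin_um)
}
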