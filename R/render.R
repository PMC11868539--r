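## Rendering synthetic two-channel micrographs of a foam with encapsulated
## swimmers: membrane dye channel (edges, brightest at junction overlaps) and
## bacteria channel (swimmer footprints), with optional shot + read noise.

#' Render a two-channel micrograph of a foam network with swimmers
#'
#' The membrane channel rasterizes all edges at sub-pixel sampling and blurs
#' with a Gaussian point-spread function; junctions come out brightest because
#' three edges overlap within the PSF. The bacteria channel rasterizes swimmer
#' footprints as disks. With `noise_level = 0` the image is deterministic;
#' otherwise per-pixel Poisson shot noise plus Gaussian read noise of standard
#' deviation `noise_level` (8-bit-style intensity units) is applied.
#'
#' @param net a [foam_network()].
#' @param swimmers optional data.frame/matrix with columns `x_um`, `y_um` of
#'   swimmer positions (e.g. one frame of [simulate_abp()] tracks).
#' @param pixel_size_um µm per pixel, default 0.5.
#' @param psf_sigma_um PSF standard deviation, µm, default 0.6. A warning is
#'   given when `pixel_size_um >= 2 * psf_sigma_um` (undersampled).
#' @param noise_level read-noise SD (intensity units); 0 for noise-free.
#' @param seed RNG seed for the noise.
#' @param swimmer_radius_um footprint radius, default `sqrt(2/pi)` (2 µm²).
#' @param membrane_peak,bacteria_peak nominal peak intensities, default
#'   200 and 180 (8-bit-style scale).
#' @param margin_um field-of-view margin around the network, default 5.
#' @param fov optional fixed field of view, a list with `origin_um` (x0, y0)
#'   and `nx`, `ny` (px) — use this when rendering a timelapse so all frames
#'   share one coordinate frame.
#' @return an [image_stack()] with one frame and attributes
#'   `vertices_px` (ground-truth vertex positions, data.frame id/col/row) and
#'   `bacteria_threshold` (rendering-level binarization threshold).
#' @export
render_micrograph <- function(net, swimmers = NULL, pixel_size_um = 0.5,
                              psf_sigma_um = 0.6, noise_level = 0, seed = 1L,
                              swimmer_radius_um = sqrt(2 / pi),
                              membrane_peak = 200, bacteria_peak = 180,
                              margin_um = 5, fov = NULL) {
  if (pixel_size_um >= 2 * psf_sigma_um)
    warning("pixel size >= PSF support: image will be undersampled")
  v <- net$vertices
  if (is.null(fov)) {
    x0 <- min(v$x_um) - margin_um; y0 <- min(v$y_um) - margin_um
    nx <- ceiling((max(v$x_um) - min(v$x_um) + 2 * margin_um) / pixel_size_um)
    ny <- ceiling((max(v$y_um) - min(v$y_um) + 2 * margin_um) / pixel_size_um)
  } else {
    x0 <- fov$origin_um[1]; y0 <- fov$origin_um[2]
    nx <- fov$nx; ny <- fov$ny
  }

  mem <- matrix(0, ny, nx)
  step <- pixel_size_um / 4
  for (r in seq_len(nrow(net$edges))) {
    p1 <- drop(vertex_xy(net, net$edges[r, 1]))
    p2 <- drop(vertex_xy(net, net$edges[r, 2]))
    len <- sqrt(sum((p2 - p1)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / step)))
    cols <- pmin(nx, pmax(1, ceiling((p1[1] + ts * (p2[1] - p1[1]) - x0) / pixel_size_um)))
    rows <- pmin(ny, pmax(1, ceiling((p1[2] + ts * (p2[2] - p1[2]) - y0) / pixel_size_um)))
    idx <- (cols - 1L) * ny + rows
    acc <- tabulate(idx, nbins = ny * nx)
    mem <- mem + matrix(acc, ny, nx)
  }
  mem <- gaussian_blur(mem, psf_sigma_um / pixel_size_um)
  if (max(mem) > 0) mem <- mem * (membrane_peak / max(mem))

  bac <- matrix(0, ny, nx)
  if (!is.null(swimmers) && nrow(swimmers) > 0) {
    rad_px <- swimmer_radius_um / pixel_size_um
    for (si in seq_len(nrow(swimmers))) {
      cc <- (swimmers[si, "x_um"] - x0) / pixel_size_um + 0.5
      rr <- (swimmers[si, "y_um"] - y0) / pixel_size_um + 0.5
      cr <- max(1, floor(cc - rad_px)):min(nx, ceiling(cc + rad_px))
      rw <- max(1, floor(rr - rad_px)):min(ny, ceiling(rr + rad_px))
      for (j in cr) for (i in rw)
        if ((j - cc)^2 + (i - rr)^2 <= rad_px^2) bac[i, j] <- bacteria_peak
    }
    bac <- gaussian_blur(bac, 0.5 * psf_sigma_um / pixel_size_um)
  }
  thr <- bacteria_peak / 2

  if (noise_level > 0) {
    set.seed(seed)
    mem <- matrix(rpois(length(mem), mem), ny, nx) +
      matrix(rnorm(length(mem), 0, noise_level), ny, nx)
    bac <- matrix(rpois(length(bac), bac), ny, nx) +
      matrix(rnorm(length(bac), 0, noise_level), ny, nx)
    mem[mem < 0] <- 0; bac[bac < 0] <- 0
  }

  st <- image_stack(list(simplify2array(list(mem, bac))), pixel_size_um,
                    frame_interval_s = 1, channels = c("membrane", "bacteria"),
                    origin_um = c(x0, y0))
  gt <- um_to_px(st, v$x_um, v$y_um)
  attr(st, "vertices_px") <- data.frame(id = v$id, col = gt$col, row = gt$row)
  attr(st, "bacteria_threshold") <- thr
  st
}

# separable Gaussian blur (matrix rows = y); sigma in pixels. Tiny negative
# ringing from the truncated kernel is clamped to zero.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  img <- EBImage::gblur(EBImage::Image(m), sigma = sigma)
  out <- EBImage::imageData(img)
  out[out < 0] <- 0
  out
}

#' Compartment polygons in pixel coordinates
#'
#' @param net a [foam_network()].
#' @param stack an [image_stack()] rendered from `net`.
#' @return list of two-column (col, row) matrices, one per compartment.
#' @export
compartment_polygons_px <- function(net, stack) {
  lapply(seq_along(net$compartments), function(i) {
    poly <- compartment_polygon(net, i)
    p <- um_to_px(stack, poly[, 1], poly[, 2])
    cbind(col = p$col, row = p$row)
  })
}
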