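## Vertex detection, max-intensity tracking and track quality control.

#' Detect candidate junction positions in a membrane frame
#'
#' Local maxima of the Gaussian-smoothed membrane channel, above an adaptive
#' threshold (a fixed fraction of the smoothed dynamic range above the
#' median, so detections are invariant to global intensity scaling), with
#' non-maximum suppression at `min_separation_um`.
#'
#' @param frame 2D matrix (membrane channel).
#' @param pixel_size_um µm per pixel.
#' @param min_separation_um minimum distance between detections, µm.
#' @param smooth_sigma_px Gaussian smoothing sigma in px (default 1).
#' @param threshold_frac adaptive threshold: median + `threshold_frac` times
#'   (max - median) of the smoothed frame (default 0.3).
#' @return data.frame with `col`, `row` (px, sub-pixel centroid-refined) and
#'   `intensity`; empty for a uniform frame.
#' @export
detect_vertices <- function(frame, pixel_size_um, min_separation_um = 5,
                            smooth_sigma_px = 1, threshold_frac = 0.3) {
  sm <- gaussian_blur(frame, smooth_sigma_px)
  rng <- max(sm) - median(sm)
  if (rng <= 0) return(data.frame(col = numeric(0), row = numeric(0),
                                  intensity = numeric(0)))
  thr <- median(sm) + threshold_frac * rng
  rad <- max(1L, round(min_separation_um / pixel_size_um / 2))
  mx <- max_filter(sm, rad)
  hit <- which(sm >= mx & sm > thr, arr.ind = TRUE)
  if (!nrow(hit)) return(data.frame(col = numeric(0), row = numeric(0),
                                    intensity = numeric(0)))
  # greedy non-maximum suppression by decreasing intensity
  o <- order(sm[hit], decreasing = TRUE)
  hit <- hit[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hit))
  minsep_px <- min_separation_um / pixel_size_um
  for (i in seq_len(nrow(hit))) {
    if (!keep[i]) next
    if (i < nrow(hit)) {
      j <- (i + 1):nrow(hit)
      d2 <- (hit[j, 1] - hit[i, 1])^2 + (hit[j, 2] - hit[i, 2])^2
      keep[j][d2 < minsep_px^2] <- FALSE
    }
  }
  hit <- hit[keep, , drop = FALSE]
  ref <- t(apply(hit, 1, function(h) centroid_refine(sm, h[1], h[2])))
  data.frame(col = ref[, 2], row = ref[, 1], intensity = sm[hit])
}

# grayscale max filter with a (2r+1) square structuring element
max_filter <- function(m, r) {
  img <- EBImage::dilate(EBImage::Image(m),
                         EBImage::makeBrush(2 * r + 1, shape = "box"))
  EBImage::imageData(img)
}

# 3x3 intensity-weighted centroid around an integer peak
centroid_refine <- function(m, row, col) {
  rs <- max(1, row - 1):min(nrow(m), row + 1)
  cs <- max(1, col - 1):min(ncol(m), col + 1)
  w <- m[rs, cs, drop = FALSE]
  w <- w - min(w)
  if (sum(w) == 0) return(c(row, col))
  c(sum(outer(rs, rep(1, length(cs))) * w) / sum(w),
    sum(outer(rep(1, length(rs)), cs) * w) / sum(w))
}

#' Track a junction by per-frame maximum intensity in a ROI
#'
#' Mirrors max-intensity tracking of an isolated, smoothed junction image:
#' per frame the brightest pixel of the smoothed ROI is the vertex position.
#' Frames whose ROI maximum falls more than `threshold_tolerance` intensity
#' units (8-bit-style scale) below the ROI's overall maximum across frames
#' are flagged invalid.
#'
#' @param stack an [image_stack()] with a membrane channel.
#' @param roi integer vector `c(row_min, row_max, col_min, col_max)` (px).
#' @param threshold_tolerance intensity offset for the validity flag,
#'   default 50.
#' @param smooth_sigma_px Gaussian smoothing sigma, px (default 1).
#' @param refine `"none"` (raw argmax, compatibility default) or
#'   `"centroid"` (3x3 sub-pixel refinement).
#' @param vertex_id id recorded in the output track.
#' @return track data.frame (`vertex_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `valid`).
#' @export
track_vertex <- function(stack, roi, threshold_tolerance = 50,
                         smooth_sigma_px = 1, refine = c("none", "centroid"),
                         vertex_id = 1L) {
  refine <- match.arg(refine)
  ch <- match("membrane", stack$channels)
  if (is.na(ch)) ch <- 1L
  rows <- roi[1]:roi[2]; cols <- roi[3]:roi[4]
  n <- length(stack$frames)
  pk <- matrix(NA_real_, n, 3)   # row, col, max intensity
  for (i in seq_len(n)) {
    sub <- stack$frames[[i]][rows, cols, ch, drop = TRUE]
    sm <- gaussian_blur(sub, smooth_sigma_px)
    w <- which.max(sm)
    r <- ((w - 1) %% nrow(sm)) + 1; cc <- ((w - 1) %/% nrow(sm)) + 1
    if (refine == "centroid") {
      rc <- centroid_refine(sm, r, cc); r <- rc[1]; cc <- rc[2]
    }
    pk[i, ] <- c(r + roi[1] - 1, cc + roi[3] - 1, max(sm))
  }
  if (all(pk[, 3] <= 0)) stop("ROI is dark in all frames: empty track")
  valid <- pk[, 3] >= (max(pk[, 3]) - threshold_tolerance)
  um <- px_to_um(stack, pk[, 2], pk[, 1])
  data.frame(vertex_id = vertex_id, frame = seq_len(n),
             t_s = (seq_len(n) - 1) * stack$frame_interval_s,
             x_um = um$x_um, y_um = um$y_um, valid = valid)
}

#' Quality-control vertex tracks
#'
#' Removes tracks showing signs of defective tracking: any frame-to-frame
#' jump above `max_jump_um`, or more than `max_invalid_frac` invalid frames.
#'
#' @param tracks long-format track table (`vertex_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `valid`).
#' @param max_jump_um jump threshold, µm (Inf disables the jump rule).
#' @param max_invalid_frac maximum tolerated invalid-frame fraction
#'   (default 0.2).
#' @return list with `tracks` (the retained rows) and `report` (data.frame
#'   `vertex_id`, `removed`, `reason`).
#' @export
qc_tracks <- function(tracks, max_jump_um = 10, max_invalid_frac = 0.2) {
  per <- split(tracks, tracks$vertex_id)
  rep_rows <- lapply(per, function(d) {
    d <- d[order(d$frame), ]
    jump <- if (nrow(d) > 1)
      max(sqrt(diff(d$x_um)^2 + diff(d$y_um)^2), na.rm = TRUE) else 0
    frac_inv <- mean(!d$valid)
    reason <- c(if (is.finite(max_jump_um) && jump > max_jump_um) "jump",
                if (frac_inv > max_invalid_frac) "invalid-frames")
    data.frame(vertex_id = d$vertex_id[1],
               removed = length(reason) > 0,
               reason = if (length(reason)) paste(reason, collapse = "+")
                        else "", stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  keep_ids <- report$vertex_id[!report$removed]
  list(tracks = tracks[tracks$vertex_id %in% keep_ids, ], report = report)
}

#' Estimate bacterial occupancy per compartment from a bacteria frame
#'
#' Binarizes the bacteria channel (Otsu threshold by default, or a fixed
#' threshold) and counts the foreground fraction of pixels inside each
#' compartment polygon:
#' \eqn{\Phi_n} = foreground pixels / total pixels in the polygon.
#'
#' @param frame 2D matrix (bacteria channel).
#' @param polygons_px list of (col, row) polygon matrices (see
#'   [compartment_polygons_px()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (intensity units) for
#'   `method = "fixed"`.
#' @return data.frame with `compartment`, `phi`, `n_pixels`; `phi` is NA
#'   (flagged) for polygons with no interior pixels.
#' @export
estimate_occupancy <- function(frame, polygons_px,
                               method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    threshold
  } else {
    mx <- max(frame)
    if (mx == 0) Inf else EBImage::otsu(EBImage::Image(frame / mx)) * mx
  }
  bin <- frame > thr
  ny <- nrow(frame); nx <- ncol(frame)
  centers <- cbind(rep(seq_len(nx), each = ny), rep(seq_len(ny), nx)) # col,row
  rows <- lapply(seq_along(polygons_px), function(i) {
    poly <- polygons_px[[i]]
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), centers)
    npx <- sum(inside)
    phi <- if (npx == 0) NA_real_ else {
      idx <- centers[inside, , drop = FALSE]
      mean(bin[(idx[, 1] - 1) * ny + idx[, 2]])
    }
    data.frame(compartment = i, phi = phi, n_pixels = npx)
  })
  do.call(rbind, rows)
}
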