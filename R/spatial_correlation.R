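## Spatial structure of vertex fluctuations: pairwise displacement
## correlation versus separation, correlation length, hotspot maps.

#' Displacement cross-correlation versus vertex separation
#'
#' For every pair of tracked vertices, the zero-lag Pearson correlation of
#' the block-re-centred radial displacement series, binned by the mean pair
#' separation. A null band is estimated per bin by circular-shift permutation
#' of one series of each pair.
#'
#' @param tracks long-format track table (common clock).
#' @param bin_width_um distance bin width, µm (default 10).
#' @param block_s re-centring block duration, s (default 60).
#' @param min_common_frames pairs with fewer common valid frames are skipped
#'   (default 30).
#' @param n_permutations circular shifts for the null band (default 200; 0
#'   disables).
#' @param seed RNG seed for the permutation shifts.
#' @return object of class `correlation_curve`: data.frame with `d_um` (bin
#'   centre), `correlation` (bin mean), `n_pairs`, `null_hi` (95th percentile
#'   of the permuted bin means); attributes `bin_width_um`,
#'   `nn_distance_um` (mean nearest-neighbour vertex distance).
#' @export
displacement_cross_correlation <- function(tracks, bin_width_um = 10,
                                           block_s = 60,
                                           min_common_frames = 30,
                                           n_permutations = 200, seed = 1L) {
  per <- split(tracks, tracks$vertex_id)
  if (length(per) < 2) stop("need at least two tracks")
  set.seed(seed)
  series <- lapply(per, function(d) {
    b <- block_series(d, block_s)
    data.frame(t_s = b$t_s, r = sqrt(b$dx_um^2 + b$dy_um^2))
  })
  centers <- t(vapply(per, function(d)
    c(mean(d$x_um), mean(d$y_um)), numeric(2)))
  ids <- names(per)
  pairs <- utils::combn(length(per), 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    m <- merge(series[[i]], series[[j]], by = "t_s")
    if (nrow(m) < min_common_frames) next
    dist_ij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (sd(m$r.x) == 0 || sd(m$r.y) == 0) next  # constant series: undefined
    cc <- cor(m$r.x, m$r.y)
    perm <- if (n_permutations > 0) {
      sh <- sample(seq_len(nrow(m) - 1), min(n_permutations, nrow(m) - 1))
      vapply(sh, function(s)
        cor(m$r.x, m$r.y[c((s + 1):nrow(m), 1:s)]), numeric(1))
    } else numeric(0)
    rows[[k]] <- list(d = dist_ij, c = cc, perm = perm)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no pair had enough common frames")
  d_all <- vapply(rows, `[[`, numeric(1), "d")
  bins <- floor(d_all / bin_width_um)
  curve <- do.call(rbind, lapply(sort(unique(bins)), function(bn) {
    sel <- bins == bn
    permmeans <- if (n_permutations > 0) {
      pm <- sapply(rows[sel], `[[`, "perm")
      if (is.matrix(pm)) rowMeans(pm) else mean(pm)
    } else NA_real_
    data.frame(d_um = (bn + 0.5) * bin_width_um,
               correlation = mean(vapply(rows[sel], `[[`, numeric(1), "c")),
               n_pairs = sum(sel),
               null_hi = if (all(is.na(permmeans))) NA_real_
                         else quantile(permmeans, 0.95, names = FALSE))
  }))
  nnd <- mean(vapply(seq_len(nrow(centers)), function(i)
    min(sqrt(rowSums((centers[-i, , drop = FALSE] -
                        matrix(centers[i, ], nrow(centers) - 1, 2,
                               byrow = TRUE))^2))), numeric(1)))
  structure(curve, class = c("correlation_curve", "data.frame"),
            bin_width_um = bin_width_um, nn_distance_um = nnd)
}

#' Correlation length of vertex motion
#'
#' The first distance at which the baseline-subtracted bin-mean correlation
#' falls below a significance threshold (the permutation null band if
#' available, otherwise `baseline + min_excess`), with linear interpolation
#' between bins. A curve that is never significant gives 0 ("none"); a curve
#' still significant at the largest distance is censored at it.
#'
#' @param curve a `correlation_curve` (or data.frame with `d_um`,
#'   `correlation`, optional `null_hi`).
#' @param baseline large-distance baseline; default the mean correlation of
#'   the outer half of the bins.
#' @param min_excess fallback threshold above baseline (default 0.05).
#' @return list with `lcorr_um` and `flag` (`"ok"`, `"none"`,
#'   `"censored"`).
#' @export
correlation_length <- function(curve, baseline = NULL, min_excess = 0.05) {
  curve <- curve[is.finite(curve$correlation), , drop = FALSE]
  stopifnot(nrow(curve) >= 3)
  if (is.null(baseline))
    baseline <- mean(curve$correlation[curve$d_um >= median(curve$d_um)])
  thr <- if (!is.null(curve$null_hi) && !all(is.na(curve$null_hi)))
    pmax(curve$null_hi, baseline + min_excess) else baseline + min_excess
  excess <- curve$correlation - thr
  if (excess[1] <= 0) return(list(lcorr_um = 0, flag = "none"))
  below <- which(excess <= 0)
  if (!length(below)) return(list(lcorr_um = max(curve$d_um), flag = "censored"))
  k <- below[1]
  # linear interpolation of the crossing between bins k-1 and k
  d0 <- curve$d_um[k - 1]; d1 <- curve$d_um[k]
  e0 <- excess[k - 1]; e1 <- excess[k]
  list(lcorr_um = d0 + e0 / (e0 - e1) * (d1 - d0), flag = "ok")
}

#' Per-window maximum vertex displacement map
#'
#' For each vertex and each time window (default 60 s), the maximum
#' displacement from the window-mean position — the "hotspot" statistic
#' locating transient collective excitations.
#'
#' @param tracks long-format track table.
#' @param window_s window duration, s (default 60). Use the full track
#'   duration for a single global window.
#' @return long-format data.frame: `vertex_id`, `window`, `t_mid_s`, `x_um`,
#'   `y_um` (mean position in window), `max_disp_um`.
#' @export
hotspot_map <- function(tracks, window_s = 60) {
  per <- split(tracks, tracks$vertex_id)
  out <- do.call(rbind, lapply(per, function(d) {
    if (!is.null(d$valid)) d <- d[d$valid, ]
    w <- floor((d$t_s - min(tracks$t_s)) / window_s)
    do.call(rbind, lapply(split(d, w), function(b) {
      mx <- mean(b$x_um); my <- mean(b$y_um)
      data.frame(vertex_id = b$vertex_id[1],
                 window = floor((b$t_s[1] - min(tracks$t_s)) / window_s) + 1L,
                 t_mid_s = mean(range(b$t_s)),
                 x_um = mx, y_um = my,
                 max_disp_um = max(sqrt((b$x_um - mx)^2 + (b$y_um - my)^2)))
    }))
  }))
  rownames(out) <- NULL
  out
}
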