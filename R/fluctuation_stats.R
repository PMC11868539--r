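## Blocked fluctuation statistics, Welch spectra and effective-temperature
## fits.

#' Partition a track into re-centred time blocks
#'
#' Tracking drift over long timescales is suppressed by confining statistics
#' to consecutive blocks (default 60 s) and re-centring each block on its own
#' mean position. The incomplete trailing block is dropped and invalid frames
#' are excluded.
#'
#' @param track track data.frame (`t_s`, `x_um`, `y_um`, optional `valid`).
#' @param block_s block duration, s (default 60).
#' @return data.frame with `block`, `t_s`, `dx_um`, `dy_um` (displacement
#'   from the block mean); attribute `block_s`.
#' @export
block_series <- function(track, block_s = 60) {
  d <- track[order(track$t_s), ]
  if (!is.null(d$valid)) d <- d[d$valid, ]
  span <- max(d$t_s) - min(d$t_s)
  if (span + 1e-9 < block_s) stop("track shorter than one block")
  blk <- floor((d$t_s - min(d$t_s)) / block_s)
  nfull <- floor((span + median(diff(d$t_s))) / block_s)
  d <- d[blk < nfull, ]
  blk <- blk[blk < nfull]
  out <- do.call(rbind, lapply(split(d, blk), function(b)
    data.frame(block = floor((b$t_s[1] - min(d$t_s)) / block_s) + 1L,
               t_s = b$t_s,
               dx_um = b$x_um - mean(b$x_um),
               dy_um = b$y_um - mean(b$y_um))))
  rownames(out) <- NULL
  attr(out, "block_s") <- block_s
  out
}

#' Blocked vertex displacement statistics
#'
#' Two summary statistics of a blocked track: the maximum over blocks of the
#' per-block 2D positional SD (the characteristic fluctuation amplitude of a
#' vertex), and the mean radial distance from the block centre (the average
#' displacement statistic used against occupancy).
#'
#' @param blocked output of [block_series()].
#' @return list with `max_block_sd_um`, `mean_distance_um` and the per-block
#'   SDs `block_sd_um`.
#' @export
vertex_displacement_stats <- function(blocked) {
  r2 <- blocked$dx_um^2 + blocked$dy_um^2
  per_block <- vapply(split(r2, blocked$block), function(v) sqrt(mean(v)),
                      numeric(1))
  list(max_block_sd_um = if (length(per_block)) max(per_block) else 0,
       mean_distance_um = mean(sqrt(r2)),
       block_sd_um = per_block)
}

#' Edge-length deviations from the blocked mean
#'
#' Edge length L(t) between two tracked junctions, re-centred per 60-s block
#' (\eqn{L - \bar L}); all deviations are pooled and their SD reported.
#' Blocks with fewer than `min_frames` common valid frames are skipped.
#'
#' @param track1,track2 endpoint track data.frames (common clock).
#' @param block_s block duration, s.
#' @param min_frames minimum common valid frames per block (default 10).
#' @return list with `deviation_um` (pooled \eqn{L - \bar L} samples),
#'   `sd_um`, `n_blocks`.
#' @export
edge_deviation <- function(track1, track2, block_s = 60, min_frames = 10) {
  m <- merge(track1, track2, by = "t_s", suffixes = c("_1", "_2"))
  if (!is.null(m$valid_1)) m <- m[m$valid_1 & m$valid_2, ]
  L <- sqrt((m$x_um_1 - m$x_um_2)^2 + (m$y_um_1 - m$y_um_2)^2)
  blk <- floor((m$t_s - min(m$t_s)) / block_s)
  dev <- unlist(lapply(split(L, blk), function(l) {
    if (length(l) < min_frames) return(NULL)
    l - mean(l)
  }), use.names = FALSE)
  if (is.null(dev)) dev <- numeric(0)
  list(deviation_um = dev, sd_um = if (length(dev)) sd(dev) else NA_real_,
       n_blocks = sum(vapply(split(L, blk), length, integer(1)) >= min_frames))
}

#' Welch power spectral density estimate
#'
#' One-sided Welch periodogram: Hann-windowed, linearly detrended,
#' 50%-overlapping segments, density-normalized so that the integral of the
#' PSD over frequency equals the signal variance (Parseval).
#'
#' @param x numeric series (µm), uniformly sampled.
#' @param fs sampling frequency, Hz.
#' @param nperseg segment length; default the full series (one segment).
#' @param detrend remove a linear trend per segment (default TRUE)?
#' @return data.frame with `f_hz` and `psd` (input units squared per Hz, DC
#'   excluded); attributes `fs`, `nperseg`, `n_segments`.
#' @export
estimate_psd <- function(x, fs, nperseg = length(x), detrend = TRUE) {
  n <- length(x)
  if (anyNA(x)) stop("PSD estimation requires gap-free, uniform sampling")
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  acc <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1)]
    if (detrend) seg <- stats::lm.fit(cbind(1, seq_len(nperseg)), seg)$residuals
    X <- fft(w * seg)
    acc <- acc + Mod(X[seq_len(floor(nperseg / 2) + 1)])^2
  }
  pxx <- acc / length(starts) * 2 / (fs * sum(w^2))
  # one-sided: DC and (for even n) Nyquist are not doubled
  pxx[1] <- pxx[1] / 2
  if (nperseg %% 2 == 0) pxx[length(pxx)] <- pxx[length(pxx)] / 2
  f <- (seq_along(pxx) - 1) * fs / nperseg
  out <- data.frame(f_hz = f[-1], psd = pxx[-1])
  attr(out, "fs") <- fs
  attr(out, "nperseg") <- nperseg
  attr(out, "n_segments") <- length(starts)
  out
}

#' Average spectra over repeats
#'
#' @param psds list of [estimate_psd()] outputs on identical frequency grids.
#' @return a single averaged PSD data.frame.
#' @export
average_psds <- function(psds) {
  f <- psds[[1]]$f_hz
  for (p in psds) stopifnot(isTRUE(all.equal(p$f_hz, f)))
  out <- data.frame(f_hz = f,
                    psd = rowMeans(sapply(psds, function(p) p$psd)))
  attr(out, "n_averaged") <- length(psds)
  out
}

# analytic one-sided OU spectrum in m^2/Hz
ou_psd_model <- function(f_hz, b_Nsm, f0_hz, teff_K) {
  4 * kB * teff_K / b_Nsm / ((2 * pi)^2 * (f_hz^2 + f0_hz^2))
}

#' Fit the effective-temperature vertex fluctuation spectrum
#'
#' Least squares in log-log space of the overdamped-harmonic (OU) one-sided
#' spectrum
#' \deqn{S(f) = \frac{4 k_B T_{eff}/b}{(2\pi)^2 (f^2 + f_0^2)}}
#' to a measured PSD. A single spectrum only constrains the ratio
#' \eqn{T_{eff}/b} together with \eqn{f_0}; the drag and the effective
#' temperature are separable either by fixing \eqn{T_{eff} = T} (`mode =
#' "passive"`, heat-killed condition) or by supplying a known drag (`mode =
#' "active"`). Use [fit_psd_paired()] to fit an active/passive pair jointly
#' with shared \eqn{(b, f_0)}.
#'
#' @param psd data.frame `f_hz`, `psd` in µm²/Hz (as from [estimate_psd()]
#'   on µm tracks).
#' @param T_K ambient temperature, K.
#' @param mode `"passive"` (Teff = T, fits b and f0) or `"active"` (fits
#'   Teff and f0 at a given drag `b`).
#' @param b drag (N·s/m), required for `mode = "active"`.
#' @param f_min drop frequencies below this from the fit (window/detrend
#'   bias); default twice the lowest available frequency.
#' @param f_max drop frequencies above this (discrete-sampling/aliasing bias
#'   near Nyquist); default 0.4 times the highest available frequency.
#' @return list of class `psd_fit` with `b_Nsm`, `f0_hz`, `teff_ratio`,
#'   `residual` (RMS log10 residual), `f_range_hz`, `mode`.
#' @export
fit_psd <- function(psd, T_K = 298, mode = c("passive", "active"), b = NULL,
                    f_min = NULL, f_max = NULL) {
  mode <- match.arg(mode)
  if (is.null(f_min)) f_min <- 2 * min(psd$f_hz)
  if (is.null(f_max)) f_max <- 0.4 * max(psd$f_hz)
  d <- psd[psd$f_hz >= f_min & psd$f_hz <= f_max & psd$psd > 0, ]
  if (nrow(d) < 5) stop("too few frequency bins to fit")
  s_m2 <- d$psd * 1e-12               # um^2/Hz -> m^2/Hz
  logS <- log10(s_m2)
  # initial values: high-frequency amplitude C = S f^2 -> 4 kB Teff/(b (2pi)^2)
  hi <- d$f_hz >= quantile(d$f_hz, 0.5)
  C0 <- median(s_m2[hi] * d$f_hz[hi]^2)
  f0_0 <- max(min(d$f_hz) / 2, 1e-6)
  obj <- function(par) {
    if (mode == "passive") {
      bb <- 10^par[1]; f0 <- 10^par[2]; te <- T_K
    } else {
      bb <- b; f0 <- 10^par[2]; te <- T_K * 10^par[1]
    }
    sum((logS - log10(ou_psd_model(d$f_hz, bb, f0, te)))^2)
  }
  start <- if (mode == "passive")
    c(log10(4 * kB * T_K / ((2 * pi)^2 * C0)), log10(f0_0))
  else c(0, log10(f0_0))
  if (mode == "active" && is.null(b))
    stop("active mode needs the drag b (e.g. from a passive fit)")
  opt <- nlminb(start, obj)
  if (mode == "passive") {
    b_fit <- 10^opt$par[1]; teff_ratio <- 1
  } else {
    b_fit <- b; teff_ratio <- 10^opt$par[1]
  }
  structure(list(b_Nsm = b_fit, f0_hz = 10^opt$par[2],
                 teff_ratio = teff_ratio,
                 residual = sqrt(opt$objective / nrow(d)),
                 f_range_hz = range(d$f_hz), mode = mode,
                 converged = opt$convergence == 0),
            class = "psd_fit")
}

#' Joint active/passive spectrum fit with shared drag and corner frequency
#'
#' Fits the OU spectrum to an active and a heat-killed (passive) PSD
#' simultaneously: both share \eqn{(b, f_0)}, the passive spectrum has
#' \eqn{T_{eff} = T}, and the active spectrum has a free \eqn{T_{eff}}. This
#' resolves the amplitude degeneracy of a single active spectrum and returns
#' both the drag and the effective temperature ratio.
#'
#' @param psd_active,psd_passive PSD data.frames in µm²/Hz.
#' @param T_K ambient temperature, K.
#' @param f_min,f_max frequency cutoffs as in [fit_psd()].
#' @return list of class `psd_fit` with `b_Nsm`, `f0_hz`, `teff_ratio`,
#'   `residual`, `mode = "paired"`.
#' @export
fit_psd_paired <- function(psd_active, psd_passive, T_K = 298, f_min = NULL,
                           f_max = NULL) {
  if (is.null(f_min)) f_min <- 2 * min(psd_active$f_hz)
  if (is.null(f_max)) f_max <- 0.4 * max(psd_active$f_hz)
  da <- psd_active[psd_active$f_hz >= f_min & psd_active$f_hz <= f_max &
                     psd_active$psd > 0, ]
  dp <- psd_passive[psd_passive$f_hz >= f_min & psd_passive$f_hz <= f_max &
                      psd_passive$psd > 0, ]
  la <- log10(da$psd * 1e-12); lp <- log10(dp$psd * 1e-12)
  hi <- dp$f_hz >= quantile(dp$f_hz, 0.5)
  C0 <- median(dp$psd[hi] * 1e-12 * dp$f_hz[hi]^2)
  start <- c(log10(4 * kB * T_K / ((2 * pi)^2 * C0)),
             log10(max(min(da$f_hz) / 2, 1e-6)), log10(3))
  obj <- function(par) {
    bb <- 10^par[1]; f0 <- 10^par[2]; tr <- 10^par[3]
    sum((la - log10(ou_psd_model(da$f_hz, bb, f0, T_K * tr)))^2) +
      sum((lp - log10(ou_psd_model(dp$f_hz, bb, f0, T_K)))^2)
  }
  opt <- nlminb(start, obj)
  structure(list(b_Nsm = 10^opt$par[1], f0_hz = 10^opt$par[2],
                 teff_ratio = 10^opt$par[3],
                 residual = sqrt(opt$objective / (nrow(da) + nrow(dp))),
                 f_range_hz = range(da$f_hz), mode = "paired",
                 converged = opt$convergence == 0),
            class = "psd_fit")
}

#' @export
print.psd_fit <- function(x, ...) {
  cat(sprintf("<psd_fit %s> b = %.3g uNs/m, f0 = %.3g Hz, Teff/T = %.3g (rms log10 resid %.3g)\n",
              x$mode, x$b_Nsm * 1e6, x$f0_hz, x$teff_ratio, x$residual))
  invisible(x)
}

#' Effective tension from edge-length fluctuations
#'
#' Equipartition of a tense edge: \eqn{\gamma_e = k_B T / \sigma} with
#' \eqn{\sigma} the variance of the edge length (m²).
#'
#' @param sigma_m2 edge-length variance, m².
#' @param T_K temperature, K (default 298).
#' @return effective tension \eqn{\gamma_e}, N/m.
#' @export
effective_tension <- function(sigma_m2, T_K = 298) {
  stopifnot(all(sigma_m2 > 0))
  kB * T_K / sigma_m2
}

#' Edge fluctuation amplitude versus compartment shape index
#'
#' Pairs, per experiment, the mean interior shape index with the pooled
#' edge-length deviation SD and the activity condition — fluctuations broaden
#' both with increasing shape index (approaching the rigidity transition) and
#' with swimming activity.
#'
#' @param experiments list; each element a list with `net` (foam_network),
#'   `tracks` (track table covering the network's vertices), `condition`
#'   (e.g. "active"/"heat-killed") and optional `label`.
#' @param block_s block duration for [edge_deviation()].
#' @return data.frame with `label`, `condition`, `shape_index`,
#'   `edge_sd_um`, `n_edges`.
#' @export
fluctuation_vs_shape <- function(experiments, block_s = 60) {
  if (length(experiments) < 2) stop("need at least 2 experiments")
  rows <- lapply(seq_along(experiments), function(i) {
    ex <- experiments[[i]]
    s_mean <- mean(shape_stats(ex$net)$shape_index)
    per <- split(ex$tracks, ex$tracks$vertex_id)
    ids <- as.integer(names(per))
    devs <- unlist(lapply(seq_len(nrow(ex$net$edges)), function(r) {
      v1 <- ex$net$edges[r, 1]; v2 <- ex$net$edges[r, 2]
      if (!(v1 %in% ids && v2 %in% ids)) return(NULL)
      edge_deviation(per[[as.character(v1)]], per[[as.character(v2)]],
                     block_s = block_s)$deviation_um
    }), use.names = FALSE)
    data.frame(label = if (!is.null(ex$label)) ex$label else paste0("exp", i),
               condition = ex$condition,
               shape_index = s_mean,
               edge_sd_um = sd(devs),
               n_edges = NA_integer_)
  })
  do.call(rbind, rows)
}
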