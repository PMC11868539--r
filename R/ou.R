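## Ornstein-Uhlenbeck vertex dynamics: the effective-temperature null model of
## an overdamped junction in a harmonic potential.

#' Simulation configuration for vertex dynamics
#'
#' Parameters of the overdamped harmonic ("effective temperature") vertex
#' model: drag `b_Nsm` (N·s/m), corner frequency `f0_hz` (Hz, giving spring
#' constant \eqn{k = 2\pi f_0 b}), ambient temperature `T_K` and effective
#' temperature ratio `teff_ratio` = Teff/T. Defaults are the fitted values for
#' an active lipid-foam vertex: b = 0.5 µN·s/m, f0 = 0.9e-3 Hz, Teff/T = 6.5.
#'
#' @param dt_s integration step (s). Must satisfy `dt < 1/(2 pi f0)/10`.
#' @param duration_s simulated duration (s), default 600 (a 10-min timelapse).
#' @param sampling_dt_s output sampling interval (s), default 1 (1 frame/s).
#' @param T_K ambient temperature (K), default 298.
#' @param b_Nsm drag coefficient (N·s/m).
#' @param f0_hz corner frequency (Hz).
#' @param teff_ratio effective temperature ratio Teff/T (1 for passive).
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt_s = 1, duration_s = 600, sampling_dt_s = 1,
                       T_K = 298, b_Nsm = 0.5e-6, f0_hz = 0.9e-3,
                       teff_ratio = 6.5, seed = 1L) {
  stopifnot(dt_s > 0, duration_s > 0, sampling_dt_s >= dt_s, T_K > 0,
            b_Nsm > 0, f0_hz > 0, teff_ratio > 0)
  relax <- 1 / (2 * pi * f0_hz)
  if (dt_s >= relax / 10)
    stop(sprintf(paste0("unstable dt: dt = %g s but the relaxation time ",
                        "1/(2 pi f0) = %.3g s requires dt < %.3g s"),
                 dt_s, relax, relax / 10))
  structure(list(dt_s = dt_s, duration_s = duration_s,
                 sampling_dt_s = sampling_dt_s, T_K = T_K, b_Nsm = b_Nsm,
                 f0_hz = f0_hz, teff_ratio = teff_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an Ornstein--Uhlenbeck vertex trajectory
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' \deqn{b\,\dot x = -k x + \sqrt{2 k_B T_{eff} b}\,\xi(t), \quad k = 2\pi f_0 b,}
#' independently per axis. The stationary variance per axis is
#' \eqn{k_B T_{eff}/k} and the normalized autocorrelation decays as
#' \eqn{e^{-2\pi f_0 t}}.
#'
#' @param cfg a [sim_config()].
#' @param ndim 1 or 2 axes.
#' @param x0_um initial position (µm), recycled to `ndim`; default 0 (add a
#'   burn-in or use `stationary_start = TRUE` for equilibrium sampling).
#' @param stationary_start draw the initial condition from the stationary
#'   distribution (default TRUE)?
#' @return a track data.frame with columns `vertex_id`, `frame`, `t_s`,
#'   `x_um`, `y_um` (y 0 when `ndim = 1`), `valid`; attribute `cfg`.
#' @export
simulate_ou_vertex <- function(cfg, ndim = 2, x0_um = 0,
                               stationary_start = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), ndim %in% 1:2)
  set.seed(cfg$seed)
  k <- 2 * pi * cfg$f0_hz * cfg$b_Nsm
  theta <- k / cfg$b_Nsm                     # relaxation rate, 1/s
  var_stat <- kB * cfg$T_K * cfg$teff_ratio / k   # m^2
  dt <- cfg$dt_s
  nstep <- ceiling(cfg$duration_s / dt)
  keep <- round(cfg$sampling_dt_s / dt)
  x0 <- rep(x0_um, length.out = ndim) * 1e-6
  sig <- sqrt(2 * kB * cfg$T_K * cfg$teff_ratio * dt / cfg$b_Nsm)
  ax <- matrix(NA_real_, nstep + 1, ndim)
  for (d in seq_len(ndim)) {
    start <- if (stationary_start) rnorm(1, 0, sqrt(var_stat)) else x0[d]
    incr <- rnorm(nstep, 0, sig)
    # x_{n+1} = (1 - theta dt) x_n + incr  (recursive filter, C-level loop)
    ax[, d] <- c(start, stats::filter(incr, filter = 1 - theta * dt,
                                      method = "recursive", init = start))
  }
  idx <- seq(1, nstep + 1, by = keep)
  t_s <- (idx - 1) * dt
  data.frame(vertex_id = 1L, frame = seq_along(idx), t_s = t_s,
             x_um = ax[idx, 1] * 1e6,
             y_um = if (ndim == 2) ax[idx, 2] * 1e6 else 0,
             valid = TRUE) -> out
  attr(out, "cfg") <- cfg
  out
}
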