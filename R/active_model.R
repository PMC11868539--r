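## Swim-pressure coupling of encapsulated swimmers to junction displacement:
## vectorial occupancy, the linear displacement law, slope fitting,
## interaction-radius inversion, and the membrane point-force response.

#' Parameters of the swim-pressure displacement law
#'
#' The time-averaged junction displacement produced by an occupancy imbalance
#' \eqn{\Phi} is
#' \deqn{\Delta\vartheta = c\,\frac{3\eta\tau A}{4R^2}\,\frac{v^2\Phi}{\gamma_e}}
#' with medium viscosity \eqn{\eta}, swimmer persistence time \eqn{\tau} and
#' speed \eqn{v}, bilayer segment area \eqn{A}, swimmer--bilayer interaction
#' radius \eqn{R}, effective (fluctuation-derived) tension \eqn{\gamma_e}, and
#' a geometric prefactor \eqn{c} of order 1.
#'
#' @param eta_pas medium viscosity, Pa·s (default 10e-3, as printed for the
#'   encapsulation medium).
#' @param tau_s persistence time, s (default 1).
#' @param A_um2 bilayer segment area, µm² (default 200).
#' @param v_umps swimmer speed, µm/s (default 3.5).
#' @param R_um swimmer-bilayer interaction radius, µm (default 2).
#' @param gamma_e_Npm effective tension, N/m (default 3.1e-8).
#' @param prefactor geometric prefactor c (default 1).
#' @return object of class `active_model_params`.
#' @export
active_model_params <- function(eta_pas = 10e-3, tau_s = 1, A_um2 = 200,
                                v_umps = 3.5, R_um = 2,
                                gamma_e_Npm = 3.1e-8, prefactor = 1) {
  p <- list(eta_pas = eta_pas, tau_s = tau_s, A_um2 = A_um2, v_umps = v_umps,
            R_um = R_um, gamma_e_Npm = gamma_e_Npm, prefactor = prefactor)
  if (any(unlist(p) <= 0)) stop("all active model parameters must be > 0")
  structure(p, class = "active_model_params")
}

# slope of the displacement law in µm per unit Phi
displacement_slope_um <- function(params) {
  with(params, {
    prefactor * (3 * eta_pas * tau_s * (A_um2 * 1e-12)) /
      (4 * (R_um * 1e-6)^2) * (v_umps * 1e-6)^2 / gamma_e_Npm * 1e6
  })
}

#' Vectorial occupancy at a three-way junction
#'
#' The three compartments around a junction are assigned the fixed directions
#' 0, 120 and 240 degrees; the occupancy vector is
#' \eqn{\sum_n \Phi_n(\cos\varphi_n, \sin\varphi_n)} and its magnitude
#' \eqn{\Phi = |\Phi_1 + \Phi_2 + \Phi_3|} measures the occupancy imbalance.
#' Equal occupancies cancel exactly (\eqn{\Phi = 0}).
#'
#' @param phi1,phi2,phi3 compartment area fractions in [0, 1].
#' @return list with `phi` (components), `magnitude`, `direction_deg`
#'   (atan2, in [0, 360); NA when the magnitude is 0).
#' @export
vector_occupancy <- function(phi1, phi2, phi3) {
  p <- c(phi1, phi2, phi3)
  if (any(p < 0 | p > 1)) stop("occupancies must be in [0, 1]")
  ang <- c(0, 120, 240) * pi / 180
  vx <- sum(p * cos(ang)); vy <- sum(p * sin(ang))
  mag <- sqrt(vx^2 + vy^2)
  dir <- if (mag < 1e-15) NA_real_ else (atan2(vy, vx) * 180 / pi) %% 360
  list(phi = p, magnitude = mag, direction_deg = dir)
}

#' Predicted junction displacement from the swim-pressure law
#'
#' @param params an [active_model_params()].
#' @param phi vectorial occupancy magnitude \eqn{\Phi \ge 0}.
#' @return predicted mean displacement in µm.
#' @export
predicted_displacement <- function(params, phi) {
  stopifnot(inherits(params, "active_model_params"), all(phi >= 0))
  displacement_slope_um(params) * phi
}

#' Zero-intercept fit of displacement versus vectorial occupancy
#'
#' Least squares through the origin: slope \eqn{= \sum\Phi\Delta / \sum\Phi^2};
#' the coefficient of determination is reported about the data mean,
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param phi vectorial occupancy magnitudes.
#' @param displacement_um measured mean vertex displacements (µm).
#' @return list with `slope_um`, `r_squared`, `n`.
#' @export
fit_displacement_slope <- function(phi, displacement_um) {
  ok <- is.finite(phi) & is.finite(displacement_um)
  phi <- phi[ok]; d <- displacement_um[ok]
  if (length(phi) < 3) stop("need at least 3 (phi, displacement) pairs")
  if (all(phi == 0)) stop("slope undefined: all phi are zero")
  slope <- sum(phi * d) / sum(phi^2)
  ss_res <- sum((d - slope * phi)^2)
  ss_tot <- sum((d - mean(d))^2)
  list(slope_um = slope, r_squared = 1 - ss_res / ss_tot, n = length(phi))
}

#' Invert the displacement law for the interaction radius
#'
#' Given the fitted displacement-versus-\eqn{\Phi} slope, solves
#' \eqn{R = \sqrt{c\,3\eta\tau A v^2/(4\gamma_e\,\mathrm{slope})}} — the exact
#' inverse of [predicted_displacement()]'s \eqn{\Phi}-slope.
#'
#' @param slope_um fitted slope in µm per unit \eqn{\Phi} (> 0).
#' @param params an [active_model_params()]; its `R_um` is ignored.
#' @return interaction radius R in µm.
#' @export
infer_interaction_radius <- function(slope_um, params) {
  stopifnot(slope_um > 0, inherits(params, "active_model_params"))
  with(params, {
    R2 <- prefactor * 3 * eta_pas * tau_s * (A_um2 * 1e-12) *
      (v_umps * 1e-6)^2 / (4 * gamma_e_Npm * (slope_um * 1e-6))
    sqrt(R2) * 1e6
  })
}

#' Quasi-static membrane deformation by a point force
#'
#' Linear response of a tensed membrane to a normal point force \eqn{F}:
#' \deqn{h = \frac{F}{2\pi\gamma}\,\ln(r_{max}/r_{min})}
#' with the tension--bending crossover length \eqn{\sqrt{\kappa/\gamma}}
#' capping `r_min` from below. At bilayer tensions of mN/m a swimmer's Stokes
#' thrust produces only sub-nanometre deformation, which justifies mapping the
#' swim pressure directly onto the junction positions rather than resolving
#' membrane shape.
#'
#' @param gamma_Npm membrane tension, N/m (> 0).
#' @param kappa_J bending rigidity, J (default 1e-19, a typical lipid
#'   bilayer).
#' @param force_N point force, N; default the Stokes thrust
#'   \eqn{6\pi\eta_w R_b v} of a 1 µm swimmer at 3.5 µm/s in water.
#' @param r_min_um,r_max_um force application radius and outer cutoff, µm.
#' @return deformation amplitude in nm.
#' @export
membrane_point_deformation <- function(gamma_Npm, kappa_J = 1e-19,
                                       force_N = 6 * pi * 1e-3 * 1e-6 * 3.5e-6,
                                       r_min_um = 1, r_max_um = 10) {
  stopifnot(gamma_Npm > 0, force_N > 0, r_min_um < r_max_um)
  lc_um <- sqrt(kappa_J / gamma_Npm) * 1e6   # crossover length
  r_min_um <- max(r_min_um, lc_um)
  if (r_min_um >= r_max_um) r_min_um <- r_max_um / exp(1)
  h_m <- force_N / (2 * pi * gamma_Npm) * log(r_max_um / r_min_um)
  h_m * 1e9
}

#' Assign the three compartments around a vertex to the idealized directions
#'
#' Real junction geometry deviates from the idealized 0/120/240-degree
#' sectors. The actual centroid directions of the three adjacent compartments
#' are rigidly rotated (per vertex) to best match the idealized directions and
#' each compartment is snapped to its nearest sector.
#'
#' @param net a [foam_network()].
#' @param vertex interior vertex id (three adjacent compartments).
#' @return data.frame with `compartment`, `angle_deg` (actual centroid
#'   direction), `sector_deg` (assigned 0/120/240).
#' @export
assign_occupancy_sectors <- function(net, vertex) {
  comps <- vertex_compartments(net, vertex)
  if (length(comps) != 3)
    stop("vertex ", vertex, " does not have exactly 3 adjacent compartments")
  p0 <- drop(vertex_xy(net, vertex))
  ang <- vapply(comps, function(ci) {
    ctr <- poly_centroid(compartment_polygon(net, ci))
    (atan2(ctr[2] - p0[2], ctr[1] - p0[1]) * 180 / pi) %% 360
  }, numeric(1))
  ord <- order(ang)
  # best rigid rotation: mean circular offset from (0, 120, 240)
  target <- c(0, 120, 240)
  sector <- target[order(ord)]  # rank within the vertex -> sector
  data.frame(compartment = comps, angle_deg = ang, sector_deg = sector)
}
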