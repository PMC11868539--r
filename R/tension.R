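## Membrane tension relations at the monolayer/bilayer scale (mN/m).

#' Bilayer tension from the monolayer tension balance
#'
#' At a Plateau--Gibbs border the bilayer unzips into two monolayers; force
#' balance along the bilayer direction gives
#' \deqn{\gamma_B = 2\,\gamma_{ML}\cos\phi}
#' with microscopic contact angle \eqn{\phi}. The zipped bilayer ceases to
#' exist for \eqn{\phi \ge 90^\circ}.
#'
#' @param gamma_ml monolayer (oil/water interface) tension, mN/m (> 0).
#' @param phi_deg microscopic contact angle in degrees, in [0, 90).
#' @return bilayer tension \eqn{\gamma_B} in mN/m.
#' @export
bilayer_tension <- function(gamma_ml, phi_deg) {
  if (any(gamma_ml <= 0)) stop("gamma_ml must be > 0")
  if (any(phi_deg < 0 | phi_deg >= 90))
    stop("phi_deg must be in [0, 90): no zipped bilayer otherwise")
  2 * gamma_ml * cos(phi_deg * pi / 180)
}

#' Microscopic contact angle from bilayer and monolayer tensions
#'
#' Inverse of [bilayer_tension()]: \eqn{\phi = \arccos(\gamma_B/2\gamma_{ML})}.
#'
#' @param gamma_b bilayer tension, mN/m, with \eqn{0 < \gamma_B \le 2\gamma_{ML}}.
#' @param gamma_ml monolayer tension, mN/m (> 0).
#' @return contact angle in degrees.
#' @export
contact_angle <- function(gamma_b, gamma_ml) {
  if (any(gamma_b <= 0) || any(gamma_ml <= 0)) stop("tensions must be > 0")
  if (any(gamma_b > 2 * gamma_ml + 1e-12))
    stop("gamma_b > 2*gamma_ml is unphysical (adhesion cannot exceed zipping)")
  acos(pmin(1, gamma_b / (2 * gamma_ml))) * 180 / pi
}

#' Critical tension from micropipette aspiration (Laplace law)
#'
#' For a membrane segment aspirated into a pipette of radius \eqn{R_p} at
#' suction pressure \eqn{\Delta P = p_1 - p_0}, the Laplace law for a
#' hemispherical cap at the pipette mouth gives
#' \eqn{\gamma_c = |\Delta P| R_p / (2\,g)} with geometric factor `geom`
#' (default 1, the flat-film cap geometry).
#'
#' @param delta_p_pa suction pressure in Pa (sign ignored; aspiration uses
#'   \eqn{\Delta P < 0}).
#' @param rp_um pipette radius in µm (> 0).
#' @param geom dimensionless geometric factor (default 1).
#' @return critical membrane tension in mN/m.
#' @export
aspiration_tension <- function(delta_p_pa, rp_um, geom = 1) {
  if (rp_um <= 0) stop("rp_um must be > 0")
  # Pa * m / 2 -> N/m; * 1e3 -> mN/m
  abs(delta_p_pa) * (rp_um * 1e-6) / (2 * geom) * 1e3
}

#' Mechanical regime from the bilayer/monolayer tension ratio
#'
#' Foam-model stability of the packing as a function of
#' \eqn{\gamma_B/\gamma_{ML}}: confluent packing requires the ratio to be at
#' least 0.23, and the density-independent rigidity (jamming/unjamming)
#' transition sits at ratio 2.
#'
#' @param gamma_b,gamma_ml tensions in mN/m (> 0).
#' @return list with `ratio` and `regime`, one of `"sub-confluent"`,
#'   `"confluent-jammed"` or `"at/above rigidity transition"`.
#' @export
stability_ratios <- function(gamma_b, gamma_ml) {
  if (gamma_b <= 0 || gamma_ml <= 0) stop("tensions must be > 0")
  ratio <- gamma_b / gamma_ml
  regime <- if (ratio < 0.23) "sub-confluent"
  else if (ratio < 2) "confluent-jammed"
  else "at/above rigidity transition"
  list(ratio = ratio, regime = regime)
}

#' Construct a tension state record
#'
#' Bundles the membrane-scale tension measurements of a foam: monolayer and
#' bilayer tension, contact angle, aspiration data, and (optionally) the
#' vertex curvature radius.
#'
#' @param gamma_ml monolayer tension mN/m; @param gamma_b bilayer tension mN/m;
#' @param phi_deg contact angle degrees; @param gamma_c critical aspiration
#'   tension mN/m; @param delta_p_pa suction pressure Pa; @param rp_um pipette
#'   radius µm; @param r_um vertex curvature radius µm or NA.
#' @return object of class `tension_state`.
#' @export
tension_state <- function(gamma_ml, gamma_b = bilayer_tension(gamma_ml, phi_deg),
                          phi_deg = 0, gamma_c = NA_real_,
                          delta_p_pa = NA_real_, rp_um = NA_real_,
                          r_um = NA_real_) {
  if (gamma_ml <= 0) stop("gamma_ml must be > 0")
  if (phi_deg < 0 || phi_deg >= 90) stop("phi_deg must be in [0, 90)")
  if (gamma_b > 2 * gamma_ml + 1e-12) stop("gamma_b must be <= 2*gamma_ml")
  structure(list(gamma_ml = gamma_ml, gamma_b = gamma_b, phi_deg = phi_deg,
                 gamma_c = gamma_c, delta_p_pa = delta_p_pa, rp_um = rp_um,
                 r_um = r_um),
            class = "tension_state")
}
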