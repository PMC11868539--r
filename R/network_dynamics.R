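## Langevin dynamics of the whole foam network: tension restoring forces,
## thermal noise, and per-compartment active forcing driven by swimmer
## occupancy.

#' Effective stiffness of a junction in the tension network
#'
#' Numerically differentiates [vertex_net_force()] about the current position:
#' returns the mean of the two diagonal stiffness components
#' \eqn{-\partial F_i/\partial x_i} (N/m when tensions are given in N and
#' positions in µm are converted internally).
#'
#' @param net a [foam_network()].
#' @param edge_tension_N edge tension(s) in newtons (per unit film height),
#'   see [vertex_net_force()] for formats.
#' @param vertex vertex id (degree 3).
#' @param h_um finite-difference step, µm.
#' @return stiffness in N/m.
#' @export
effective_stiffness <- function(net, edge_tension_N, vertex, h_um = 0.01) {
  kxx <- numeric(2)
  for (d in 1:2) {
    col <- if (d == 1) "x_um" else "y_um"
    i <- match(vertex, net$vertices$id)
    np <- net; np$vertices[[col]][i] <- np$vertices[[col]][i] + h_um
    nm <- net; nm$vertices[[col]][i] <- nm$vertices[[col]][i] - h_um
    fp <- vertex_net_force(np, edge_tension_N, vertex)$force[d]
    fm <- vertex_net_force(nm, edge_tension_N, vertex)$force[d]
    kxx[d] <- -(fp - fm) / (2 * h_um * 1e-6)
  }
  mean(kxx)
}

#' Harmonic Hessian of the foam energy
#'
#' Second derivative of the vertex-model energy
#' \eqn{E = \sum_e \gamma L_e + \sum_c \tfrac{K_A}{2}(A_c - A_c^0)^2}
#' with respect to the interior vertex coordinates, at the current
#' configuration (taken as the reference, \eqn{A_c = A_c^0}). A stretched edge
#' of length L contributes the transverse block \eqn{(\gamma/L)(I - t t^T)};
#' central-force edges have no longitudinal curvature, so the degree-3 tension
#' network alone is sub-isostatic, and the area elasticity of the (effectively
#' incompressible) compartments supplies the missing rigidity. Boundary
#' vertices are treated as pinned.
#'
#' @param net a [foam_network()].
#' @param edge_tension_N uniform edge tension, N.
#' @param area_stiffness area modulus \eqn{K_A} in N/m^3; default
#'   \eqn{\gamma / L_0^3} with \eqn{L_0} the mean edge length, which puts the
#'   area-mode stiffness on the same scale as the tension stiffness.
#' @return list with `K` (2n x 2n stiffness matrix, N/m, interior vertices
#'   only, coordinate order x1,y1,x2,y2,...), `ids` (vertex ids) and
#'   `area_stiffness`.
#' @export
network_hessian <- function(net, edge_tension_N, area_stiffness = NULL) {
  v <- net$vertices
  interior <- which(!v$boundary)
  idx <- setNames(seq_along(interior), v$id[interior])
  n <- length(interior)
  K <- matrix(0, 2 * n, 2 * n)
  pos <- cbind(v$x_um, v$y_um) * 1e-6
  if (is.null(area_stiffness)) {
    L0 <- mean(edge_lengths(net)) * 1e-6
    area_stiffness <- edge_tension_N / L0^3
  }
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges[r, 1], v$id); j <- match(net$edges[r, 2], v$id)
    d <- pos[j, ] - pos[i, ]
    L <- sqrt(sum(d^2))
    t_ <- d / L
    H <- edge_tension_N / L * (diag(2) - tcrossprod(t_))
    ii <- idx[as.character(v$id[i])]; jj <- idx[as.character(v$id[j])]
    ri <- if (!is.na(ii)) c(2 * ii - 1, 2 * ii) else NULL
    rj <- if (!is.na(jj)) c(2 * jj - 1, 2 * jj) else NULL
    if (!is.null(ri)) K[ri, ri] <- K[ri, ri] + H
    if (!is.null(rj)) K[rj, rj] <- K[rj, rj] + H
    if (!is.null(ri) && !is.null(rj)) {
      K[ri, rj] <- K[ri, rj] - H
      K[rj, ri] <- K[rj, ri] - H
    }
  }
  # area elasticity: rank-1 contribution K_A (dA/dx)(dA/dx)^T per compartment
  for (ci in seq_along(net$compartments)) {
    cyc <- net$compartments[[ci]]
    g <- area_gradient(pos, match(cyc, v$id))
    gv <- numeric(2 * n)
    for (j in seq_along(cyc)) {
      ii <- idx[as.character(cyc[j])]
      if (!is.na(ii)) gv[c(2 * ii - 1, 2 * ii)] <- g[j, ]
    }
    K <- K + area_stiffness * tcrossprod(gv)
  }
  list(K = K, ids = v$id[interior], area_stiffness = area_stiffness)
}

# gradient of the signed polygon area wrt each cycle vertex (rows of `rows`
# index into `pos`); d(A)/d(x_v, y_v) = ((y_next - y_prev)/2, (x_prev - x_next)/2)
area_gradient <- function(pos, rows) {
  m <- length(rows)
  prv <- rows[c(m, seq_len(m - 1))]
  nxt <- rows[c(2:m, 1)]
  cbind((pos[nxt, 2] - pos[prv, 2]) / 2, (pos[prv, 1] - pos[nxt, 1]) / 2)
}

signed_area <- function(pos, rows) {
  x <- pos[rows, 1]; y <- pos[rows, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Equilibrium vertex fluctuation variance of the tension network
#'
#' Closed-form equipartition prediction: with stiffness matrix K (see
#' [network_hessian()]), the covariance of interior vertex coordinates is
#' \eqn{k_B T K^{-1}}; returned per vertex as the radial (x+y) variance.
#'
#' @inheritParams network_hessian
#' @param T_K temperature (K).
#' @param area_stiffness area modulus, see [network_hessian()].
#' @return data.frame with `vertex_id` and `var_um2` (total 2D variance,
#'   µm²).
#' @export
network_vertex_variance <- function(net, edge_tension_N, T_K = 298,
                                    area_stiffness = NULL) {
  h <- network_hessian(net, edge_tension_N, area_stiffness)
  Kinv <- solve(h$K)
  n <- length(h$ids)
  v2 <- kB * T_K * (diag(Kinv)[2 * seq_len(n) - 1] + diag(Kinv)[2 * seq_len(n)])
  data.frame(vertex_id = h$ids, var_um2 = v2 * 1e12)
}

#' Simulate foam network Langevin dynamics with active compartments
#'
#' Overdamped dynamics of all interior vertices (boundary vertices pinned):
#' \deqn{b\,\dot{x}_v = F^{tension}_v + F^{active}_v + \sqrt{2 k_B T b}\,\xi_v(t)}
#' where the tension force is the vector sum of edge pulls and the active
#' force from each adjacent compartment is an Ornstein--Uhlenbeck process
#' (correlation time `tau_s`) directed outward from that compartment's
#' centroid. The mean force of a compartment with occupancy \eqn{\Phi_n} is
#' calibrated through the network compliance matrix (see [network_hessian()])
#' so that, acting alone, it displaces the compartment's vertices on average
#' by the swim-pressure law [predicted_displacement()]; around a symmetric
#' junction the three outward means then vector-sum as the vectorial
#' occupancy model. Sharing one force process per compartment induces spatial
#' correlation between that compartment's vertices.
#'
#' @param net a [foam_network()].
#' @param cfg a [sim_config()] providing dt, duration, sampling, T, drag b
#'   (its `teff_ratio` is ignored here — activity is explicit).
#' @param occupancy data.frame from [sample_occupancy()] (or NULL for a
#'   passive network).
#' @param active_params an [active_model_params()] used to calibrate the mean
#'   active force. The default uses `prefactor = 0.11`, which reproduces the
#'   experimentally fitted displacement slope of 16.4 µm per unit occupancy at
#'   an interaction radius of 2 µm.
#' @param edge_tension_N uniform edge tension in N; default chosen so the
#'   effective junction stiffness approximates \eqn{2\pi f_0 b} from `cfg`.
#' @param active_fluct overall multiplier on the fluctuating active force
#'   amplitude (default 1).
#' @param teff_target effective temperature ratio produced by the active
#'   force fluctuations when all three compartments at a vertex carry the
#'   reference occupancy `phi_ref` (default 6.5, the fitted activity level).
#' @param phi_ref reference occupancy for `teff_target` (default 0.03, about
#'   15 swimmers of 2 µm² in a 1000 µm² compartment). Fluctuation variance
#'   scales linearly with \eqn{\Phi_n}, so activity always exceeds the
#'   thermal baseline in loaded compartments and grows monotonically with
#'   occupancy.
#' @param seed integer RNG seed.
#' @return track table (`vertex_id`, `frame`, `t_s`, `x_um`, `y_um`, `valid`)
#'   for interior vertices, with attributes `k_eff_Npm`, `edge_tension_N`,
#'   `equilibrium` (the input vertex table) and `net`.
#' @export
simulate_network_dynamics <- function(net, cfg, occupancy = NULL,
                                      active_params = NULL,
                                      edge_tension_N = NULL,
                                      active_fluct = 1, teff_target = 6.5,
                                      phi_ref = 0.03, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  v <- net$vertices
  interior <- which(!v$boundary)
  if (!length(interior)) stop("network has no interior vertices")
  L0 <- mean(edge_lengths(net))
  k_target <- 2 * pi * cfg$f0_hz * cfg$b_Nsm
  if (is.null(edge_tension_N)) {
    # transverse stiffness of a tense edge of length L is ~ gamma/L per edge;
    # calibrate on a representative interior junction
    gam0 <- k_target * (L0 * 1e-6)
    k0 <- effective_stiffness(net, gam0, v$id[interior[1]])
    edge_tension_N <- gam0 * k_target / k0
  }
  k_eff <- effective_stiffness(net, edge_tension_N, v$id[interior[1]])

  pos <- cbind(v$x_um, v$y_um) * 1e-6          # meters
  e1 <- match(net$edges[, 1], v$id); e2 <- match(net$edges[, 2], v$id)
  ncomp <- length(net$compartments)
  comp_members <- lapply(net$compartments, function(cyc) match(cyc, v$id))
  centroids <- t(vapply(seq_len(ncomp), function(i)
    poly_centroid(compartment_polygon(net, i)), numeric(2))) * 1e-6
  # fixed outward unit vectors compartment -> vertex (reference geometry)
  comp_dirs <- lapply(seq_len(ncomp), function(ci) {
    d <- pos[comp_members[[ci]], , drop = FALSE] -
      matrix(centroids[ci, ], length(comp_members[[ci]]), 2, byrow = TRUE)
    d / sqrt(rowSums(d^2))
  })

  L0m <- L0 * 1e-6
  K_A <- edge_tension_N / L0m^3          # area modulus, matches network_hessian
  comp_rows <- comp_members
  A0 <- vapply(comp_rows, function(m) signed_area(pos, m), numeric(1))

  phi <- rep(0, ncomp)
  if (!is.null(occupancy)) phi[occupancy$compartment] <- occupancy$phi
  if (is.null(active_params)) active_params <- active_model_params(prefactor = 0.11)
  slope_m <- displacement_slope_um(active_params) * 1e-6    # m per unit Phi
  # calibrate the mean force through the network compliance: a unit outward
  # force pattern on compartment ci displaces its vertices by g_c metres/N
  h <- network_hessian(net, edge_tension_N, K_A)
  Kinv <- solve(h$K)
  dof <- function(vid) { k <- match(vid, h$ids); c(2 * k - 1, 2 * k) }
  a_mean <- numeric(ncomp)
  for (ci in which(phi > 0)) {
    m <- comp_members[[ci]]
    fvec <- numeric(2 * length(h$ids))
    rows <- integer(0)
    for (j in seq_along(m)) {
      vid <- v$id[m[j]]
      if (vid %in% h$ids) {
        fvec[dof(vid)] <- comp_dirs[[ci]][j, ]
        rows <- c(rows, j)
      }
    }
    if (!length(rows)) next
    u <- Kinv %*% fvec
    g_c <- mean(vapply(rows, function(j)
      sum(u[dof(v$id[m[j]])] * comp_dirs[[ci]][j, ]), numeric(1)))
    a_mean[ci] <- slope_m * phi[ci] / g_c
  }
  # fluctuating (zero-mean) collision noise: low-frequency force power of the
  # OU process is 4 a_sd^2 tau per compartment; three compartments at 120 deg
  # contribute 3/2 per axis, so a_sd^2 = (2/3)(Teff/T - 1) kB T b / tau at the
  # reference occupancy, scaling linearly with phi
  tau <- active_params$tau_s
  a_sd <- active_fluct *
    sqrt((2 / 3) * pmax(teff_target - 1, 0) * kB * cfg$T_K * cfg$b_Nsm /
           tau * phi / phi_ref)
  a_now <- a_mean

  dt <- cfg$dt_s
  nstep <- ceiling(cfg$duration_s / dt)
  keep <- max(1L, round(cfg$sampling_dt_s / dt))
  noise_sd <- sqrt(2 * kB * cfg$T_K * cfg$b_Nsm * dt) / cfg$b_Nsm  # m
  maxstep <- 0.5 * min(vapply(seq_len(ncomp), function(i)
    sqrt(poly_area(compartment_polygon(net, i))), numeric(1))) * 1e-6
  nint <- length(interior)

  frames <- vector("list", floor(nstep / keep) + 1L)
  frames[[1]] <- pos[interior, , drop = FALSE]
  fi <- 1L
  for (s in seq_len(nstep)) {
    for (attempt in 0:6) {
      sub <- 2L^attempt
      dts <- dt / sub
      pos_try <- pos
      a_try <- a_now
      ok <- TRUE
      for (ss in seq_len(sub)) {
        d <- pos_try[e2, , drop = FALSE] - pos_try[e1, , drop = FALSE]
        len <- sqrt(rowSums(d^2))
        fe <- edge_tension_N * d / len
        Fm <- rowsum(rbind(fe, -fe), group = c(e1, e2))
        Ftot <- matrix(0, nrow(pos), 2)
        Ftot[as.integer(rownames(Fm)), ] <- Fm
        # area elasticity restoring force per compartment
        for (ci in seq_len(ncomp)) {
          m <- comp_rows[[ci]]
          coefA <- -K_A * (signed_area(pos_try, m) - A0[ci])
          Ftot[m, ] <- Ftot[m, ] + coefA * area_gradient(pos_try, m)
        }
        # active forcing, shared per compartment
        a_try <- a_try + (a_mean - a_try) * dts / tau +
          a_sd * sqrt(2 * dts / tau) * rnorm(ncomp)
        for (ci in which(phi > 0)) {
          m <- comp_members[[ci]]
          Ftot[m, ] <- Ftot[m, ] + a_try[ci] * comp_dirs[[ci]]
        }
        dx <- Ftot[interior, , drop = FALSE] * dts / cfg$b_Nsm +
          matrix(rnorm(2 * nint, 0, noise_sd / sqrt(sub)), nint, 2)
        if (max(abs(dx)) > maxstep) { ok <- FALSE; break }
        pos_try[interior, ] <- pos_try[interior, ] + dx
      }
      if (ok) { pos <- pos_try; a_now <- a_try; break }
      if (attempt == 6)
        stop("step rejection: displacement exceeded compartment scale even at dt/64")
    }
    if (s %% keep == 0L) {
      fi <- fi + 1L
      frames[[fi]] <- pos[interior, , drop = FALSE]
    }
  }
  t_s <- (seq_len(fi) - 1L) * keep * dt
  out <- do.call(rbind, lapply(seq_len(fi), function(i)
    data.frame(vertex_id = v$id[interior], frame = i, t_s = t_s[i],
               x_um = frames[[i]][, 1] * 1e6, y_um = frames[[i]][, 2] * 1e6,
               valid = TRUE)))
  out <- out[order(out$vertex_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "k_eff_Npm") <- k_eff
  attr(out, "edge_tension_N") <- edge_tension_N
  attr(out, "equilibrium") <- v
  attr(out, "net") <- net
  out
}
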