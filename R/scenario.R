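## End-to-end synthetic scenarios: one call produces everything the analysis
## pipeline consumes, with ground truth for recovery tests.

#' Scenario configuration
#'
#' Defaults emulate the experimental acquisition: a foam of ~35 µm
#' compartments imaged at 1 frame/s for 10 min, swimmers at 3.5 µm/s with 1 s
#' persistence, 0--40 per compartment.
#'
#' @param mode `"active"` (swimming bacteria) or `"heat-killed"` (identical
#'   geometry and noise, swimmer speed 0, no active forcing).
#' @param n_rows,n_cols hexagonal lattice size (compartments).
#' @param edge_length_um hexagon side, µm (default 20: compartments ~35 µm
#'   across).
#' @param disorder optional jitter for a disordered foam; 0 keeps the
#'   regular lattice.
#' @param duration_s total time, s (default 600).
#' @param frame_interval_s frame interval, s (default 1).
#' @param lambda_swimmers mean swimmers per compartment (default 15).
#' @param footprint_um2 swimmer footprint, µm² (default 2).
#' @param v_umps,tau_s swimmer speed (µm/s) and persistence (s).
#' @param T_K,b_Nsm,f0_hz thermal/drag parameters of the vertex dynamics
#'   (see [sim_config()]).
#' @param dyn_dt_s integration step of the network dynamics, s.
#' @param pixel_size_um,psf_sigma_um,noise_level rendering parameters
#'   (see [render_micrograph()]).
#' @param render render the micrograph stack (default TRUE; disable for
#'   track-level studies)?
#' @param seed integer master seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("active", "heat-killed"),
                            n_rows = 3, n_cols = 3, edge_length_um = 20,
                            disorder = 0, duration_s = 600,
                            frame_interval_s = 1, lambda_swimmers = 15,
                            footprint_um2 = 2, v_umps = 3.5, tau_s = 1,
                            T_K = 298, b_Nsm = 0.5e-6, f0_hz = 0.9e-3,
                            dyn_dt_s = 0.25, pixel_size_um = 1,
                            psf_sigma_um = 1, noise_level = 0,
                            render = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a full synthetic scenario
#'
#' Builds the foam, samples swimmer occupancy, simulates the vertex dynamics
#' (with active forcing in `"active"` mode), simulates swimmer trajectories
#' in each loaded compartment, and optionally renders the two-channel
#' timelapse. In `"heat-killed"` mode swimmers are static and the network
#' experiences thermal forces only.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `scenario_bundle` with `net`, `occupancy`,
#'   `truth_tracks` (network-dynamics vertex tracks), `swimmers` (long
#'   data.frame: compartment, particle, frame, t_s, x_um, y_um), `stack` (an
#'   [image_stack()], or NULL), `config`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  net <- if (cfg$disorder > 0)
    build_disordered_foam(cfg$n_rows * cfg$n_cols, cfg$disorder,
                          seed = cfg$seed,
                          spacing_um = cfg$edge_length_um * sqrt(3))
  else build_hexagonal_lattice(cfg$n_rows, cfg$n_cols, cfg$edge_length_um)

  areas <- vapply(seq_along(net$compartments), function(i)
    poly_area(compartment_polygon(net, i)), numeric(1))
  occupancy <- sample_occupancy(cfg$lambda_swimmers, cfg$footprint_um2,
                                areas, seed = cfg$seed + 1L)
  active <- cfg$mode == "active"
  dyn_cfg <- sim_config(dt_s = cfg$dyn_dt_s, duration_s = cfg$duration_s,
                        sampling_dt_s = cfg$frame_interval_s, T_K = cfg$T_K,
                        b_Nsm = cfg$b_Nsm, f0_hz = cfg$f0_hz,
                        teff_ratio = 1, seed = cfg$seed)
  truth <- simulate_network_dynamics(
    net, dyn_cfg, occupancy = if (active) occupancy else NULL,
    seed = cfg$seed + 2L)

  nframe <- length(unique(truth$frame))
  swimmers <- do.call(rbind, lapply(seq_along(net$compartments), function(ci) {
    n <- occupancy$count[ci]
    if (n == 0) return(NULL)
    poly <- compartment_polygon(net, ci)
    if (active) {
      ab <- simulate_abp(poly, n, v_umps = cfg$v_umps, tau_s = cfg$tau_s,
                         dt_s = min(0.05, 0.1 * cfg$edge_length_um / cfg$v_umps),
                         duration_s = cfg$duration_s, seed = cfg$seed + 10L + ci,
                         sampling_dt_s = cfg$frame_interval_s)
      tr <- ab$tracks
    } else {
      # heat-killed: static swimmers at random positions
      ab <- simulate_abp(poly, n, v_umps = 1e-6, tau_s = cfg$tau_s,
                         dt_s = 0.05, duration_s = 0.05,
                         seed = cfg$seed + 10L + ci, sampling_dt_s = 0.05)
      p0 <- ab$tracks[ab$tracks$frame == 1, ]
      tr <- do.call(rbind, lapply(seq_len(nframe), function(f) {
        d <- p0; d$frame <- f; d$t_s <- (f - 1) * cfg$frame_interval_s; d
      }))
    }
    tr <- tr[tr$frame <= nframe, ]
    data.frame(compartment = ci, particle = tr$particle, frame = tr$frame,
               t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um)
  }))

  stack <- NULL
  if (cfg$render) {
    v <- net$vertices
    margin <- 5
    fov <- list(origin_um = c(min(v$x_um) - margin, min(v$y_um) - margin),
                nx = ceiling((diff(range(v$x_um)) + 2 * margin) / cfg$pixel_size_um),
                ny = ceiling((diff(range(v$y_um)) + 2 * margin) / cfg$pixel_size_um))
    frames <- lapply(seq_len(nframe), function(f) {
      vf <- v
      tf <- truth[truth$frame == f, ]
      i <- match(tf$vertex_id, vf$id)
      vf$x_um[i] <- tf$x_um; vf$y_um[i] <- tf$y_um
      netf <- net; netf$vertices <- vf
      sw <- if (!is.null(swimmers)) swimmers[swimmers$frame == f, ] else NULL
      st1 <- render_micrograph(netf, swimmers = sw,
                               pixel_size_um = cfg$pixel_size_um,
                               psf_sigma_um = cfg$psf_sigma_um,
                               noise_level = cfg$noise_level,
                               seed = cfg$seed + 1000L + f, fov = fov)
      st1$frames[[1]]
    })
    stack <- image_stack(frames, cfg$pixel_size_um, cfg$frame_interval_s,
                         origin_um = fov$origin_um)
  }
  structure(list(net = net, occupancy = occupancy, truth_tracks = truth,
                 swimmers = swimmers, stack = stack, config = cfg),
            class = "scenario_bundle")
}

#' Write / read a scenario bundle
#'
#' Writes plain-text artifacts: the network tables
#' (`network_{vertices,edges,compartments}`), ground-truth tracks and
#' swimmer trajectories (CSV), occupancy (CSV), the resolved configuration
#' (YAML) and, when present, the image stack (TIFF + JSON sidecar).
#'
#' @param bundle a `scenario_bundle`.
#' @param dir output directory (created if needed).
#' @return `write_scenario_bundle`: `dir`, invisibly;
#'   `read_scenario_bundle`: the bundle (without re-reading the stack unless
#'   present).
#' @export
write_scenario_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_foam_network(bundle$net, file.path(dir, "network"))
  foam_network_to_json(bundle$net, file.path(dir, "network.json"))
  write.csv(bundle$truth_tracks, file.path(dir, "truth_tracks.csv"),
            row.names = FALSE)
  write.csv(bundle$occupancy, file.path(dir, "occupancy.csv"),
            row.names = FALSE)
  if (!is.null(bundle$swimmers))
    write.csv(bundle$swimmers, file.path(dir, "swimmers.csv"),
              row.names = FALSE)
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  if (!is.null(bundle$stack))
    write_image_stack(bundle$stack, file.path(dir, "stack.tif"))
  invisible(dir)
}

#' @rdname write_scenario_bundle
#' @export
read_scenario_bundle <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$mode <- match.arg(cfg$mode, c("active", "heat-killed"))
  class(cfg) <- "scenario_config"
  sw_path <- file.path(dir, "swimmers.csv")
  st_path <- file.path(dir, "stack.tif")
  structure(list(
    net = read_foam_network(file.path(dir, "network")),
    occupancy = read.csv(file.path(dir, "occupancy.csv")),
    truth_tracks = read.csv(file.path(dir, "truth_tracks.csv")),
    swimmers = if (file.exists(sw_path)) read.csv(sw_path) else NULL,
    stack = if (file.exists(st_path)) read_image_stack(st_path) else NULL,
    config = cfg), class = "scenario_bundle")
}
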