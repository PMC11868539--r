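## Orchestration: simulate -> track -> statistics -> fits -> report, with
## resolved-config snapshots for reproducibility.

#' Simulate a scenario and write the bundle to disk
#'
#' @param cfg a [scenario_config()].
#' @param out_dir output directory.
#' @return the output directory, invisibly; writes TIFF/CSV/JSON plus the
#'   resolved `config.yaml`.
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  bundle <- generate_scenario(cfg)
  write_scenario_bundle(bundle, out_dir)
  invisible(out_dir)
}

#' Analyze a scenario bundle
#'
#' Runs the full measurement chain on a bundle (from disk or in memory):
#' vertex tracking (from the rendered stack, or the ground-truth tracks),
#' track QC, 60-s blocked displacement and edge-deviation statistics,
#' effective tension, spectra and effective-temperature fit, the
#' occupancy--displacement law fit with interaction-radius inversion, spatial
#' cross-correlation with correlation length, and the hotspot map.
#'
#' @param bundle a `scenario_bundle` or a directory written by
#'   [write_scenario_bundle()].
#' @param out_dir optional output directory for the report artifacts
#'   (`report.json`, statistics CSVs).
#' @param use_truth_tracks analyze the generator's ground-truth tracks
#'   (default) instead of re-tracking the rendered stack.
#' @param passive_bundle optional matched heat-killed bundle; enables the
#'   paired spectrum fit returning drag and Teff/T.
#' @param block_s statistics block duration, s.
#' @param max_jump_um QC jump threshold, µm.
#' @return list of class `foam_report` (statistics, fits, tables).
#' @export
pipeline_analyze <- function(bundle, out_dir = NULL, use_truth_tracks = TRUE,
                             passive_bundle = NULL, block_s = 60,
                             max_jump_um = 10) {
  if (is.character(bundle)) bundle <- read_scenario_bundle(bundle)
  if (is.character(passive_bundle))
    passive_bundle <- read_scenario_bundle(passive_bundle)
  net <- bundle$net
  cfg <- bundle$config
  tracks <- if (use_truth_tracks) bundle$truth_tracks
            else track_stack(bundle$stack, net, max_jump_um = max_jump_um)
  qc <- qc_tracks(tracks, max_jump_um = max_jump_um)
  tracks <- qc$tracks

  per <- split(tracks, tracks$vertex_id)
  disp <- do.call(rbind, lapply(per, function(d) {
    st <- vertex_displacement_stats(block_series(d, block_s))
    # offset of the time-averaged position from the reference (force-balanced)
    # vertex position: the statistic the displacement law predicts
    i <- match(d$vertex_id[1], net$vertices$id)
    ox <- mean(d$x_um) - net$vertices$x_um[i]
    oy <- mean(d$y_um) - net$vertices$y_um[i]
    data.frame(vertex_id = d$vertex_id[1],
               max_block_sd_um = st$max_block_sd_um,
               mean_distance_um = st$mean_distance_um,
               mean_offset_um = sqrt(ox^2 + oy^2),
               offset_x_um = ox, offset_y_um = oy)
  }))

  ids <- as.integer(names(per))
  edge_devs <- unlist(lapply(seq_len(nrow(net$edges)), function(r) {
    v1 <- net$edges[r, 1]; v2 <- net$edges[r, 2]
    if (!(v1 %in% ids && v2 %in% ids)) return(NULL)
    edge_deviation(per[[as.character(v1)]], per[[as.character(v2)]],
                   block_s = block_s)$deviation_um
  }), use.names = FALSE)
  edge_sd_um <- if (length(edge_devs)) sd(edge_devs) else NA_real_
  gamma_e <- if (length(edge_devs))
    effective_tension(var(edge_devs) * 1e-12, cfg$T_K) else NA_real_

  fs <- 1 / cfg$frame_interval_s
  psd <- average_psds(unlist(lapply(per, function(d) {
    d <- d[order(d$t_s), ]
    list(estimate_psd(d$x_um, fs), estimate_psd(d$y_um, fs))
  }), recursive = FALSE))
  psd_fit <- if (!is.null(passive_bundle)) {
    ptr <- passive_bundle$truth_tracks
    ppsd <- average_psds(unlist(lapply(split(ptr, ptr$vertex_id), function(d) {
      d <- d[order(d$t_s), ]
      list(estimate_psd(d$x_um, fs), estimate_psd(d$y_um, fs))
    }), recursive = FALSE))
    fit_psd_paired(psd, ppsd, T_K = cfg$T_K)
  } else {
    fit_psd(psd, T_K = cfg$T_K, mode = "passive")
  }

  occ_fit <- occupancy_displacement_fit(net, bundle$occupancy, disp)

  corr <- tryCatch(
    displacement_cross_correlation(tracks, block_s = block_s),
    error = function(e) NULL)
  lcorr <- if (!is.null(corr) && nrow(corr) >= 3) correlation_length(corr)
           else NULL
  hotspots <- hotspot_map(tracks, window_s = block_s)

  report <- structure(list(
    condition = cfg$mode,
    n_vertices = length(per),
    qc = qc$report,
    displacement_stats = disp,
    edge_sd_um = edge_sd_um,
    gamma_e_Npm = gamma_e,
    mean_shape_index = mean(shape_stats(net)$shape_index),
    psd = psd, psd_fit = psd_fit,
    occupancy_fit = occ_fit,
    correlation_curve = corr, lcorr = lcorr,
    hotspots = hotspots), class = "foam_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(disp, file.path(out_dir, "displacement_stats.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(psd), file.path(out_dir, "psd.csv"),
              row.names = FALSE)
    if (!is.null(corr))
      write.csv(as.data.frame(corr), file.path(out_dir, "correlation_curve.csv"),
                row.names = FALSE)
    write.csv(hotspots, file.path(out_dir, "hotspots.csv"), row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# track every detected vertex of the first membrane frame through the stack;
# sub-pixel centroid refinement keeps quantization noise below the pixel size
track_stack <- function(stack, net = NULL, roi_half_um = 8, max_jump_um = 10,
                        refine = "centroid") {
  f1 <- stack$frames[[1]][, , 1]
  det <- detect_vertices(f1, stack$pixel_size_um,
                         min_separation_um = roi_half_um)
  if (!nrow(det)) stop("no vertices detected in frame 1")
  if (!is.null(net)) {
    # label detections by the nearest ground-truth vertex id
    gt <- um_to_px(stack, net$vertices$x_um, net$vertices$y_um)
    lab <- vapply(seq_len(nrow(det)), function(i)
      which.min((gt$col - det$col[i])^2 + (gt$row - det$row[i])^2),
      integer(1))
    det$vertex_id <- net$vertices$id[lab]
    det <- det[!duplicated(det$vertex_id), ]
  } else det$vertex_id <- seq_len(nrow(det))
  half <- round(roi_half_um / stack$pixel_size_um)
  d1 <- dim(f1)
  do.call(rbind, lapply(seq_len(nrow(det)), function(i) {
    roi <- c(max(1, round(det$row[i]) - half), min(d1[1], round(det$row[i]) + half),
             max(1, round(det$col[i]) - half), min(d1[2], round(det$col[i]) + half))
    track_vertex(stack, roi, refine = refine, vertex_id = det$vertex_id[i])
  }))
}

# per-vertex vectorial occupancy + zero-intercept displacement-law fit; the
# measured displacement is the offset of the time-averaged position from the
# reference position, projected onto the direction the occupancy imbalance
# predicts (projection is noise-unbiased, unlike the offset magnitude)
occupancy_displacement_fit <- function(net, occupancy, disp) {
  iv <- net$vertices$id[!net$vertices$boundary]
  iv <- intersect(iv, disp$vertex_id)
  rows <- lapply(iv, function(v) {
    comps <- vertex_compartments(net, v)
    if (length(comps) != 3) return(NULL)
    phis <- occupancy$phi[match(comps, occupancy$compartment)]
    p0 <- drop(vertex_xy(net, v))
    sv <- c(0, 0)
    for (k in 1:3) {
      u <- p0 - poly_centroid(compartment_polygon(net, comps[k]))
      sv <- sv + phis[k] * u / sqrt(sum(u^2))
    }
    phi_vec <- sqrt(sum(sv^2))
    i <- match(v, disp$vertex_id)
    proj <- if (phi_vec > 0)
      sum(c(disp$offset_x_um[i], disp$offset_y_um[i]) * sv / phi_vec)
    else sqrt(disp$offset_x_um[i]^2 + disp$offset_y_um[i]^2)
    data.frame(vertex_id = v, phi_vec = phi_vec, displacement_um = proj)
  })
  tab <- do.call(rbind, rows)
  fit <- tryCatch(fit_displacement_slope(tab$phi_vec, tab$displacement_um),
                  error = function(e) NULL)
  R_um <- if (!is.null(fit) && fit$slope_um > 0)
    infer_interaction_radius(fit$slope_um, active_model_params(prefactor = 0.11))
  else NA_real_
  list(table = tab, slope_um = if (is.null(fit)) NA_real_ else fit$slope_um,
       r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
       R_um = R_um)
}

# flat, machine-readable summary of a report
report_summary <- function(report) {
  list(condition = report$condition,
       n_vertices = report$n_vertices,
       mean_shape_index = report$mean_shape_index,
       edge_sd_um = report$edge_sd_um,
       gamma_e_Npm = report$gamma_e_Npm,
       b_uNsm = report$psd_fit$b_Nsm * 1e6,
       f0_hz = report$psd_fit$f0_hz,
       teff_ratio = report$psd_fit$teff_ratio,
       slope_um = report$occupancy_fit$slope_um,
       r_squared = report$occupancy_fit$r_squared,
       R_um = report$occupancy_fit$R_um,
       lcorr_um = if (is.null(report$lcorr)) NA else report$lcorr$lcorr_um,
       max_hotspot_um = max(report$hotspots$max_disp_um))
}

#' @export
print.foam_report <- function(x, ...) {
  s <- report_summary(x)
  cat(sprintf("<foam_report: %s> %d vertices, <s> = %.3f\n", s$condition,
              s$n_vertices, s$mean_shape_index))
  cat(sprintf("  edge SD %.3g um, gamma_e %.3g N/m\n", s$edge_sd_um,
              s$gamma_e_Npm))
  cat(sprintf("  PSD fit: b = %.3g uNs/m, f0 = %.3g Hz, Teff/T = %.3g\n",
              s$b_uNsm, s$f0_hz, s$teff_ratio))
  cat(sprintf("  displacement law: slope %.3g um (R^2 %.2f), R = %.3g um\n",
              s$slope_um, s$r_squared, s$R_um))
  cat(sprintf("  lcorr %.3g um; largest hotspot %.3g um\n",
              s$lcorr_um, s$max_hotspot_um))
  invisible(x)
}

#' Render report figures
#'
#' Writes the standard panels from an analyzed report: vertex fluctuation
#' map, PSD with the fitted spectrum, edge-deviation histogram, displacement
#' versus vectorial occupancy with the zero-intercept fit, correlation curve,
#' and hotspot time series. Panels whose inputs are missing are skipped with
#' a warning.
#'
#' @param report a `foam_report` (from [pipeline_analyze()]).
#' @param out_dir directory for the PNG files.
#' @param tracks optional track table for the edge-deviation histogram panel.
#' @return character vector of files written.
#' @export
pipeline_report <- function(report, out_dir, tracks = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save_panel <- function(p, name) {
    f <- file.path(out_dir, name)
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
    written <<- c(written, f)
  }
  d <- report$displacement_stats
  hs <- report$hotspots
  pos <- stats::aggregate(cbind(x_um, y_um) ~ vertex_id, hs, mean)
  mp <- merge(d, pos, by = "vertex_id")
  save_panel(
    ggplot2::ggplot(mp, ggplot2::aes(x_um, y_um, size = max_block_sd_um,
                                     color = max_block_sd_um)) +
      ggplot2::geom_point() + ggplot2::coord_equal() +
      ggplot2::labs(title = "Vertex fluctuation map",
                    size = "max SD (um)", color = "max SD (um)"),
    "fluctuation_map.png")
  psd <- report$psd
  fitline <- data.frame(
    f_hz = psd$f_hz,
    psd = ou_psd_model(psd$f_hz, report$psd_fit$b_Nsm, report$psd_fit$f0_hz,
                       298 * report$psd_fit$teff_ratio) * 1e12)
  save_panel(
    ggplot2::ggplot(psd, ggplot2::aes(f_hz, psd)) + ggplot2::geom_line() +
      ggplot2::geom_line(data = fitline, color = "red") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(title = "Vertex fluctuation PSD", x = "f (Hz)",
                    y = "PSD (um^2/Hz)"),
    "psd.png")
  ot <- report$occupancy_fit$table
  if (!is.null(ot) && nrow(ot)) {
    save_panel(
      ggplot2::ggplot(ot, ggplot2::aes(phi_vec, displacement_um)) +
        ggplot2::geom_point() +
        ggplot2::geom_abline(slope = report$occupancy_fit$slope_um,
                             intercept = 0, color = "red") +
        ggplot2::labs(title = "Displacement vs vectorial occupancy",
                      x = expression(Phi), y = "mean displacement (um)"),
      "displacement_vs_phi.png")
  } else warning("occupancy panel skipped: no table")
  if (!is.null(report$correlation_curve)) {
    save_panel(
      ggplot2::ggplot(as.data.frame(report$correlation_curve),
                      ggplot2::aes(d_um, correlation)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(title = "Displacement cross-correlation vs distance",
                      x = "d (um)", y = "correlation"),
      "correlation_curve.png")
  } else warning("correlation panel skipped")
  save_panel(
    ggplot2::ggplot(hs, ggplot2::aes(window, vertex_id,
                                     size = max_disp_um, color = max_disp_um)) +
      ggplot2::geom_point() +
      ggplot2::labs(title = "Hotspot time series (60-s windows)"),
    "hotspots.png")
  if (!is.null(tracks)) {
    per <- split(tracks, tracks$vertex_id)
    # pooled edge deviations need the network; histogram of per-vertex blocked
    # radial displacement stands in when only tracks are given
    bl <- do.call(rbind, lapply(per, function(x) block_series(x)))
    save_panel(
      ggplot2::ggplot(data.frame(r = sqrt(bl$dx_um^2 + bl$dy_um^2)),
                      ggplot2::aes(r)) +
        ggplot2::geom_histogram(bins = 40) +
        ggplot2::labs(title = "Blocked displacement distribution",
                      x = "|displacement| (um)"),
      "displacement_hist.png")
  }
  written
}
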