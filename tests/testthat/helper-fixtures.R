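# shared fixtures: all built in code at test time

regular_polygon <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th))
}

hex_polygon_um <- function(circumradius_um = 20) {
  regular_polygon(6, circumradius_um)
}

# a fast-relaxing simulation config (correlation time ~3 s) used where the
# experiment-scale corner frequency (0.9 mHz) would need hours of simulated
# time for converged statistics
fast_cfg <- function(duration_s = 600, seed = 1, teff_ratio = 1, dt_s = 0.25) {
  sim_config(dt_s = dt_s, duration_s = duration_s, sampling_dt_s = 1,
             b_Nsm = 0.5e-6, f0_hz = 0.05, teff_ratio = teff_ratio,
             seed = seed)
}

# offsets of time-averaged positions from the reference network, per vertex
mean_offsets <- function(tracks, net) {
  eq <- net$vertices
  do.call(rbind, lapply(split(tracks, tracks$vertex_id), function(d) {
    i <- match(d$vertex_id[1], eq$id)
    data.frame(vertex_id = d$vertex_id[1],
               max_block_sd_um = NA_real_, mean_distance_um = NA_real_,
               mean_offset_um = sqrt((mean(d$x_um) - eq$x_um[i])^2 +
                                       (mean(d$y_um) - eq$y_um[i])^2),
               offset_x_um = mean(d$x_um) - eq$x_um[i],
               offset_y_um = mean(d$y_um) - eq$y_um[i])
  }))
}

interior_edge <- function(net) {
  int_ids <- net$vertices$id[!net$vertices$boundary]
  ok <- apply(net$edges, 1, function(e)
    all(e %in% int_ids) &&
      length(lipidfoam:::edge_compartments(net, e[1], e[2])) == 2)
  net$edges[which(ok)[1], ]
}

# pooled edge-deviation SD of one interior edge from a track table
edge_sd_of <- function(tracks, v1, v2) {
  per <- split(tracks, tracks$vertex_id)
  if (!all(c(v1, v2) %in% names(per))) return(NULL)
  edge_deviation(per[[as.character(v1)]], per[[as.character(v2)]])$sd_um
}
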