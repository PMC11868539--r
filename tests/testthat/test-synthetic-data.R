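test_that("OU vertex dynamics reproduce equipartition and autocorrelation", {
  # fast-relaxing parameters so ~6000 correlation times fit in one run
  cfg <- sim_config(dt_s = 0.01, duration_s = 2e4, sampling_dt_s = 0.01,
                    b_Nsm = 1e-6, f0_hz = 0.5, teff_ratio = 2, seed = 2)
  tr <- simulate_ou_vertex(cfg, ndim = 1)
  k <- 2 * pi * cfg$f0_hz * cfg$b_Nsm
  var_th <- 1.380649e-23 * cfg$T_K * cfg$teff_ratio / k * 1e12  # um^2
  expect_equal(var(tr$x_um), var_th, tolerance = 0.05)
  ac <- acf(tr$x_um, lag.max = 40, plot = FALSE)$acf
  lags_s <- (0:40) * 0.01
  expect_equal(as.numeric(ac), exp(-2 * pi * cfg$f0_hz * lags_s),
               tolerance = 0.02)
})

test_that("OU dynamics decay deterministically as Teff -> 0", {
  cfg <- sim_config(dt_s = 0.001, duration_s = 2, sampling_dt_s = 0.01,
                    b_Nsm = 1e-6, f0_hz = 1, teff_ratio = 1e-30, seed = 1)
  tr <- simulate_ou_vertex(cfg, ndim = 1, x0_um = 5, stationary_start = FALSE)
  expect_equal(tr$x_um, 5 * exp(-2 * pi * cfg$f0_hz * tr$t_s),
               tolerance = 0.01)
})

test_that("unstable integration steps are refused with a diagnostic", {
  expect_error(sim_config(dt_s = 60, sampling_dt_s = 60, f0_hz = 0.9e-3),
               "unstable dt")
  expect_no_error(sim_config(dt_s = 1, f0_hz = 0.9e-3))
})

test_that("simulators are exactly reproducible under a fixed seed", {
  cfg <- sim_config(dt_s = 0.5, duration_s = 120, seed = 42)
  expect_identical(simulate_ou_vertex(cfg), simulate_ou_vertex(cfg))
  dom <- hex_polygon_um(20)
  a1 <- simulate_abp(dom, 4, dt_s = 0.05, duration_s = 10, seed = 3)
  a2 <- simulate_abp(dom, 4, dt_s = 0.05, duration_s = 10, seed = 3)
  expect_identical(a1$tracks, a2$tracks)
})

test_that("active Brownian particles are ballistic then diffusive", {
  ab <- simulate_abp(NULL, n = 60, v_umps = 3.5, tau_s = 1, dt_s = 0.01,
                     duration_s = 150, seed = 5)
  per <- split(ab$tracks, ab$tracks$particle)
  msd <- function(lag) mean(vapply(per, function(d) {
    dx <- d$x_um[-(1:lag)] - head(d$x_um, -lag)
    dy <- d$y_um[-(1:lag)] - head(d$y_um, -lag)
    mean(dx^2 + dy^2)
  }, numeric(1)))
  expect_equal(msd(5) / (3.5^2 * 0.05^2), 1, tolerance = 0.1)      # t << tau
  t_long <- 40
  expect_equal(msd(t_long * 100) / (2 * 3.5^2 * 1 * t_long), 1,
               tolerance = 0.1)                                     # t >> tau
})

test_that("confined swimmers stay inside and collide often with the walls", {
  dom <- hex_polygon_um(20)  # 40 um across
  ab <- simulate_abp(dom, n = 9, v_umps = 3.5, tau_s = 1, dt_s = 0.05,
                     duration_s = 60, seed = 5, sampling_dt_s = 1)
  inside <- mgcv::in.out(rbind(dom, dom[1, ]),
                         as.matrix(ab$tracks[, c("x_um", "y_um")]))
  expect_true(all(inside))
  expect_equal(length(unique(ab$tracks$particle)), 9)  # count conserved
  expect_gt(nrow(ab$collisions) / 9, 1)  # many collisions per minute
  expect_true(all(c("incidence_deg", "dv_normal_umps") %in%
                    names(ab$collisions)))
  expect_error(simulate_abp(dom, 1, v_umps = 50, dt_s = 0.2, duration_s = 1),
               "dt too large")
})

test_that("occupancy sampling is truncated Poisson with correct area fractions", {
  areas <- rep(400, 5)
  z <- sample_occupancy(0, 2, areas, seed = 1)
  expect_true(all(z$phi == 0))
  one <- sample_occupancy(20, 2, 400, seed = 2)
  expect_equal(one$phi, one$count * 2 / 400)
  big <- sample_occupancy(35, 2, rep(400, 1e4), seed = 3)
  expect_lte(max(big$count), 40)
  # chi-square against the truncated Poisson pmf
  pk <- dpois(0:40, 35); pk <- pk / sum(pk)
  obs <- tabulate(big$count + 1L, nbins = 41)
  keep <- pk * 1e4 >= 5
  chi <- sum((obs[keep] - 1e4 * pk[keep])^2 / (1e4 * pk[keep]))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("network dynamics match the analytic fluctuation covariance", {
  net <- build_hexagonal_lattice(4, 4, 20)
  tr <- simulate_network_dynamics(net, fast_cfg(900), seed = 11)
  vv <- network_vertex_variance(net, attr(tr, "edge_tension_N"), 298)
  eq <- attr(tr, "equilibrium")
  obs <- vapply(split(tr, tr$vertex_id), function(d) {
    i <- match(d$vertex_id[1], eq$id)
    mean((d$x_um - eq$x_um[i])^2 + (d$y_um - eq$y_um[i])^2)
  }, numeric(1))
  pred <- vv$var_um2[match(as.integer(names(obs)), vv$vertex_id)]
  expect_equal(mean(obs / pred), 1, tolerance = 0.15)
})

test_that("equal occupancy of a vertex's three compartments cancels", {
  # a three-compartment "flower": one free junction surrounded by its three
  # hexagons, everything else pinned — exactly C3-symmetric
  full <- build_hexagonal_lattice(2, 2, 20)
  eq <- full$vertices
  int_v <- eq[!eq$boundary, ]
  ctr <- c(mean(eq$x_um), mean(eq$y_um))
  vc <- int_v$id[which.min((int_v$x_um - ctr[1])^2 + (int_v$y_um - ctr[2])^2)]
  comps <- lipidfoam:::vertex_compartments(full, vc)
  expect_length(comps, 3)
  keep_v <- sort(unique(unlist(full$compartments[comps])))
  keep_e <- full$edges[full$edges[, 1] %in% keep_v &
                         full$edges[, 2] %in% keep_v, ]
  verts <- full$vertices[full$vertices$id %in% keep_v, ]
  verts$boundary <- verts$id != vc
  net <- foam_network(verts, keep_e, full$compartments[comps])
  # geometric cancellation of the three equal outward directions
  p0 <- drop(lipidfoam:::vertex_xy(net, vc))
  sv <- Reduce(`+`, lapply(1:3, function(ci) {
    u <- p0 - lipidfoam:::poly_centroid(compartment_polygon(net, ci))
    u / sqrt(sum(u^2))
  }))
  expect_lt(sqrt(sum(sv^2)), 1e-9)
  # all three loaded equally: 95% CI of the mean displacement covers 0
  occ3 <- data.frame(compartment = 1:3, phi = 0.1, count = 20)
  tr <- simulate_network_dynamics(net, fast_cfg(900), occupancy = occ3,
                                  seed = 13)
  d <- tr[tr$vertex_id == vc, ]
  i <- match(vc, eq$id)
  bm_x <- tapply(d$x_um - eq$x_um[i], floor(d$t_s / 60), mean)
  bm_y <- tapply(d$y_um - eq$y_um[i], floor(d$t_s / 60), mean)
  expect_lt(abs(mean(bm_x)), 3 * sd(bm_x) / sqrt(length(bm_x)))
  expect_lt(abs(mean(bm_y)), 3 * sd(bm_y) / sqrt(length(bm_y)))
  # one loaded compartment alone displaces the same vertex measurably away
  occ1 <- data.frame(compartment = 1, phi = 0.1, count = 20)
  tr1 <- simulate_network_dynamics(net, fast_cfg(900), occupancy = occ1,
                                   seed = 13)
  d1 <- tr1[tr1$vertex_id == vc, ]
  off1 <- sqrt((mean(d1$x_um) - eq$x_um[i])^2 + (mean(d1$y_um) - eq$y_um[i])^2)
  off3 <- sqrt((mean(d$x_um) - eq$x_um[i])^2 + (mean(d$y_um) - eq$y_um[i])^2)
  expect_gt(off1, 3 * off3)
  u1 <- p0 - lipidfoam:::poly_centroid(compartment_polygon(net, 1))
  proj <- sum((c(mean(d1$x_um), mean(d1$y_um)) - p0) * u1 / sqrt(sum(u1^2)))
  expect_gt(proj, 0)  # pushed away from the loaded compartment
})

test_that("a single loaded compartment pushes its vertices outward", {
  net <- build_hexagonal_lattice(4, 4, 20)
  occ <- data.frame(compartment = 6, phi = 0.1, count = 20)
  ap <- active_model_params(prefactor = 0.11)
  tr <- simulate_network_dynamics(net, fast_cfg(600), occupancy = occ,
                                  active_params = ap, seed = 12)
  eq <- attr(tr, "equilibrium")
  ctr <- lipidfoam:::poly_centroid(compartment_polygon(net, 6))
  vint <- intersect(net$compartments[[6]], eq$id[!eq$boundary])
  off <- mean_offsets(tr[tr$vertex_id %in% vint, ], net)
  outward <- vapply(seq_len(nrow(off)), function(k) {
    i <- match(off$vertex_id[k], eq$id)
    u <- c(eq$x_um[i], eq$y_um[i]) - ctr
    sum(c(off$offset_x_um[k], off$offset_y_um[k]) * u / sqrt(sum(u^2)))
  }, numeric(1))
  expect_gt(mean(outward), 0)
  expect_equal(mean(outward), predicted_displacement(ap, 0.1),
               tolerance = 0.25)
})

test_that("active vertex variance grows monotonically with occupancy", {
  net <- build_hexagonal_lattice(3, 3, 20)
  vs <- vapply(c(0, 0.02, 0.06), function(p) {
    occ <- if (p > 0)
      data.frame(compartment = seq_along(net$compartments), phi = p, count = 1)
    else NULL
    tr <- simulate_network_dynamics(net, fast_cfg(300), occupancy = occ,
                                    seed = 9)
    mean(vapply(split(tr, tr$vertex_id), function(d)
      var(d$x_um) + var(d$y_um), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("rendered micrographs have bright junctions and recover occupancy", {
  net <- build_hexagonal_lattice(3, 3, 20)
  st <- render_micrograph(net, pixel_size_um = 0.5)
  gt <- attr(st, "vertices_px")
  mem <- st$frames[[1]][, , 1]
  # noise-free: the intensity maximum near each interior vertex is within 1 px
  for (k in which(!net$vertices$boundary)) {
    r0 <- round(gt$row[k]); c0 <- round(gt$col[k])
    win <- mem[(r0 - 4):(r0 + 4), (c0 - 4):(c0 + 4)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(pk - 5)), 1)
  }
  # same seed, noisy render: bit-identical
  n1 <- render_micrograph(net, pixel_size_um = 0.5, noise_level = 10, seed = 7)
  n2 <- render_micrograph(net, pixel_size_um = 0.5, noise_level = 10, seed = 7)
  expect_identical(n1$frames, n2$frames)
  # occupancy round trip at the rendering threshold
  poly <- compartment_polygon(net, 5)
  sw <- simulate_abp(poly, 12, dt_s = 0.05, duration_s = 1, seed = 2,
                     sampling_dt_s = 1)$tracks
  sw <- sw[sw$t_s == 0, c("x_um", "y_um")]
  st2 <- render_micrograph(net, swimmers = sw, pixel_size_um = 0.5)
  occ <- estimate_occupancy(st2$frames[[1]][, , 2],
                            compartment_polygons_px(net, st2),
                            method = "fixed",
                            threshold = attr(st2, "bacteria_threshold"))
  expect_lt(abs(occ$phi[5] - 12 * 2 / lipidfoam:::poly_area(poly)), 0.02)
  expect_true(all(occ$phi[-5] == 0, na.rm = TRUE))
})

test_that("scenario bundles have matched active/heat-killed behaviour", {
  cfg_a <- scenario_config(mode = "active", n_rows = 2, n_cols = 2,
                           duration_s = 120, lambda_swimmers = 10,
                           render = TRUE, seed = 4)
  cfg_p <- scenario_config(mode = "heat-killed", n_rows = 2, n_cols = 2,
                           duration_s = 120, lambda_swimmers = 10,
                           render = TRUE, seed = 4)
  ba <- generate_scenario(cfg_a)
  bp <- generate_scenario(cfg_p)
  # heat-killed: bacteria channel static up to (zero) noise
  expect_equal(bp$stack$frames[[1]][, , 2], bp$stack$frames[[50]][, , 2])
  # active fluctuations exceed the thermal baseline at matched seeds
  sd_of <- function(b) mean(vapply(split(b$truth_tracks,
                                         b$truth_tracks$vertex_id),
                                   function(d) sd(d$x_um) + sd(d$y_um),
                                   numeric(1)))
  expect_gt(sd_of(ba), sd_of(bp))
  # lossless file round trip
  dir <- file.path(tempdir(), "bundle-rt")
  write_scenario_bundle(ba, dir)
  back <- read_scenario_bundle(dir)
  expect_equal(back$truth_tracks$x_um, ba$truth_tracks$x_um)
  expect_equal(back$occupancy, ba$occupancy)
  expect_equal(back$stack$frames[[3]], ba$stack$frames[[3]],
               tolerance = 1e-5)
})
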