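mk_track <- function(x, y = 0, dt = 1, id = 1L) data.frame(
  vertex_id = id, frame = seq_along(x), t_s = (seq_along(x) - 1) * dt,
  x_um = x, y_um = rep_len(y, length(x)), valid = TRUE)

test_that("blocking partitions a 10-min 1 Hz track into ten 60-s blocks", {
  tr <- mk_track(rnorm(600))
  b <- block_series(tr, 60)
  expect_equal(length(unique(b$block)), 10)
  expect_equal(unname(table(b$block)), rep(60L, 10), ignore_attr = TRUE)
  # each block is re-centred exactly
  expect_true(all(abs(tapply(b$dx_um, b$block, mean)) < 1e-12))
  expect_error(block_series(mk_track(rnorm(30)), 60), "shorter")
})

test_that("blocking suppresses slow drift and passes zero signal through", {
  drift <- mk_track(0.05 * (0:599))  # 30 um drift over 10 min
  b <- block_series(drift, 60)
  expect_lt(var(b$dx_um), var(drift$x_um) / 50)
  z <- block_series(mk_track(rep(1.5, 300)), 60)
  expect_true(all(z$dx_um == 0))
})

test_that("displacement statistics scale with the fluctuation amplitude", {
  expect_equal(vertex_displacement_stats(
    block_series(mk_track(rep(2, 120))))$max_block_sd_um, 0)
  set.seed(4)
  x <- rnorm(600); y <- rnorm(600)
  s1 <- vertex_displacement_stats(block_series(mk_track(x, y)))
  s2 <- vertex_displacement_stats(block_series(mk_track(2 * x, 2 * y)))
  expect_equal(s2$max_block_sd_um / s1$max_block_sd_um, 2, tolerance = 1e-9)
  expect_equal(s2$mean_distance_um / s1$mean_distance_um, 2, tolerance = 1e-9)
  # OU fixture: max-block SD concentrates near the stationary radial SD
  cfg <- fast_cfg(duration_s = 600, seed = 8)
  tr <- simulate_ou_vertex(cfg, ndim = 2)
  st <- vertex_displacement_stats(block_series(tr))
  k <- 2 * pi * cfg$f0_hz * cfg$b_Nsm
  sd2d <- sqrt(2 * 1.380649e-23 * cfg$T_K / k) * 1e6
  expect_equal(st$max_block_sd_um, sd2d, tolerance = 0.5)
})

test_that("edge deviations are re-centred per block and broaden with activity", {
  rigid1 <- mk_track(rep(0, 300)); rigid2 <- mk_track(rep(10, 300), id = 2L)
  ed <- edge_deviation(rigid1, rigid2)
  expect_true(all(ed$deviation_um == 0))
  set.seed(2)
  t1 <- mk_track(rnorm(600, sd = 0.5)); t2 <- mk_track(10 + rnorm(600, sd = 0.5), id = 2L)
  ed2 <- edge_deviation(t1, t2)
  expect_lt(abs(mean(ed2$deviation_um)), 1e-12 * ed2$sd_um * 600)
  # active scenario broadens edge-length deviations vs matched heat-killed
  net <- build_hexagonal_lattice(3, 3, 20)
  occ <- data.frame(compartment = seq_along(net$compartments), phi = 0.06,
                    count = 12)
  tra <- simulate_network_dynamics(net, fast_cfg(300), occupancy = occ,
                                   seed = 21)
  trp <- simulate_network_dynamics(net, fast_cfg(300), seed = 21)
  pool_sd <- function(tr) {
    per <- split(tr, tr$vertex_id); ids <- as.integer(names(per))
    sd(unlist(lapply(seq_len(nrow(net$edges)), function(r) {
      v1 <- net$edges[r, 1]; v2 <- net$edges[r, 2]
      if (!(v1 %in% ids && v2 %in% ids)) return(NULL)
      edge_deviation(per[[as.character(v1)]],
                     per[[as.character(v2)]])$deviation_um
    })))
  }
  expect_gt(pool_sd(tra), pool_sd(trp))
})

test_that("Welch spectra satisfy Parseval and find spectral structure", {
  set.seed(1)
  x <- rnorm(2048, sd = 2)
  p <- estimate_psd(x, fs = 1, detrend = FALSE)
  expect_equal(sum(p$psd) / 2048, var(x), tolerance = 0.05)
  ps <- estimate_psd(sin(2 * pi * 0.1 * (1:1000)), fs = 1)
  expect_equal(ps$f_hz[which.max(ps$psd)], 0.1, tolerance = 0.002)
  # OU spectrum: log-log slope -2 above the knee
  cfg <- sim_config(dt_s = 0.02, duration_s = 2000, sampling_dt_s = 0.02,
                    b_Nsm = 1e-6, f0_hz = 0.05, teff_ratio = 1, seed = 3)
  tr <- simulate_ou_vertex(cfg, ndim = 1)
  po <- estimate_psd(tr$x_um, fs = 50, nperseg = 8192)
  hi <- po$f_hz > 0.5 & po$f_hz < 5
  slope <- coef(lm(log10(psd) ~ log10(f_hz), po[hi, ]))[[2]]
  expect_equal(slope, -2, tolerance = 0.2)
  expect_error(estimate_psd(c(1, NA, 3), fs = 1), "uniform")
})

test_that("spectrum fits recover analytic parameters exactly", {
  f <- seq_len(300) / 600
  ana_p <- data.frame(f_hz = f,
                      psd = lipidfoam:::ou_psd_model(f, 0.5e-6, 0.9e-3, 298) * 1e12)
  ana_a <- data.frame(f_hz = f,
                      psd = lipidfoam:::ou_psd_model(f, 0.5e-6, 0.9e-3,
                                                     298 * 6.5) * 1e12)
  fp <- fit_psd(ana_p, T_K = 298, mode = "passive", f_min = min(f),
                f_max = max(f))
  expect_equal(fp$b_Nsm, 0.5e-6, tolerance = 1e-6)
  expect_equal(fp$f0_hz, 0.9e-3, tolerance = 1e-5)
  fa <- fit_psd(ana_a, T_K = 298, mode = "active", b = 0.5e-6,
                f_min = min(f), f_max = max(f))
  expect_equal(fa$teff_ratio, 6.5, tolerance = 1e-6)
  fj <- fit_psd_paired(ana_a, ana_p, T_K = 298, f_min = min(f), f_max = max(f))
  expect_equal(fj$b_Nsm, 0.5e-6, tolerance = 1e-6)
  expect_equal(fj$teff_ratio, 6.5, tolerance = 1e-6)
  expect_equal(fj$f0_hz, 0.9e-3, tolerance = 1e-5)
  # stiffness arithmetic at the fitted parameters
  expect_equal(2 * pi * fj$f0_hz * fj$b_Nsm, 2.83e-9, tolerance = 0.01)
})

test_that("effective tension inverts edge-length variance", {
  expect_equal(effective_tension(1.33e-13, 298), 3.1e-8, tolerance = 0.02)
  expect_equal(effective_tension(0.5e-13), 2 * effective_tension(1e-13))
  # passive network fixture: measured edge variance matches the analytic
  # Hessian covariance, so gamma_e agrees with the generator's stiffness scale
  net <- build_hexagonal_lattice(3, 3, 20)
  tr <- simulate_network_dynamics(net, fast_cfg(900), seed = 31)
  h <- network_hessian(net, attr(tr, "edge_tension_N"))
  Kinv <- solve(h$K) * 1.380649e-23 * 298
  e <- interior_edge(net)
  i1 <- match(e[1], h$ids); i2 <- match(e[2], h$ids)
  p1 <- drop(lipidfoam:::vertex_xy(net, e[1]))
  p2 <- drop(lipidfoam:::vertex_xy(net, e[2]))
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  g <- numeric(nrow(Kinv))
  g[c(2 * i1 - 1, 2 * i1)] <- -u; g[c(2 * i2 - 1, 2 * i2)] <- u
  var_pred_um2 <- drop(g %*% Kinv %*% g) * 1e12
  per <- split(tr, tr$vertex_id)
  L <- {
    d1 <- per[[as.character(e[1])]]; d2 <- per[[as.character(e[2])]]
    sqrt((d1$x_um - d2$x_um)^2 + (d1$y_um - d2$y_um)^2)
  }
  expect_equal(var(L), var_pred_um2, tolerance = 0.3)
  g1 <- effective_tension(var(L) * 1e-12)
  g2 <- effective_tension(var_pred_um2 * 1e-12)
  expect_equal(g1 / g2, 1, tolerance = 0.3)
})

test_that("edge fluctuations broaden with shape index and with activity", {
  nets <- list(ordered = build_hexagonal_lattice(3, 3, 23),
               disordered = build_disordered_foam(16, 0.28, seed = 2))
  run <- function(net, occ, seed) simulate_network_dynamics(
    net, fast_cfg(300), occupancy = occ, seed = seed)
  occ_of <- function(net) data.frame(
    compartment = seq_along(net$compartments), phi = 0.06, count = 12)
  experiments <- list(
    list(net = nets$ordered, tracks = run(nets$ordered, NULL, 1),
         condition = "heat-killed", label = "hk-ordered"),
    list(net = nets$disordered, tracks = run(nets$disordered, NULL, 2),
         condition = "heat-killed", label = "hk-disordered"),
    list(net = nets$ordered, tracks = run(nets$ordered, occ_of(nets$ordered), 1),
         condition = "active", label = "act-ordered"),
    list(net = nets$disordered,
         tracks = run(nets$disordered, occ_of(nets$disordered), 2),
         condition = "active", label = "act-disordered"))
  tab <- fluctuation_vs_shape(experiments)
  expect_equal(nrow(tab), 4)
  hk <- tab[tab$condition == "heat-killed", ]
  expect_gt(hk$shape_index[2], hk$shape_index[1])
  expect_gt(hk$edge_sd_um[2], hk$edge_sd_um[1])
  # activity broadens at every shape index
  act <- tab[tab$condition == "active", ]
  expect_true(all(act$edge_sd_um > hk$edge_sd_um))
  # duplicate experiment gives an identical row
  tab2 <- fluctuation_vs_shape(experiments[c(1, 1)])
  expect_equal(tab2$edge_sd_um[1], tab2$edge_sd_um[2])
})
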