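test_that("hexagonal lattice has honeycomb geometry", {
  h1 <- build_hexagonal_lattice(1, 1, 10)
  ss <- shape_stats(h1, interior_only = FALSE)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$perimeter_um, 60, tolerance = 1e-9)
  expect_equal(ss$area_um2, 3 * sqrt(3) / 2 * 100, tolerance = 1e-9)

  h <- build_hexagonal_lattice(3, 3, 10)
  expect_equal(length(h$compartments), 9)
  expect_no_error(validate_foam_network(h))
  deg <- vertex_degrees(h)
  int_ids <- h$vertices$id[!h$vertices$boundary]
  expect_true(all(deg[as.character(int_ids)] == 3))
  # every interior vertex meets its edges at 120 degrees
  for (v in int_ids) {
    nb <- lipidfoam:::edge_neighbors(h, v)
    p0 <- drop(lipidfoam:::vertex_xy(h, v))
    th <- sort(vapply(nb, function(u) {
      d <- drop(lipidfoam:::vertex_xy(h, u)) - p0
      atan2(d[2], d[1])
    }, numeric(1)))
    ang <- c(diff(th), 2 * pi + th[1] - th[3]) * 180 / pi
    expect_equal(ang, rep(120, 3), tolerance = 1e-6)
  }
  expect_equal(shape_stats(h, FALSE)$shape_index, rep(60 / sqrt(150 * sqrt(3)), 9),
               tolerance = 1e-3)
  expect_error(build_hexagonal_lattice(0, 3, 10), "n_rows")
  expect_error(build_hexagonal_lattice(2, 2, -1), "edge_length")
})

test_that("shape index matches closed forms and is scale invariant", {
  expect_equal(shape_index(build_hexagonal_lattice(1, 1, 5) |>
                             compartment_polygon(1)), 3.722, tolerance = 1e-3)
  expect_equal(shape_index(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 4.0)
  expect_equal(shape_index(regular_polygon(360)), 2 * sqrt(pi), tolerance = 1e-3)
  # scale invariance across random simple polygons
  set.seed(7)
  for (i in 1:20) {
    poly <- regular_polygon(sample(3:12, 1), r = runif(1, 0.5, 50))
    lam <- runif(1, 0.01, 100)
    expect_equal(shape_index(poly * lam), shape_index(poly), tolerance = 1e-12)
  }
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(shape_index(bowtie), "self-intersecting")
})

test_that("disordered foam calibrates against the honeycomb and is deterministic", {
  d0 <- build_disordered_foam(64, 0, seed = 1)
  expect_no_error(validate_foam_network(d0))
  s0 <- shape_stats(d0)
  expect_equal(mean(s0$shape_index), 3.722, tolerance = 1e-3)
  # at zero disorder the interior compartments are the honeycomb cells
  href <- shape_stats(build_hexagonal_lattice(3, 3, 40 / sqrt(3)), FALSE)
  expect_equal(median(s0$area_um2), median(href$area_um2), tolerance = 1e-6)

  d3 <- build_disordered_foam(100, 0.3, seed = 11)
  expect_no_error(validate_foam_network(d3))
  s3 <- mean(shape_stats(d3)$shape_index)
  expect_gt(s3, 3.75); expect_lt(s3, 3.85)
  expect_identical(build_disordered_foam(50, 0.3, seed = 5),
                   build_disordered_foam(50, 0.3, seed = 5))
  expect_error(build_disordered_foam(2, 0.1, seed = 1), "n_cells")
})

test_that("degenerate fourfold junctions are split into three-way junctions", {
  # a square point lattice produces fourfold Voronoi vertices
  pts <- as.matrix(expand.grid(x = (0:3) * 10, y = (0:3) * 10))
  cells <- lipidfoam:::voronoi_cells(pts, c(-5, 35, -5, 35))
  corners <- do.call(rbind, lapply(seq_along(cells), function(i)
    cbind(cells[[i]], i)))
  net <- lipidfoam:::assemble_network_from_cells(
    corners[, 1:2], corners[, 3], merge_tol = 1e-5, bbox = c(-5, 35, -5, 35))
  expect_no_error(validate_foam_network(net))
  deg <- vertex_degrees(net)
  int_ids <- net$vertices$id[!net$vertices$boundary]
  expect_true(all(deg[as.character(int_ids)] == 3))
  # split pairs sit ~1e-6 um apart
  expect_lt(min(edge_lengths(net)), 1e-5)
})

test_that("bilayer tension and contact angle invert each other", {
  expect_equal(bilayer_tension(1.0, 0), 2.0)
  expect_equal(bilayer_tension(1.0, 60), 1.0, tolerance = 1e-12)
  expect_equal(bilayer_tension(1.0, 40), 1.532, tolerance = 1e-3)
  expect_equal(contact_angle(2.0, 1.0), 0)
  expect_equal(contact_angle(1.532, 1.0), 40.0, tolerance = 0.1)
  expect_equal(contact_angle(1.231, 1.0), 52.0, tolerance = 0.1)
  set.seed(3)
  for (i in 1:25) {
    gml <- runif(1, 0.2, 5); phi <- runif(1, 0, 89.9)
    expect_equal(contact_angle(bilayer_tension(gml, phi), gml), phi,
                 tolerance = 1e-9)
  }
  expect_error(bilayer_tension(1, 95), "90")
  expect_error(contact_angle(2.5, 1), "unphysical")
})

test_that("aspiration tension follows the Laplace law", {
  expect_equal(aspiration_tension(0, 2), 0)
  expect_equal(aspiration_tension(3000, 2), 3.0)
  expect_equal(aspiration_tension(-3000, 2), 3.0)  # sign of suction irrelevant
  expect_equal(aspiration_tension(1500, 4), 2 * aspiration_tension(1500, 2))
})

test_that("tension-ratio classification uses the 0.23 and 2 thresholds", {
  expect_equal(stability_ratios(0.1, 1)$regime, "sub-confluent")
  expect_equal(stability_ratios(1.5, 1)$regime, "confluent-jammed")
  expect_equal(stability_ratios(2.0, 1)$regime, "at/above rigidity transition")
  expect_equal(stability_ratios(3, 2)$ratio, 1.5)
})

test_that("vertex force balance is zero at symmetry and restoring off it", {
  h <- build_hexagonal_lattice(3, 3, 10)
  v <- h$vertices$id[!h$vertices$boundary][1]
  f0 <- vertex_net_force(h, 1.0, v)
  expect_lt(f0$magnitude, 1e-12)
  expect_false(f0$boundary)
  # perturb: force points back toward the symmetric position
  i <- match(v, h$vertices$id)
  hp <- h; hp$vertices$x_um[i] <- hp$vertices$x_um[i] + 2
  fp <- vertex_net_force(hp, 1.0, v)
  expect_lt(fp$force[1], 0)
  # oracle: brute-force vector sum with tensions (2, 1, 1)
  nb <- lipidfoam:::edge_neighbors(h, v)
  gam <- setNames(c(2, 1, 1),
                  vapply(nb, function(u) lipidfoam:::edge_key(v, u), ""))
  got <- vertex_net_force(h, gam, v)$force
  p0 <- drop(lipidfoam:::vertex_xy(h, v))
  want <- Reduce(`+`, lapply(seq_along(nb), function(k) {
    d <- drop(lipidfoam:::vertex_xy(h, nb[k])) - p0
    c(2, 1, 1)[k] * d / sqrt(sum(d^2))
  }))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("vertex relaxation reaches the 120-degree Fermat point", {
  anchors <- rbind(c(0, 0), c(30, 5), c(8, 26))
  net <- foam_network(
    data.frame(id = 1:4,
               x_um = c(anchors[, 1], 12), y_um = c(anchors[, 2], 9),
               boundary = c(TRUE, TRUE, TRUE, FALSE)),
    rbind(c(1, 4), c(2, 4), c(3, 4)), list(), validate = FALSE)
  r <- relax_vertex(net, 1.0, 4)
  expect_equal(r$angles_deg, rep(120, 3), tolerance = 0.5)
  # oracle: grid minimization of total edge length on a 0.01 um grid
  grid <- expand.grid(x = seq(5, 20, by = 0.01), y = seq(5, 15, by = 0.01))
  en <- sqrt((grid$x - anchors[1, 1])^2 + (grid$y - anchors[1, 2])^2) +
    sqrt((grid$x - anchors[2, 1])^2 + (grid$y - anchors[2, 2])^2) +
    sqrt((grid$x - anchors[3, 1])^2 + (grid$y - anchors[3, 2])^2)
  best <- grid[which.min(en), ]
  expect_equal(r$position, c(best$x, best$y), tolerance = 0.02,
               ignore_attr = TRUE)
  # dominant tension pulls the vertex onto the strong edge's anchor
  gam <- setNames(c(100, 1, 1), c("1-4", "2-4", "3-4"))
  r2 <- relax_vertex(net, gam, 4)
  expect_lt(sqrt(sum((r2$position - anchors[1, ])^2)), 0.5)
})

test_that("T1 detection finds scripted collapse events only", {
  times <- 0:99
  static <- list("1-2" = rep(10, 100))
  expect_equal(nrow(detect_t1(static, times)), 0)
  scripted <- list("1-2" = c(seq(10, 0.05, length.out = 50),
                             seq(0.05, 10, length.out = 50)))
  ev <- detect_t1(scripted, times)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$time - 49.5), 1)
  expect_equal(nrow(detect_t1(scripted, times, collapse_threshold = 0)), 0)
  # missing frames: collapse inside an NA gap is not reported
  gappy <- scripted
  gappy[["1-2"]][45:55] <- NA
  expect_equal(nrow(detect_t1(gappy, times)), 0)
})

test_that("T1 operator swaps neighbours, conserves topology and involutes", {
  h <- build_hexagonal_lattice(4, 4, 10)
  e <- interior_edge(h)
  before <- lipidfoam:::t1_compartments(h, e[1], e[2])
  h1 <- apply_t1(h, e)
  expect_no_error(validate_foam_network(h1))
  after <- lipidfoam:::t1_compartments(h1, e[1], e[2])
  # flanking and end compartments swap roles
  expect_setequal(after$flanking, c(before$end_a, before$end_b))
  expect_setequal(c(after$end_a, after$end_b), before$flanking)
  expect_equal(length(h1$compartments), length(h$compartments))
  # Euler characteristic V - E + F of the planar subdivision is preserved
  chi <- function(n) nrow(n$vertices) - nrow(n$edges) +
    length(n$compartments) + 1L
  expect_equal(chi(h1), chi(h))
  # involution on topology
  h2 <- apply_t1(h1, e)
  expect_equal(lapply(h2$compartments, sort), lapply(h$compartments, sort))
  eo <- function(m) m[order(m[, 1], m[, 2]), ]
  expect_equal(eo(h2$edges), eo(h$edges))
  # oracle: adjacency recomputed from the polygons agrees with the cycles
  share_edge <- function(net, i, j)
    length(intersect(net$compartments[[i]], net$compartments[[j]])) >= 2
  expect_true(share_edge(h1, before$end_a, before$end_b))
  expect_false(share_edge(h1, before$flanking[1], before$flanking[2]))
  # boundary edge refused
  bnd <- h$edges[apply(h$edges, 1, function(ee)
    any(ee %in% h$vertices$id[h$vertices$boundary])), ][1, ]
  expect_error(apply_t1(h, bnd))
})

test_that("network tables and JSON round-trip losslessly", {
  net <- build_disordered_foam(36, 0.2, seed = 9)
  pre <- file.path(tempdir(), "netio")
  write_foam_network(net, pre)
  back <- read_foam_network(pre)
  expect_equal(back$vertices$x_um, net$vertices$x_um)
  expect_equal(back$edges, net$edges)
  expect_equal(back$compartments, net$compartments)
  jf <- file.path(tempdir(), "net.json")
  foam_network_to_json(net, jf)
  back2 <- foam_network_from_json(jf)
  expect_equal(back2$vertices$y_um, net$vertices$y_um)
  expect_equal(back2$compartments, net$compartments)
})
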