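## Network construction: regular honeycomb and jittered-lattice Voronoi foams.

#' Build a regular hexagonal (honeycomb) foam network
#'
#' Reference geometry for a defect-free lipid foam: `n_rows` x `n_cols`
#' pointy-top regular hexagons of side `edge_length`. Every interior vertex is
#' a three-way junction and every interior compartment has shape index 3.722.
#'
#' @param n_rows,n_cols number of hexagon rows/columns (>= 1).
#' @param edge_length hexagon side length in µm (> 0).
#' @return a [foam_network()]. Vertices shared by fewer than three hexagons
#'   are flagged as boundary.
#' @export
build_hexagonal_lattice <- function(n_rows, n_cols, edge_length) {
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1")
  if (edge_length <= 0) stop("edge_length must be > 0")
  a <- edge_length
  ang <- (30 + 60 * (0:5)) * pi / 180  # pointy-top corners
  corner_dx <- a * cos(ang); corner_dy <- a * sin(ang)
  centers <- do.call(rbind, lapply(seq_len(n_rows) - 1L, function(r) {
    cbind(sqrt(3) * a * (seq_len(n_cols) - 1L + 0.5 * (r %% 2)),
          1.5 * a * r)
  }))
  corners <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(centers[i, 1] + corner_dx, centers[i, 2] + corner_dy, i)))
  assemble_network_from_cells(
    corners[, 1:2], cell_id = corners[, 3], merge_tol = a * 1e-8)
}

#' Build a disordered foam by Voronoi tessellation of a jittered lattice
#'
#' Emulates the packing disorder of an experimentally prepared lipid foam:
#' seed points on a triangular lattice are displaced uniformly within a disk
#' of radius `disorder` times the mean lattice spacing, and their
#' Voronoi cells (clipped to the lattice bounding box) become the compartments.
#' At `disorder = 0` the result is the regular honeycomb (mean interior shape
#' index 3.722); increasing disorder raises the mean shape index towards the
#' rigidity-transition range around 3.8.
#'
#' @param n_cells approximate number of compartments (>= 4); realised as the
#'   nearest feasible rectangular arrangement of lattice points.
#' @param disorder jitter radius as a fraction of the mean seed spacing
#'   (>= 0).
#' @param seed RNG seed (integer) — identical seeds give identical networks.
#' @param spacing_um mean seed spacing in µm (default 40, a typical
#'   compartment diameter).
#' @return a [foam_network()].
#' @export
build_disordered_foam <- function(n_cells, disorder, seed, spacing_um = 40) {
  if (n_cells < 4) stop("n_cells must be >= 4")
  if (disorder < 0) stop("disorder must be >= 0")
  L <- spacing_um
  ncol_ <- max(2L, round(sqrt(n_cells)))
  nrow_ <- max(2L, ceiling(n_cells / ncol_))
  pts <- do.call(rbind, lapply(seq_len(nrow_) - 1L, function(r)
    cbind(L * (seq_len(ncol_) - 1L + 0.5 * (r %% 2)), L * sqrt(3) / 2 * r)))
  set.seed(seed)
  for (attempt in 1:5) {
    r <- disorder * L * sqrt(runif(nrow(pts)))
    th <- runif(nrow(pts), 0, 2 * pi)
    seeds <- pts + cbind(r * cos(th), r * sin(th))
    # degenerate (coincident/collinear) seeds: retry with fresh perturbation
    if (min(dist(seeds)) > 1e-3 * L) break
    if (attempt == 5) stop("could not obtain non-degenerate seed points")
  }
  bbox <- c(min(seeds[, 1]), max(seeds[, 1]), min(seeds[, 2]), max(seeds[, 2]))
  cells <- voronoi_cells(seeds, bbox)
  keep <- lengths(cells) > 0
  cells <- cells[keep]
  corners <- do.call(rbind, lapply(seq_along(cells), function(i)
    cbind(cells[[i]], i)))
  assemble_network_from_cells(corners[, 1:2], cell_id = corners[, 3],
                              merge_tol = L * 1e-6, bbox = bbox)
}

## Voronoi by half-plane clipping: each seed's cell is the bounding box
## successively clipped by the perpendicular bisectors against all other
## seeds. O(n^2) but robust and dependency-free at the scales used here.
voronoi_cells <- function(seeds, bbox) {
  box <- rbind(c(bbox[1], bbox[3]), c(bbox[2], bbox[3]),
               c(bbox[2], bbox[4]), c(bbox[1], bbox[4]))
  n <- nrow(seeds)
  lapply(seq_len(n), function(i) {
    poly <- box
    p <- seeds[i, ]
    d2 <- rowSums((seeds - matrix(p, n, 2, byrow = TRUE))^2)
    for (j in order(d2)[-1]) {
      if (nrow(poly) < 3) break
      q <- seeds[j, ]
      poly <- clip_halfplane(poly, (p + q) / 2, q - p)
    }
    if (is.null(poly) || nrow(poly) < 3) matrix(numeric(0), 0, 2) else poly
  })
}

# keep the part of (ccw) polygon with (x - m) . nrm <= 0  (Sutherland-Hodgman)
clip_halfplane <- function(poly, m, nrm) {
  n <- nrow(poly)
  s <- drop((poly - matrix(m, n, 2, byrow = TRUE)) %*% nrm)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (s[i] <= 0) out <- rbind(out, poly[i, ])
    if ((s[i] < 0 && s[j] > 0) || (s[i] > 0 && s[j] < 0)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

## Merge per-cell corner lists into a shared-vertex network. Vertices closer
## than merge_tol collapse to one junction; interior junctions that would end
## with degree 4 (degenerate, e.g. four co-circular seeds) are split into two
## degree-3 vertices 1e-6 µm apart to preserve the three-way-junction
## invariant.
assemble_network_from_cells <- function(corners, cell_id, merge_tol,
                                        bbox = NULL) {
  corners <- as.matrix(corners)
  # union-find clustering of near-coincident corners
  grp <- cluster_points(corners, merge_tol)
  pos <- cbind(tapply(corners[, 1], grp, mean), tapply(corners[, 2], grp, mean))
  ids <- seq_len(nrow(pos))
  cycles <- lapply(split(seq_len(nrow(corners)), cell_id), function(rows) {
    cyc <- grp[rows]
    cyc[c(TRUE, cyc[-1] != cyc[-length(cyc)])]  # drop tol-collapsed repeats
  })
  cycles <- lapply(cycles, function(cyc) {
    if (length(cyc) > 1 && cyc[1] == cyc[length(cyc)]) cyc[-length(cyc)] else cyc
  })
  names(cycles) <- NULL
  edges <- unique(do.call(rbind, lapply(cycles, function(cyc) {
    t(apply(cbind(cyc, c(cyc[-1], cyc[1])), 1, sort))
  })))
  # boundary: vertex used by fewer than three compartments, or on the bbox
  ncomp <- table(factor(unlist(lapply(cycles, unique)), levels = ids))
  boundary <- as.integer(ncomp) < 3L
  if (!is.null(bbox)) {
    tol <- merge_tol * 10
    on_box <- pos[, 1] < bbox[1] + tol | pos[, 1] > bbox[2] - tol |
      pos[, 2] < bbox[3] + tol | pos[, 2] > bbox[4] - tol
    boundary <- boundary | on_box
  }
  net <- list(vertices = data.frame(id = ids, x_um = pos[, 1], y_um = pos[, 2],
                                    boundary = boundary),
              edges = edges, compartments = cycles)
  net <- split_degenerate_vertices(net)
  foam_network(net$vertices, net$edges, net$compartments)
}

cluster_points <- function(xy, tol) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(xy[, 1])
  x <- xy[ord, 1]
  for (a in seq_len(n - 1)) {
    b <- a + 1
    while (b <= n && x[b] - x[a] <= tol) {
      if (abs(xy[ord[b], 2] - xy[ord[a], 2]) <= tol &&
          sum((xy[ord[b], ] - xy[ord[a], ])^2) <= tol^2) {
        ra <- find(ord[a]); rb <- find(ord[b])
        if (ra != rb) parent[rb] <- ra
      }
      b <- b + 1
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## Split any interior degree-4 vertex into two degree-3 vertices joined by a
## short edge; compartment cycles are rewired consistently.
split_degenerate_vertices <- function(net) {
  repeat {
    deg <- table(factor(c(net$edges[, 1], net$edges[, 2]),
                        levels = net$vertices$id))
    v4 <- net$vertices$id[!net$vertices$boundary &
                            as.integer(deg) >= 4L]
    if (!length(v4)) return(net)
    net <- split_one_vertex(net, v4[1])
  }
}

split_one_vertex <- function(net, v) {
  vi <- match(v, net$vertices$id)
  vpos <- c(net$vertices$x_um[vi], net$vertices$y_um[vi])
  nb <- setdiff(as.vector(net$edges[net$edges[, 1] == v | net$edges[, 2] == v, ]), v)
  nbi <- match(nb, net$vertices$id)
  th <- atan2(net$vertices$y_um[nbi] - vpos[2], net$vertices$x_um[nbi] - vpos[1])
  nb <- nb[order(th)]; th <- sort(th)
  # pair the first two and last two neighbours (by angle) onto the two halves
  own <- setNames(rep(c(1L, 2L), each = 2)[seq_along(nb)], nb)
  dirs <- cbind(cos(th), sin(th))
  u1 <- colSums(dirs[own == 1L, , drop = FALSE]); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- colSums(dirs[own == 2L, , drop = FALSE]); u2 <- u2 / sqrt(sum(u2^2))
  delta <- 5e-7
  id2 <- max(net$vertices$id) + 1L
  net$vertices$x_um[vi] <- vpos[1] + delta * u1[1]
  net$vertices$y_um[vi] <- vpos[2] + delta * u1[2]
  net$vertices <- rbind(net$vertices,
                        data.frame(id = id2, x_um = vpos[1] + delta * u2[1],
                                   y_um = vpos[2] + delta * u2[2],
                                   boundary = FALSE))
  owner <- function(u) if (own[as.character(u)] == 1L) v else id2
  e <- net$edges
  for (r in which(e[, 1] == v | e[, 2] == v)) {
    other <- setdiff(e[r, ], v)
    e[r, ] <- sort(c(other, owner(other)))
  }
  net$edges <- rbind(e, sort(c(v, id2)))
  net$compartments <- lapply(net$compartments, function(cyc) {
    k <- which(cyc == v)
    if (!length(k)) return(cyc)
    nc <- length(cyc)
    p <- cyc[if (k == 1) nc else k - 1]; s <- cyc[if (k == nc) 1 else k + 1]
    rep_with <- unique(c(owner(p), owner(s)))
    append(cyc[-k], rep_with, after = k - 1)
  })
  net
}
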