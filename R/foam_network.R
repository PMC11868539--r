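#' Foam network of bilayer-bound compartments
#'
#' A `foam_network` is a planar graph describing a two-dimensional lipid foam:
#' vertices are the three-way junctions where bilayer films meet, edges are the
#' bilayer segments between junctions, and compartments are the polygonal
#' aqueous cells bounded by edges. Interior vertices have degree exactly 3;
#' vertices on the clipped boundary of the field of view are flagged.
#'
#' @param vertices data.frame with columns `id` (integer), `x_um`, `y_um`
#'   (positions in micrometres) and logical `boundary`.
#' @param edges two-column matrix or data.frame of vertex ids (unordered
#'   pairs).
#' @param compartments list of integer vectors, each an ordered cycle of
#'   vertex ids tracing a simple polygon.
#' @param validate check invariants (degree-3 interior vertices, positive edge
#'   lengths, finite positions, simple polygons)?
#'
#' @return An object of class `foam_network` with elements `vertices`,
#'   `edges` (2-column integer matrix, rows sorted pairs) and `compartments`.
#' @export
foam_network <- function(vertices, edges, compartments, validate = TRUE) {
  stopifnot(all(c("id", "x_um", "y_um", "boundary") %in% names(vertices)))
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  dimnames(edges) <- list(NULL, c("v1", "v2"))
  net <- structure(
    list(vertices = as.data.frame(vertices),
         edges = edges,
         compartments = lapply(compartments, as.integer)),
    class = "foam_network")
  if (validate) validate_foam_network(net)
  net
}

#' Validate foam network invariants
#'
#' Checks that positions are finite, all edge lengths positive, every interior
#' (non-boundary) vertex has degree exactly 3, and all compartment polygons are
#' simple.
#'
#' @param net a [foam_network()].
#' @return `net`, invisibly; errors on violation.
#' @export
validate_foam_network <- function(net) {
  v <- net$vertices
  if (!all(is.finite(v$x_um)) || !all(is.finite(v$y_um)))
    stop("non-finite vertex positions")
  if (anyDuplicated(v$id)) stop("duplicate vertex ids")
  len <- edge_lengths(net)
  if (any(len <= 0)) stop("non-positive edge length")
  deg <- vertex_degrees(net)
  interior <- v$id[!v$boundary]
  bad <- interior[deg[as.character(interior)] != 3L]
  if (length(bad))
    stop("interior vertices without degree 3: ", paste(bad, collapse = ", "))
  for (i in seq_along(net$compartments)) {
    poly <- compartment_polygon(net, i)
    if (!is_simple_polygon(poly))
      stop("compartment ", i, " polygon is not simple")
  }
  invisible(net)
}

#' @export
print.foam_network <- function(x, ...) {
  cat(sprintf("<foam_network> %d vertices (%d interior), %d edges, %d compartments\n",
              nrow(x$vertices), sum(!x$vertices$boundary),
              nrow(x$edges), length(x$compartments)))
  invisible(x)
}

vertex_xy <- function(net, ids) {
  idx <- match(ids, net$vertices$id)
  cbind(x = net$vertices$x_um[idx], y = net$vertices$y_um[idx])
}

#' Vertex degrees
#' @param net a [foam_network()].
#' @return named integer vector, names are vertex ids.
#' @export
vertex_degrees <- function(net) {
  ids <- net$vertices$id
  tab <- table(factor(c(net$edges[, 1], net$edges[, 2]), levels = ids))
  setNames(as.integer(tab), as.character(ids))
}

#' Edge lengths in micrometres
#' @param net a [foam_network()].
#' @return numeric vector, one entry per row of `net$edges`.
#' @export
edge_lengths <- function(net) {
  p1 <- vertex_xy(net, net$edges[, 1])
  p2 <- vertex_xy(net, net$edges[, 2])
  sqrt(rowSums((p1 - p2)^2))
}

#' Compartment polygon coordinates
#' @param net a [foam_network()].
#' @param i compartment index.
#' @return two-column matrix of vertex coordinates (µm), one row per cycle
#'   vertex, not closed.
#' @export
compartment_polygon <- function(net, i) {
  vertex_xy(net, net$compartments[[i]])
}

incident_edges <- function(net, vid) {
  which(net$edges[, 1] == vid | net$edges[, 2] == vid)
}

edge_neighbors <- function(net, vid) {
  e <- net$edges[incident_edges(net, vid), , drop = FALSE]
  setdiff(as.vector(e), vid)
}

# which compartments contain vertex vid in their cycle
vertex_compartments <- function(net, vid) {
  which(vapply(net$compartments, function(cyc) vid %in% cyc, logical(1)))
}

# compartments flanking an edge (sharing both endpoints consecutively)
edge_compartments <- function(net, v1, v2) {
  which(vapply(net$compartments, function(cyc) {
    n <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    any((cyc == v1 & nxt == v2) | (cyc == v2 & nxt == v1))
  }, logical(1)))
}

## ---- polygon primitives ----------------------------------------------------

poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

poly_perimeter <- function(xy) {
  d <- xy - xy[c(2:nrow(xy), 1), ]
  sum(sqrt(rowSums(d^2)))
}

poly_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(xy[idx[i, 1], ], xy[idx[i, 2], ],
                             xy[idx[j, 1], ], xy[idx[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

## ---- shape statistics ------------------------------------------------------

#' Shape index of a polygonal compartment
#'
#' The dimensionless shape index \eqn{s = p/\sqrt{A}} with perimeter \eqn{p}
#' and area \eqn{A}. A regular hexagon has \eqn{s = 3.722}; the isoperimetric
#' bound is \eqn{2\sqrt{\pi} \approx 3.545}; \eqn{s \approx 3.81} marks the
#' density-independent rigidity transition of vertex models.
#'
#' @param polygon two-column matrix of polygon vertex coordinates (not closed),
#'   in any length unit — `s` is scale invariant.
#' @return shape index (dimensionless).
#' @export
shape_index <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (!is_simple_polygon(polygon)) stop("polygon is self-intersecting")
  A <- poly_area(polygon)
  if (A <= 0) stop("polygon has non-positive area")
  poly_perimeter(polygon) / sqrt(A)
}

#' Per-compartment shape statistics
#'
#' @param net a [foam_network()].
#' @param interior_only drop compartments touching a boundary vertex (clipped
#'   polygons are artifacts of the field of view)? Default `TRUE`.
#' @return data.frame with columns `compartment`, `perimeter_um`, `area_um2`,
#'   `shape_index`, `interior`.
#' @export
shape_stats <- function(net, interior_only = TRUE) {
  bnd_ids <- net$vertices$id[net$vertices$boundary]
  rows <- lapply(seq_along(net$compartments), function(i) {
    poly <- compartment_polygon(net, i)
    data.frame(compartment = i,
               perimeter_um = poly_perimeter(poly),
               area_um2 = poly_area(poly),
               shape_index = shape_index(poly),
               interior = !any(net$compartments[[i]] %in% bnd_ids))
  })
  out <- do.call(rbind, rows)
  if (interior_only) out <- out[out$interior, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- I/O -------------------------------------------------------------------

#' Write / read a foam network as plain-text tables
#'
#' Writes `<prefix>_vertices.csv` (id, x_um, y_um, boundary),
#' `<prefix>_edges.txt` (whitespace-separated vertex-id pairs) and
#' `<prefix>_compartments.csv` (compartment_id, vertex_id, position in cycle).
#'
#' @param net a [foam_network()].
#' @param prefix file path prefix.
#' @return `write_foam_network`: the three file paths, invisibly.
#' @export
write_foam_network <- function(net, prefix) {
  vf <- paste0(prefix, "_vertices.csv")
  ef <- paste0(prefix, "_edges.txt")
  cf <- paste0(prefix, "_compartments.csv")
  write.csv(net$vertices, vf, row.names = FALSE)
  write(t(net$edges), ef, ncolumns = 2)
  comp <- do.call(rbind, lapply(seq_along(net$compartments), function(i)
    data.frame(compartment_id = i,
               vertex_id = net$compartments[[i]],
               position = seq_along(net$compartments[[i]]))))
  write.csv(comp, cf, row.names = FALSE)
  invisible(c(vf, ef, cf))
}

#' @rdname write_foam_network
#' @export
read_foam_network <- function(prefix) {
  v <- read.csv(paste0(prefix, "_vertices.csv"))
  e <- as.matrix(read.table(paste0(prefix, "_edges.txt")))
  comp <- read.csv(paste0(prefix, "_compartments.csv"))
  cycles <- lapply(split(comp, comp$compartment_id), function(d)
    d$vertex_id[order(d$position)])
  names(cycles) <- NULL
  foam_network(v, e, cycles)
}

#' JSON round trip of a foam network
#' @param net a [foam_network()].
#' @param path JSON file path.
#' @return `foam_network_to_json`: `path` invisibly;
#'   `foam_network_from_json`: the network.
#' @export
foam_network_to_json <- function(net, path) {
  jsonlite::write_json(
    list(vertices = net$vertices,
         edges = as.data.frame(net$edges),
         compartments = net$compartments),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname foam_network_to_json
#' @export
foam_network_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  foam_network(obj$vertices, as.matrix(obj$edges), obj$compartments)
}
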