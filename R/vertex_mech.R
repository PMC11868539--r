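## Force balance and relaxation at three-way junctions.

edge_tension_lookup <- function(net, edge_tensions) {
  key <- paste(net$edges[, 1], net$edges[, 2], sep = "-")
  if (is.null(names(edge_tensions))) {
    if (length(edge_tensions) == 1L)
      return(setNames(rep(edge_tensions, nrow(net$edges)), key))
    stopifnot(length(edge_tensions) == nrow(net$edges))
    return(setNames(edge_tensions, key))
  }
  edge_tensions
}

edge_key <- function(v1, v2) paste(pmin(v1, v2), pmax(v1, v2), sep = "-")

#' Net tension force on a junction vertex
#'
#' Each bilayer edge pulls the vertex towards its far endpoint with a force of
#' magnitude equal to the edge tension (per unit height of the quasi-2D film).
#' The net force is the vector sum over incident edges; it vanishes when equal
#' tensions meet at 120 degrees.
#'
#' @param net a [foam_network()].
#' @param edge_tensions a single number (uniform tension), an unnamed vector
#'   matching `net$edges` rows, or a vector named `"v1-v2"` (sorted ids).
#' @param vertex vertex id.
#' @return list with `force` (length-2 vector, tension units), `magnitude`,
#'   and `boundary` (TRUE if the vertex has degree < 3 — force still
#'   returned).
#' @export
vertex_net_force <- function(net, edge_tensions, vertex) {
  gam <- edge_tension_lookup(net, edge_tensions)
  nb <- edge_neighbors(net, vertex)
  if (!length(nb)) stop("vertex ", vertex, " has no incident edges")
  p0 <- drop(vertex_xy(net, vertex))
  f <- c(0, 0)
  for (u in nb) {
    d <- drop(vertex_xy(net, u)) - p0
    f <- f + gam[[edge_key(vertex, u)]] * d / sqrt(sum(d^2))
  }
  list(force = f, magnitude = sqrt(sum(f^2)), boundary = length(nb) < 3L)
}

#' Relax a junction vertex to mechanical equilibrium
#'
#' Gradient descent on the tension energy \eqn{E = \sum_i \gamma_i L_i} over
#' the position of one vertex, with the far endpoints of its three incident
#' edges pinned. At equal tensions the equilibrium is the Fermat point of the
#' pinned triangle, where the three edges meet at 120 degrees.
#'
#' @inheritParams vertex_net_force
#' @param step initial step size in µm.
#' @param tol convergence tolerance on displacement per iteration, µm.
#' @param max_iter iteration cap.
#' @return list with `position` (µm), `angles_deg` (the three inter-edge
#'   angles at equilibrium), `energy`, `iterations`, `converged`.
#' @export
relax_vertex <- function(net, edge_tensions, vertex, step = 0.5, tol = 1e-9,
                         max_iter = 20000) {
  gam <- edge_tension_lookup(net, edge_tensions)
  nb <- edge_neighbors(net, vertex)
  if (length(nb) != 3L) stop("relax_vertex needs a degree-3 vertex")
  anchors <- vertex_xy(net, nb)
  g <- vapply(nb, function(u) gam[[edge_key(vertex, u)]], numeric(1))
  energy <- function(p) sum(g * sqrt(rowSums((anchors - matrix(p, 3, 2, byrow = TRUE))^2)))
  p <- drop(vertex_xy(net, vertex))
  e <- energy(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- anchors - matrix(p, 3, 2, byrow = TRUE)
    len <- pmax(sqrt(rowSums(d^2)), 1e-12)
    f <- colSums(g * d / len)             # -grad E
    pn <- p + step * f
    en <- energy(pn)
    if (en < e) {
      moved <- sqrt(sum((pn - p)^2))
      p <- pn; e <- en
      if (moved < tol) { converged <- TRUE; break }
    } else {
      step <- step / 2
      if (step < tol / 10) { converged <- TRUE; break }
    }
  }
  if (!converged)
    stop(sprintf("relax_vertex did not converge (last step %.3g, |F| %.3g)",
                 step, sqrt(sum(f^2))))
  d <- anchors - matrix(p, 3, 2, byrow = TRUE)
  th <- atan2(d[, 2], d[, 1])
  th <- sort(th)
  ang <- c(diff(th), 2 * pi + th[1] - th[3]) * 180 / pi
  list(position = p, angles_deg = ang, energy = e, iterations = it,
       converged = converged)
}
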