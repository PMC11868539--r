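## T1 topological transitions: detection in edge-length time series and the
## topology operator on the network.

#' Detect T1 transitions in edge-length time series
#'
#' A T1 transition is flagged when an edge length drops strictly below
#' `collapse_threshold` and subsequently re-expands above it (the collapsed
#' edge re-forms in the perpendicular direction, swapping neighbouring
#' compartments). Missing frames (NA) restrict the search to contiguous runs.
#'
#' @param edge_series named list of numeric edge-length series (µm), all
#'   sampled on a common clock.
#' @param times time stamps (s), one per frame.
#' @param collapse_threshold collapse threshold in µm (default 0.5, well below
#'   the 20--50 µm compartment scale and above tracking noise).
#' @param net optional [foam_network()]; if supplied and the list names are
#'   `"v1-v2"` edge keys, each event is annotated with the four involved
#'   compartments (two flanking, two end).
#' @return data.frame with columns `edge`, `time`, `min_length_um`, and (if
#'   annotated) `compartments` (list column).
#' @export
detect_t1 <- function(edge_series, times, collapse_threshold = 0.5,
                      net = NULL) {
  events <- list()
  for (nm in names(edge_series)) {
    x <- edge_series[[nm]]
    ok <- !is.na(x)
    runs <- split(seq_along(x)[ok], cumsum(!ok)[ok])
    for (run in runs) {
      xi <- x[run]
      below <- xi < collapse_threshold
      if (!any(below)) next
      # runs of consecutive below-threshold frames
      grp <- cumsum(c(TRUE, diff(below) != 0))
      for (g in unique(grp[below])) {
        idx <- which(grp == g & below)
        after <- idx[length(idx)] + 1
        if (after > length(xi) || xi[after] < collapse_threshold) next
        kmin <- idx[which.min(xi[idx])]
        ev <- data.frame(edge = nm, time = times[run[kmin]],
                         min_length_um = xi[kmin],
                         stringsAsFactors = FALSE)
        if (!is.null(net)) {
          vv <- as.integer(strsplit(nm, "-", fixed = TRUE)[[1]])
          ev$compartments <- I(list(t1_compartments(net, vv[1], vv[2])))
        }
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  if (!length(events))
    return(data.frame(edge = character(0), time = numeric(0),
                      min_length_um = numeric(0)))
  do.call(rbind, events)
}

# the four compartments involved in a T1 on edge (a, b):
# two flanking (share the edge) and two end (touch only one endpoint)
t1_compartments <- function(net, a, b) {
  flank <- edge_compartments(net, a, b)
  at_a <- setdiff(vertex_compartments(net, a), flank)
  at_b <- setdiff(vertex_compartments(net, b), flank)
  list(flanking = flank, end_a = at_a, end_b = at_b)
}

#' Apply a T1 transition to a foam network
#'
#' Rotates the interior edge `(a, b)`: the two compartments that shared the
#' edge become second neighbours and the two end compartments become
#' edge-sharing. Degree-3 connectivity and the compartment count are
#' preserved; vertex positions are rotated 90 degrees about the edge midpoint
#' and the re-formed edge starts short (fraction `relength` of the collapsed
#' edge, as after a physical T1 where the edge shrinks to a point and
#' re-expands perpendicular), which keeps the new polygons simple.
#'
#' @param net a [foam_network()].
#' @param edge length-2 vector of vertex ids of an interior edge.
#' @param rotate_positions rotate the endpoint positions (default TRUE)?
#' @param relength initial length of the re-formed edge as a fraction of the
#'   original edge length (default 0.3).
#' @return the modified [foam_network()].
#' @export
apply_t1 <- function(net, edge, rotate_positions = TRUE, relength = 0.3) {
  a <- edge[1]; b <- edge[2]
  flank <- edge_compartments(net, a, b)
  if (length(flank) != 2L)
    stop("edge (", a, ",", b, ") is not interior: needs two flanking compartments")
  inv <- t1_compartments(net, a, b)
  if (length(inv$end_a) != 1L || length(inv$end_b) != 1L)
    stop("edge (", a, ",", b, ") endpoints are on the boundary")
  C1 <- flank[1]; C2 <- flank[2]; Da <- inv$end_a; Db <- inv$end_b
  nb_in <- function(comp, v) {
    cyc <- net$compartments[[comp]]
    k <- which(cyc == v); n <- length(cyc)
    c(cyc[if (k == 1) n else k - 1], cyc[if (k == n) 1 else k + 1])
  }
  u <- setdiff(nb_in(C1, a), b)  # a's other neighbour in C1
  w <- setdiff(nb_in(C2, a), b)
  x <- setdiff(nb_in(C1, b), a)
  y <- setdiff(nb_in(C2, b), a)
  stopifnot(length(u) == 1, length(w) == 1, length(x) == 1, length(y) == 1)
  # rewire: remove a-w and b-x, add a-x and b-w; a-b persists
  keys <- edge_key(net$edges[, 1], net$edges[, 2])
  drop <- keys %in% c(edge_key(a, w), edge_key(b, x))
  edges <- rbind(net$edges[!drop, , drop = FALSE],
                 rbind(sort(c(a, x)), sort(c(b, w))))
  comps <- net$compartments
  comps[[C1]] <- setdiff_keep(comps[[C1]], b)
  comps[[C2]] <- setdiff_keep(comps[[C2]], a)
  comps[[Da]] <- insert_before(comps[[Da]], at = a, from = w, value = b)
  comps[[Db]] <- insert_before(comps[[Db]], at = b, from = x, value = a)
  verts <- net$vertices
  if (rotate_positions) {
    ia <- match(a, verts$id); ib <- match(b, verts$id)
    pa <- c(verts$x_um[ia], verts$y_um[ia]); pb <- c(verts$x_um[ib], verts$y_um[ib])
    m <- (pa + pb) / 2; h <- (pa - pb) / 2 * relength
    hp <- c(-h[2], h[1])
    # after the swap `a` keeps both its C1-side neighbours: place it on C1's side
    c1c <- poly_centroid(compartment_polygon(net, C1))
    if (sum(hp * (c1c - m)) < 0) hp <- -hp
    verts$x_um[ia] <- m[1] + hp[1]; verts$y_um[ia] <- m[2] + hp[2]
    verts$x_um[ib] <- m[1] - hp[1]; verts$y_um[ib] <- m[2] - hp[2]
  }
  foam_network(verts, edges, comps, validate = FALSE)
}

setdiff_keep <- function(cyc, v) cyc[cyc != v]

# insert `value` into the cycle adjacent to `at`, on the side of neighbour
# `from` (i.e. between `from` and `at`)
insert_before <- function(cyc, at, from, value) {
  n <- length(cyc)
  k <- which(cyc == at)
  prev <- cyc[if (k == 1) n else k - 1]
  if (prev == from) append(cyc, value, after = k - 1)
  else append(cyc, value, after = k)
}
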