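## Bacterial occupancy of compartments.

#' Sample per-compartment swimmer counts and area fractions
#'
#' Encapsulation loads compartments stochastically: counts are Poisson with
#' mean `lambda`, truncated at `max_count` (40, the observed upper range), and
#' the occupancy of compartment n is
#' \eqn{\Phi_n = \min(1, count \cdot footprint / A_n)}.
#'
#' @param lambda mean swimmer count per compartment (>= 0).
#' @param footprint_um2 projected area of one swimmer (µm²), default 2 (a
#'   rod of roughly 0.8 x 2.5 µm).
#' @param areas_um2 compartment areas (µm²).
#' @param seed integer RNG seed.
#' @param max_count truncation of the count distribution, default 40.
#' @return data.frame with `compartment`, `count`, `phi` (in [0, 1]).
#' @export
sample_occupancy <- function(lambda, footprint_um2 = 2, areas_um2, seed = 1L,
                             max_count = 40L) {
  stopifnot(lambda >= 0, footprint_um2 > 0, all(areas_um2 > 0))
  set.seed(seed)
  n <- length(areas_um2)
  counts <- rpois(n, lambda)
  # truncated (not censored) Poisson: redraw values above the cut
  while (any(bad <- counts > max_count))
    counts[bad] <- rpois(sum(bad), lambda)
  phi <- pmin(1, counts * footprint_um2 / areas_um2)
  data.frame(compartment = seq_len(n), count = counts, phi = phi)
}
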