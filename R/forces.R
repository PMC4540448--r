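# Deterministic force field: scalar force laws plus the full field over a
# configuration (evaluated by the compiled core).

#' Excluded-volume repulsion between two particles
#'
#' Soft pairwise repulsion acting on the surface gap `d`: magnitude
#' `eps * (L_r / d - 1)` for `0 < d <= L_r`, exactly zero beyond the range
#' `L_r`. The force diverges as the surfaces approach contact, so `d <= 0`
#' is treated as an integration failure.
#'
#' @param d surface distance(s), nm.
#' @param eps repulsion scale, pN.
#' @param L_r repulsion range, nm.
#' @return Repulsive force magnitude(s) in pN (non-negative).
#' @examples
#' repulsion_force(121.2 / 2, 0.5, 121.2) # 0.5 pN
#' repulsion_force(121.2, 0.5, 121.2)     # 0 at the cutoff
#' @export
repulsion_force <- function(d, eps = 0.5, L_r = 121.2) {
  if (any(d <= 0)) {
    stop("contact: surface distance must be positive for the repulsion law")
  }
  ifelse(d <= L_r, eps * (L_r / d - 1), 0)
}

#' Motor spring force between a bonded cargo and its microtubule
#'
#' Zero-rest-length elastic coupling through the motor cross-bridge:
#' attractive magnitude `kappa * d` for surface gaps `0 <= d <= R_b`, zero
#' beyond the binding radius (the bond itself persists; only the force
#' vanishes).
#'
#' @param d surface distance(s), nm.
#' @param kappa spring constant, pN/nm.
#' @param R_b binding radius, nm.
#' @return Attractive force magnitude(s) in pN.
#' @examples
#' spring_force(50, 0.18, 80)  # 9 pN
#' spring_force(100, 0.18, 80) # 0 beyond the binding radius
#' @export
spring_force <- function(d, kappa = 0.18, R_b = 80) {
  ifelse(d >= 0 & d <= R_b, kappa * d, 0)
}

#' Boundary confinement force (disk domain)
#'
#' The axonal membrane repels a particle whose surface gap to the boundary,
#' `d_B = R0 - |x| - r`, falls below the repulsion range: inward magnitude
#' `eps * (L_r / d_B - 1)`, zero further in.
#'
#' @param x length-2 particle center (nm), relative to the axis.
#' @param r particle radius (nm).
#' @param R0 domain radius (nm).
#' @param eps repulsion scale, pN.
#' @param L_r repulsion range, nm.
#' @return Length-2 force vector in pN (pointing inward).
#' @export
boundary_force <- function(x, r, R0, eps = 0.5, L_r = 121.2) {
  rr <- sqrt(sum(x^2))
  db <- R0 - rr - r
  if (db <= 0) stop("contact: particle touches or crosses the boundary")
  if (db > L_r || rr == 0) return(c(0, 0))
  -eps * (L_r / db - 1) * x / rr
}

#' Total force field over a configuration
#'
#' Sums, for every particle, the pairwise repulsions within range (all type
#' pairs), the boundary repulsion (disk domain), and the motor springs over
#' its bonds. While an organelle pushes into the section (z < 0, radius
#' growing) the repulsion prefactors of all its pairs are doubled,
#' accounting for the axoplasm it displaces.
#'
#' @param state an `axc_state`.
#' @param bonds an `axc_bonds` (defaults to no engagements).
#' @param params an `axc_params`.
#' @return List of force matrices `mt`, `nf`, `org` (pN, one row per
#'   particle). Errors if any pair is in contact.
#' @export
total_forces <- function(state, bonds = empty_bonds(state),
                         params = model_params()) {
  .check_state_params(state, params)
  out <- cpp_forces(.lower_state(state), .lower_bonds(bonds),
                    .par_vec(params))
  if (isTRUE(out$contact)) {
    stop("contact: overlapping particles; the configuration is not ",
         "integrable")
  }
  out[c("mt", "nf", "org")]
}
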