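# Stochastic cargo kinetics: discrete Bernoulli events evaluated once per
# kinetics tick of length h, with per-event probability rate * h.

#' One tick of neurofilament transport kinetics
#'
#' For each unbound neurofilament with at least one microtubule within the
#' binding radius, a bond forms with probability `k_on_N * h` (the track is
#' drawn uniformly among candidates). Each bound neurofilament draws a
#' single variate against the cumulative probabilities `k_off_N * h`
#' (unbind) and `(k_off_N + k_out_N) * h` (depart), so at most one
#' transition fires per filament per tick. A departing filament is replaced
#' immediately to conserve the neurofilament count: the entrant is seeded
#' at surface distance `R_b` from an eligible microtubule (one that has
#' another neurofilament within `R_b`), at a rejection-sampled
#' non-overlapping angle, and starts unbound. If no eligible track or no
#' clear placement is found within 100 attempts the departure is cancelled.
#'
#' @param state an `axc_state`.
#' @param bonds an `axc_bonds`.
#' @param params an `axc_params`.
#' @param h tick length in s (`rate * h` must be small).
#' @param seed integer seed for this tick's event draws.
#' @return List with updated `state`, `bonds`, and an `events` count vector
#'   (`binds`, `unbinds`, `departs`, `cancelled`).
#' @export
nf_binding_step <- function(state, bonds, params = model_params(),
                            h = params$h_slow, seed = 1) {
  out <- cpp_nf_kinetics(.lower_state(state), .lower_bonds(bonds),
                         .par_vec(params), h, as.integer(seed))
  list(state = .raise_state(out$state, state),
       bonds = .raise_bonds(out$bonds), events = out$events)
}

#' One tick of organelle arrivals
#'
#' With probability `k_in_O * h` a new organelle enters the section: its
#' tip (`z = -a`, cross-sectional radius 0) is placed at surface distance
#' `R_b` from a uniformly chosen microtubule at a rejection-sampled
#' non-overlapping angle, and it is immediately engaged with that track.
#' With no microtubules present, or no clear placement within 100 attempts,
#' the arrival is deferred.
#'
#' @inheritParams nf_binding_step
#' @return List with updated `state`, `bonds`, and counts `arrived`,
#'   `deferred`.
#' @export
organelle_arrival_step <- function(state, bonds = empty_bonds(state),
                                   params = model_params(),
                                   h = params$h_slow, seed = 1) {
  out <- cpp_org_arrival(.lower_state(state), .lower_bonds(bonds),
                         .par_vec(params), h, as.integer(seed))
  list(state = .raise_state(out$state, state),
       bonds = .raise_bonds(out$bonds),
       arrived = out$arrived, deferred = out$deferred)
}

#' Deterministic axial advance of organelles
#'
#' Each organelle advances `z` by `s_O * h`; its cross-sectional radius
#' follows `b * (1 - z^2 / a^2)`, growing until the midpoint (`z = 0`) and
#' shrinking after. An organelle whose trailing tip reaches the section
#' (`z >= a`) has fully crossed and is removed together with all its bonds,
#' after a residence time `2 a / s_O`.
#'
#' @inheritParams nf_binding_step
#' @return List with updated `state` and `bonds`.
#' @export
organelle_advance <- function(state, bonds = empty_bonds(state),
                              params = model_params(), h = params$h_slow) {
  org <- state$org
  if (nrow(org)) {
    org$z <- org$z + params$s_O * 1e3 * h
    keep <- org$z < org$a
    state$org <- org[keep, , drop = FALSE]
    rownames(state$org) <- NULL
    bonds$org <- bonds$org[keep]
  }
  list(state = state, bonds = bonds)
}

#' One tick of organelle-microtubule engagement kinetics
#'
#' Every existing bond breaks independently with probability `k_off_O * h`;
#' every (organelle, unbonded microtubule) pair within the binding radius
#' forms a bond with probability `k_on_O * h`, as long as the organelle's
#' engagement count stays within `m_max`. Because a large organelle can be
#' within `R_b` of several microtubules at once, multi-track engagement —
#' the "zippering" that pulls microtubules together — is generic.
#'
#' @inheritParams nf_binding_step
#' @return List with updated `state` (unchanged) and `bonds`.
#' @export
organelle_binding_step <- function(state, bonds, params = model_params(),
                                   h = params$h_slow, seed = 1) {
  out <- cpp_org_binding(.lower_state(state), .lower_bonds(bonds),
                         .par_vec(params), h, as.integer(seed))
  list(state = state, bonds = .raise_bonds(out$bonds))
}
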