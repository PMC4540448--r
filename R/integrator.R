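# Euler-Maruyama integration of the overdamped Langevin system, with the
# two-level adaptive step policy and interleaved cargo kinetics.

#' One Euler-Maruyama step of the mechanics
#'
#' Every particle of type k moves by `F/mu_k * h + sqrt(2 D_k h) * xi` with
#' `xi` a pair of independent standard normal draws; organelle axial
#' offsets advance deterministically by `s_O * h` and organelles that have
#' fully crossed are removed. If the displacement produces a contact
#' (overlapping surfaces, where the repulsion diverges) the step is
#' rejected and retried at half the step size; repeated failure down to
#' `h / 1024` is an error.
#'
#' @param state an `axc_state`.
#' @param bonds an `axc_bonds`.
#' @param params an `axc_params`.
#' @param h step size in s.
#' @param seed integer seed for the noise draws.
#' @return List with updated `state`, `bonds`, the step size actually used
#'   (`h_used`) and the number of rejected attempts (`rejects`).
#' @export
em_step <- function(state, bonds = empty_bonds(state),
                    params = model_params(), h = params$h_slow, seed = 1) {
  .check_state_params(state, params)
  out <- cpp_em_step(.lower_state(state), .lower_bonds(bonds),
                     .par_vec(params), h, as.integer(seed))
  list(state = .raise_state(out$state, state),
       bonds = .raise_bonds(out$bonds),
       h_used = out$h_used, rejects = out$rejects)
}

#' Run the full simulation loop
#'
#' Advances the system to `t_end`, interleaving, on every kinetics tick of
#' length `h_slow`: scheduled parameter changes, neurofilament transport
#' events, organelle arrivals and engagement kinetics, and then the
#' mechanics. Mechanics sub-steps use `h_slow` while no organelle is
#' present and `h_fast` otherwise (the equations stiffen while an organelle
#' pushes into the section). The run is deterministic given `seed`.
#'
#' @param state initial `axc_state`.
#' @param bonds initial `axc_bonds`.
#' @param params an `axc_params`.
#' @param schedule an `axc_schedule` of timed parameter changes, or `NULL`.
#' @param t_end end time, s.
#' @param series_dt cadence of the summary series (mean pairwise MT
#'   distance, bound-NF fraction, organelle count), s.
#' @param snapshot_dt cadence of full configuration snapshots, s; `0`
#'   disables periodic snapshots (the final state is always kept).
#' @param seed integer seed driving all randomness of the run.
#' @param strict_kinetics if `TRUE`, kinetics events are evaluated at every
#'   mechanics sub-step (probability `rate * h_fast` while organelles are
#'   present) instead of once per tick; the default tick-wise evaluation
#'   preserves the advertised rates at far lower cost.
#' @return An object of class `axc_trajectory`: list with `series` (data
#'   frame `t`, `pdmt_mean`, `bound_frac`, `n_org`), `snapshots` (list of
#'   `t`/`state`/`bonds`), `final_state`, `final_bonds`, `t_final`,
#'   `counters`, and the run metadata (`params`, `schedule`, `seed`).
#' @examples
#' \donttest{
#' st <- init_hexagonal_randomized(8, 40, disk_domain(400),
#'                                 randomize_time = 2, seed = 1)
#' tr <- run_sim(st, t_end = 5, series_dt = 1, seed = 1)
#' tr$series
#' }
#' @export
run_sim <- function(state, bonds = empty_bonds(state),
                    params = model_params(), schedule = NULL, t_end,
                    series_dt = 60, snapshot_dt = 0, seed = 1,
                    strict_kinetics = FALSE) {
  .check_state_params(state, params)
  stopifnot(t_end >= 0)
  out <- cpp_run(.lower_state(state), .lower_bonds(bonds),
                 .par_vec(params), .lower_schedule(schedule, params),
                 as.numeric(t_end), as.numeric(series_dt),
                 as.numeric(snapshot_dt), as.integer(seed),
                 isTRUE(strict_kinetics))
  snaps <- lapply(out$snapshots, function(s) {
    list(t = s$t, state = .raise_state(s$state, state),
         bonds = .raise_bonds(s$bonds))
  })
  structure(list(
    series = data.frame(t = out$series$t, pdmt_mean = out$series$pdmt_mean,
                        bound_frac = out$series$bound_frac,
                        n_org = out$series$n_org),
    snapshots = snaps,
    final_state = .raise_state(out$final_state, state),
    final_bonds = .raise_bonds(out$final_bonds),
    t_final = out$t_final,
    counters = out$counters,
    params = params, schedule = schedule, seed = as.integer(seed)
  ), class = "axc_trajectory")
}

#' @export
print.axc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<axc_trajectory> t = 0..%g s, %d series points, %d snapshots (seed %d)\n",
    x$t_final, nrow(x$series), length(x$snapshots), x$seed))
  cat(sprintf("  steps: %d slow + %d fast, %d rejected\n",
              as.integer(x$counters[["slow_steps"]]),
              as.integer(x$counters[["fast_steps"]]),
              as.integer(x$counters[["rejects"]])))
  invisible(x)
}
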