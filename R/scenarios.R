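# Preset experiment configurations and the initial-condition generator.

# hexagonal lattice sites covering a domain; spacing chosen so that at
# least n sites are available, then the n sites nearest the center (disk)
# or the first n rows-first sites (periodic) are used
.hex_sites <- function(domain, n, margin) {
  stopifnot(n >= 1)
  if (domain$kind == "disk") {
    R <- domain$size - margin
    if (R <= 0) stop("domain too small for the requested margin")
    # target spacing from the hexagonal site density 2/(sqrt(3) s^2)
    s <- sqrt(2 * pi * R^2 / (sqrt(3) * n))
    repeat {
      dy <- s * sqrt(3) / 2
      ys <- seq(-R, R, by = dy)
      pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
        xo <- if (i %% 2 == 0) s / 2 else 0
        xs <- seq(-R - xo, R, by = s) + xo
        cbind(xs, ys[i])
      }))
      pts <- pts[rowSums(pts^2) <= R^2, , drop = FALSE]
      if (nrow(pts) >= n) break
      s <- s * 0.98
    }
    ord <- order(rowSums(pts^2))
    pts[ord[seq_len(n)], , drop = FALSE]
  } else {
    L <- domain$size
    ncol_ <- ceiling(sqrt(n * 2 / sqrt(3)))
    nrow_ <- ceiling(n / ncol_)
    sx <- L / ncol_
    sy <- L / nrow_
    pts <- do.call(rbind, lapply(seq_len(nrow_), function(i) {
      xo <- if (i %% 2 == 0) sx / 2 else 0
      cbind(((seq_len(ncol_) - 1) * sx + xo) %% L, (i - 1) * sy)
    }))
    pts[seq_len(n), , drop = FALSE]
  }
}

#' Initial condition: hexagonal seeding followed by randomization
#'
#' Particles are first placed on a hexagonal lattice (microtubules and
#' neurofilaments assigned to lattice sites uniformly at random for mixed
#' configurations), then evolved under excluded-volume repulsion, boundary
#' confinement and Brownian motion only — no motor bonds, no cargo
#' kinetics — for `randomize_time` seconds of simulated time, which washes
#' out the lattice while keeping the pattern overlap-free.
#'
#' For mixed disk configurations an optional convergence guard stops the
#' randomization early once the mean pairwise MT distance changes by less
#' than 1% over a 10 s block.
#'
#' @param n_mt,n_nf particle counts.
#' @param domain a domain descriptor.
#' @param params an `axc_params`.
#' @param randomize_time randomization duration, simulated s; `0` returns
#'   the bare lattice.
#' @param h integration step for the randomization, s; defaults to
#'   `params$h_slow`.
#' @param seed integer seed (site assignment and Brownian noise).
#' @param guard use the PDMT convergence guard (mixed disk configurations).
#' @return An `axc_state`.
#' @examples
#' \donttest{
#' st <- init_hexagonal_randomized(8, 40, disk_domain(400),
#'                                 randomize_time = 2, seed = 1)
#' }
#' @export
init_hexagonal_randomized <- function(n_mt, n_nf, domain,
                                      params = model_params(),
                                      randomize_time = 60, h = NULL,
                                      seed = 1, guard = FALSE) {
  n <- n_mt + n_nf
  margin <- max(params$r_M, params$r_N) + 10
  sites <- .hex_sites(domain, n, margin)
  # deterministic site assignment from the seed, without touching
  # .Random.seed
  ord <- order(.opd_rng(seed + 211)(n))
  mt_idx <- ord[seq_len(n_mt)]
  st <- particle_state(
    mt = sites[mt_idx, , drop = FALSE],
    nf = sites[setdiff(seq_len(n), mt_idx), , drop = FALSE],
    domain = domain, mt_radius = params$r_M, nf_radius = params$r_N
  )
  if (randomize_time <= 0) return(st)
  p0 <- params
  p0$k_on_N <- 0; p0$k_in_O <- 0 # repulsion + boundary + Brownian only
  if (!is.null(h)) p0$h_slow <- h
  class(p0) <- "axc_params"
  if (guard && n_mt >= 2) {
    block <- 10
    t_done <- 0
    last <- pdmt(st)$mean
    while (t_done < randomize_time) {
      dt <- min(block, randomize_time - t_done)
      tr <- run_sim(st, params = p0, t_end = dt, series_dt = 0,
                    snapshot_dt = 0, seed = seed + 1000 + round(t_done))
      st <- tr$final_state
      t_done <- t_done + dt
      cur <- pdmt(st)$mean
      if (abs(cur - last) < 0.01 * last && t_done >= 2 * block) break
      last <- cur
    }
    st
  } else {
    tr <- run_sim(st, params = p0, t_end = randomize_time, series_dt = 0,
                  snapshot_dt = 0, seed = seed + 1000)
    tr$final_state
  }
}

#' Preset scenario configurations
#'
#' Named, fully resolved experiment protocols:
#' \describe{
#'   \item{`nf_only_200`, `nf_only_400`}{neurofilaments only (200 or 400
#'     per um^2) in a 1 um periodic square, step 1/200 s, randomized for
#'     25 s and sampled every 0.1 s from 25 s to 30 s — the protocol for
#'     RDF/OPD morphometrics of normal neurofilament packing.}
#'   \item{`nf_only_400_lowrep`}{as `nf_only_400` with the repulsion scale
#'     halved to 0.25 pN (weakly phosphorylated sidearms).}
#'   \item{`control`}{56 MT + 361 NF in a 1-um-radius disk with organelle
#'     traffic (b = 140 nm, a/b = 10), transport intact, 20 h.}
#'   \item{`reversible_segregation`}{control protocol with neurofilament
#'     binding switched off at t = 1 h and restored at t = 13 h.}
#'   \item{`blocked_from_start`}{neurofilament binding off from t = 0
#'     (used for scaled-down segregation-trend checks).}
#'   \item{`mmax_1`, `mmax_2`, `mmax_4`, `mmax_8`, `mmax_16`}{blockage at
#'     1 h with the organelle engagement cap set to the given value.}
#'   \item{`sizeflux_b140_x1`, `sizeflux_b140_x1.5`, `sizeflux_b70_x1`,
#'     `sizeflux_b70_x2`}{blockage at 1 h with organelle size b (nm) and
#'     arrival-rate multiplier as named.}
#'   \item{`partial_block_50`, `partial_block_20`, `partial_block_0`}{
#'     binding rate reduced at 1 h to 50%, 20% or 0% of its normal value.}
#' }
#'
#' @param name preset name.
#' @return An object of class `axc_scenario`: list with `name`, `domain`,
#'   `n_mt`, `n_nf`, `params`, `schedule`, `t_end`, `series_dt`,
#'   `snapshot_dt`, `randomize_time`, `h_init`, `guard`.
#' @examples
#' preset("reversible_segregation")
#' @export
preset <- function(name) {
  mk <- function(name, domain, n_mt, n_nf, params, schedule = NULL,
                 t_end, series_dt = 60, snapshot_dt = 0,
                 randomize_time = 60, h_init = NULL, guard = TRUE) {
    structure(list(name = name, domain = domain, n_mt = n_mt, n_nf = n_nf,
                   params = params, schedule = schedule, t_end = t_end,
                   series_dt = series_dt, snapshot_dt = snapshot_dt,
                   randomize_time = randomize_time, h_init = h_init,
                   guard = guard),
              class = "axc_scenario")
  }
  nf_only <- function(name, n, eps) {
    mk(name, periodic_domain(1000), 0, n,
       model_params(eps_r = eps, k_in_O = 0, h_slow = 1 / 200),
       t_end = 30, series_dt = 0, snapshot_dt = 0.1,
       randomize_time = 25, h_init = 1 / 200, guard = FALSE)
  }
  disk <- disk_domain(1000)
  nM <- counts_from_density(18, 1)   # 56
  nN <- counts_from_density(115, 1)  # 361
  block1h <- function(p = model_params(), extra = NULL) {
    event_schedule(3600, "k_on_N", 0)
  }
  switch(
    name,
    nf_only_200 = nf_only(name, 200, 0.5),
    nf_only_400 = nf_only(name, 400, 0.5),
    nf_only_400_lowrep = nf_only(name, 400, 0.25),
    control = mk(name, disk, nM, nN, model_params(), NULL, t_end = 20 * 3600),
    reversible_segregation = mk(
      name, disk, nM, nN, model_params(),
      event_schedule(c(3600, 13 * 3600), c("k_on_N", "k_on_N"),
                     c(0, 1e-2)),
      t_end = 20 * 3600),
    blocked_from_start = mk(name, disk, nM, nN, model_params(k_on_N = 0),
                            NULL, t_end = 12 * 3600),
    mmax_1 = mk(name, disk, nM, nN, model_params(m_max = 1), block1h(),
                t_end = 18 * 3600),
    mmax_2 = mk(name, disk, nM, nN, model_params(m_max = 2), block1h(),
                t_end = 18 * 3600),
    mmax_4 = mk(name, disk, nM, nN, model_params(m_max = 4), block1h(),
                t_end = 18 * 3600),
    mmax_8 = mk(name, disk, nM, nN, model_params(m_max = 8), block1h(),
                t_end = 18 * 3600),
    mmax_16 = mk(name, disk, nM, nN, model_params(m_max = 16), block1h(),
                 t_end = 18 * 3600),
    sizeflux_b140_x1 = mk(name, disk, nM, nN, model_params(), block1h(),
                          t_end = 18 * 3600),
    `sizeflux_b140_x1.5` = mk(name, disk, nM, nN,
                              model_params(k_in_O = 0.105 * 1.5), block1h(),
                              t_end = 18 * 3600),
    sizeflux_b70_x1 = mk(name, disk, nM, nN, model_params(org_b = 70),
                         block1h(), t_end = 18 * 3600),
    sizeflux_b70_x2 = mk(name, disk, nM, nN,
                         model_params(org_b = 70, k_in_O = 0.21), block1h(),
                         t_end = 18 * 3600),
    partial_block_50 = mk(name, disk, nM, nN, model_params(),
                          event_schedule(3600, "k_on_N", 0.5e-2),
                          t_end = 18 * 3600),
    partial_block_20 = mk(name, disk, nM, nN, model_params(),
                          event_schedule(3600, "k_on_N", 0.2e-2),
                          t_end = 18 * 3600),
    partial_block_0 = mk(name, disk, nM, nN, model_params(), block1h(),
                         t_end = 18 * 3600),
    stop("unknown preset: ", name)
  )
}

#' Names of all built-in presets
#' @return Character vector.
#' @export
preset_names <- function() {
  c("nf_only_200", "nf_only_400", "nf_only_400_lowrep", "control",
    "reversible_segregation", "blocked_from_start",
    paste0("mmax_", c(1, 2, 4, 8, 16)),
    "sizeflux_b140_x1", "sizeflux_b140_x1.5", "sizeflux_b70_x1",
    "sizeflux_b70_x2",
    paste0("partial_block_", c(50, 20, 0)))
}

#' @export
print.axc_scenario <- function(x, ...) {
  cat(sprintf("<axc_scenario> %s: %d MT + %d NF in %s (%g nm), t_end %g s\n",
              x$name, x$n_mt, x$n_nf, x$domain$kind, x$domain$size, x$t_end))
  if (!is.null(x$schedule) && nrow(x$schedule)) {
    cat("  schedule:\n")
    for (i in seq_len(nrow(x$schedule))) {
      cat(sprintf("    t=%gs %s <- %g\n", x$schedule$time[i],
                  x$schedule$param[i], x$schedule$value[i]))
    }
  }
  invisible(x)
}

#' Blockage via an increased neurofilament off-rate
#'
#' The alternative way to impair neurofilament transport: instead of
#' preventing binding, multiply the unbinding rate `k_off_N` by `factor`
#' at the blockage time. `factor = 1` reproduces the control.
#'
#' @param factor multiplier for `k_off_N` (>= 1).
#' @param at blockage time, s.
#' @return An `axc_scenario`.
#' @examples
#' alt_blockage_offrate(100)
#' @export
alt_blockage_offrate <- function(factor, at = 3600) {
  stopifnot(factor >= 1)
  sc <- preset("control")
  sc$name <- sprintf("offrate_x%g", factor)
  if (factor > 1) {
    sc$schedule <- event_schedule(at, "k_off_N",
                                  factor * sc$params$k_off_N)
  }
  sc
}

#' Run a scenario end to end
#'
#' Generates the randomized initial condition of the scenario, runs the
#' full simulation loop with its schedule, and returns the trajectory.
#' Fields of the scenario (most usefully `t_end`, `series_dt`,
#' `snapshot_dt`) can be overridden for shorter exploratory runs.
#'
#' @param scenario an `axc_scenario` (or a preset name).
#' @param seed integer seed; drives initial condition and run.
#' @param ... scenario field overrides.
#' @return An `axc_trajectory`.
#' @export
run_scenario <- function(scenario, seed = 1, ...) {
  if (is.character(scenario)) scenario <- preset(scenario)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(scenario))
    if (length(bad)) stop("unknown scenario fields: ",
                          paste(bad, collapse = ", "))
    scenario[names(dots)] <- dots
  }
  st <- init_hexagonal_randomized(
    scenario$n_mt, scenario$n_nf, scenario$domain, scenario$params,
    randomize_time = scenario$randomize_time, h = scenario$h_init,
    seed = seed, guard = isTRUE(scenario$guard)
  )
  tr <- run_sim(st, params = scenario$params, schedule = scenario$schedule,
                t_end = scenario$t_end, series_dt = scenario$series_dt,
                snapshot_dt = scenario$snapshot_dt, seed = seed)
  tr$scenario <- scenario
  tr
}
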