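# Domain types: particle configurations, bond sets, event schedules.

#' Disk and periodic-square domains
#'
#' The cross-section is either a disk of radius `R0` (the physiological
#' geometry, bounded by the axonal membrane) or a periodic square of side
#' `L` (used for boundary-free morphometrics of neurofilament-only
#' patterns). All lengths in nm.
#'
#' @param R0,L domain radius / side length in nm.
#' @return A domain descriptor list with elements `kind` and `size`.
#' @examples
#' disk_domain(1000)       # 1-um-radius axon cross-section
#' periodic_domain(1000)   # 1 um x 1 um periodic patch
#' @export
disk_domain <- function(R0) {
  stopifnot(is.numeric(R0), length(R0) == 1, R0 > 0)
  structure(list(kind = "disk", size = R0), class = "axc_domain")
}

#' @rdname disk_domain
#' @export
periodic_domain <- function(L) {
  stopifnot(is.numeric(L), length(L) == 1, L > 0)
  structure(list(kind = "periodic", size = L), class = "axc_domain")
}

#' @export
print.axc_domain <- function(x, ...) {
  cat(sprintf("<axc_domain> %s, %s = %g nm\n", x$kind,
              if (x$kind == "disk") "R0" else "L", x$size))
  invisible(x)
}

.dom_kind_code <- function(domain) {
  switch(domain$kind, disk = 0L, periodic = 1L,
         stop("unknown domain kind: ", domain$kind))
}

#' Area of a domain (nm^2)
#' @param domain a domain from [disk_domain()] or [periodic_domain()].
#' @return Area in nm^2.
#' @export
domain_area <- function(domain) {
  if (domain$kind == "disk") pi * domain$size^2 else domain$size^2
}

#' Particle configuration of one cross-section
#'
#' Positions of all microtubules, neurofilaments and organelles at one
#' instant. Coordinates are in nm: centered at the axon axis for a disk
#' domain, in `[0, L)` for a periodic domain. Organelles are described by
#' their in-plane center, axial offset `z` relative to the section, spindle
#' half-length `a` and maximum radius `b`; their current cross-sectional
#' radius is `b * (1 - z^2 / a^2)`.
#'
#' @param mt,nf numeric matrices with two columns (x, y in nm); zero-row
#'   matrices are allowed.
#' @param org data frame with columns `x`, `y`, `z`, `a`, `b` (one row per
#'   organelle present), or `NULL` for none.
#' @param domain a domain descriptor.
#' @param mt_radius,nf_radius disk radii in nm.
#' @return An object of class `axc_state`.
#' @export
particle_state <- function(mt, nf, org = NULL, domain = disk_domain(1000),
                           mt_radius = 12.5, nf_radius = 5) {
  mt <- .as_xy(mt); nf <- .as_xy(nf)
  if (is.null(org)) {
    org <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      a = numeric(0), b = numeric(0))
  }
  stopifnot(all(c("x", "y", "z", "a", "b") %in% names(org)))
  if (nrow(org) && any(abs(org$z) > org$a)) {
    stop("organelle axial offset |z| must not exceed the half-length a")
  }
  structure(list(mt = mt, nf = nf, org = as.data.frame(org),
                 domain = domain, mt_radius = mt_radius,
                 nf_radius = nf_radius),
            class = "axc_state")
}

.as_xy <- function(x) {
  if (is.null(x)) x <- matrix(numeric(0), ncol = 2)
  x <- as.matrix(x)
  if (length(x) == 2 && is.null(dim(x))) x <- matrix(x, ncol = 2)
  stopifnot(ncol(x) == 2)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.axc_state <- function(x, ...) {
  cat(sprintf("<axc_state> %d MT + %d NF + %d organelle(s) in %s (%g nm)\n",
              nrow(x$mt), nrow(x$nf), nrow(x$org), x$domain$kind,
              x$domain$size))
  invisible(x)
}

#' Motor-engagement bond set
#'
#' The engagement graph at one instant: each neurofilament is bound to at
#' most one microtubule (a partial matching), while each organelle may hold
#' bonds to several microtubules at once (capped by `m_max` when a cap is
#' configured).
#'
#' @param n_nf number of neurofilaments.
#' @param nf integer vector of length `n_nf`: the bonded MT index (1-based)
#'   or `NA` for unbound.
#' @param org list with one integer vector of bonded MT indices per
#'   organelle.
#' @return An object of class `axc_bonds`.
#' @export
bond_set <- function(n_nf, nf = rep(NA_integer_, n_nf), org = list()) {
  nf <- as.integer(nf)
  stopifnot(length(nf) == n_nf)
  structure(list(nf = nf, org = lapply(org, as.integer)),
            class = "axc_bonds")
}

#' Empty bond set matching a state
#' @param state an `axc_state`.
#' @return An `axc_bonds` with no engagements.
#' @export
empty_bonds <- function(state) {
  bond_set(nrow(state$nf), org = rep(list(integer(0)), nrow(state$org)))
}

#' @export
print.axc_bonds <- function(x, ...) {
  cat(sprintf("<axc_bonds> %d/%d NF bound; organelle engagements: %s\n",
              sum(!is.na(x$nf)), length(x$nf),
              if (length(x$org)) paste(lengths(x$org), collapse = ",")
              else "none"))
  invisible(x)
}

#' Surface-to-surface distance between two disks
#'
#' Center distance under the domain metric (Euclidean, or minimum-image for
#' a periodic square) minus both radii. Negative values indicate
#' overlapping disks; callers decide how to react.
#'
#' @param xi,xj length-2 centers (nm).
#' @param ri,rj disk radii (nm).
#' @param domain a domain descriptor; the default disk metric is plain
#'   Euclidean.
#' @return Signed surface distance in nm.
#' @examples
#' surface_distance(c(0, 0), 12.5, c(100, 0), 12.5) # 75
#' @export
surface_distance <- function(xi, ri, xj, rj, domain = disk_domain(1000)) {
  d <- xj - xi
  if (domain$kind == "periodic") {
    L <- domain$size
    d <- d - L * round(d / L)
  }
  sqrt(sum(d^2)) - ri - rj
}

#' Cross-sectional radius of a transiting organelle
#'
#' A spindle of half-length `a` and maximum radius `b` intersects the
#' section in a disk of radius `b * (1 - z^2 / a^2)` when its center is at
#' axial offset `z`; the radius is maximal (`b`) at `z = 0` and vanishes at
#' the tips `z = -a, +a`.
#'
#' @param z axial offset (nm); must satisfy `|z| <= a`.
#' @param a spindle half-length (nm).
#' @param b maximum cross-sectional radius (nm).
#' @return Radius in nm.
#' @examples
#' organelle_radius(0, 1400, 140)      # 140
#' organelle_radius(700, 1400, 140)    # 105
#' @export
organelle_radius <- function(z, a, b) {
  stopifnot(a > 0, b > 0)
  if (any(abs(z) > a)) {
    stop("axial offset out of range: |z| must not exceed a")
  }
  b * (1 - z^2 / a^2)
}

#' Timed parameter changes
#'
#' An ordered schedule of parameter reassignments applied during a run,
#' e.g. setting the neurofilament binding rate to zero at t = 1 h to block
#' neurofilament transport, and restoring it later.
#'
#' @param time event times in s (non-decreasing).
#' @param param parameter names; one of
#'   `r paste0("\x60", paste(.schedulable, collapse = "\x60, \x60"), "\x60")`.
#' @param value new values (in the parameter's usual units).
#' @return An object of class `axc_schedule` (a data frame).
#' @examples
#' event_schedule(c(3600, 13 * 3600), c("k_on_N", "k_on_N"), c(0, 1e-2))
#' @export
event_schedule <- function(time = numeric(0), param = character(0),
                           value = numeric(0)) {
  stopifnot(length(time) == length(param), length(time) == length(value))
  if (length(time) > 1 && any(diff(time) < 0)) {
    stop("schedule times must be non-decreasing")
  }
  bad <- setdiff(param, .schedulable)
  if (length(bad)) {
    stop("not schedulable: ", paste(unique(bad), collapse = ", "),
         " (allowed: ", paste(.schedulable, collapse = ", "), ")")
  }
  structure(data.frame(time = as.numeric(time), param = as.character(param),
                       value = as.numeric(value)),
            class = c("axc_schedule", "data.frame"))
}

# ---- lowering to the compiled core --------------------------------------

.lower_state <- function(state) {
  list(mt = state$mt, nf = state$nf,
       org_x = as.numeric(state$org$x), org_y = as.numeric(state$org$y),
       org_z = as.numeric(state$org$z), org_a = as.numeric(state$org$a),
       org_b = as.numeric(state$org$b),
       dom_kind = .dom_kind_code(state$domain),
       dom_size = as.numeric(state$domain$size))
}

.raise_state <- function(low, template) {
  particle_state(
    mt = low$mt, nf = low$nf,
    org = data.frame(x = low$org_x, y = low$org_y, z = low$org_z,
                     a = low$org_a, b = low$org_b),
    domain = template$domain,
    mt_radius = template$mt_radius, nf_radius = template$nf_radius
  )
}

.lower_bonds <- function(bonds) {
  nf <- bonds$nf
  nf[is.na(nf)] <- 0L
  list(nf = as.integer(nf) - 1L,
       org = lapply(bonds$org, function(v) as.integer(v) - 1L))
}

.raise_bonds <- function(low) {
  nf <- as.integer(low$nf) + 1L
  nf[nf == 0L] <- NA_integer_
  structure(list(nf = nf,
                 org = lapply(low$org, function(v) as.integer(v) + 1L)),
            class = "axc_bonds")
}

.lower_schedule <- function(schedule, params) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    return(list(time = numeric(0), idx = integer(0), value = numeric(0)))
  }
  idx <- match(schedule$param, .par_names) - 1L
  if (anyNA(idx)) stop("schedule refers to unknown parameters")
  # convert values to internal units by reusing .par_vec on a modified set
  val <- vapply(seq_len(nrow(schedule)), function(i) {
    q <- params
    q[[schedule$param[i]]] <- schedule$value[i]
    class(q) <- "axc_params"
    unname(.par_vec(q)[schedule$param[i]])
  }, numeric(1))
  list(time = as.numeric(schedule$time), idx = as.integer(idx),
       value = as.numeric(val))
}

# consistency guard used by the wrappers
.check_state_params <- function(state, params) {
  if (abs(state$mt_radius - params$r_M) > 1e-9 ||
      abs(state$nf_radius - params$r_N) > 1e-9) {
    warning("state radii differ from parameter radii; ",
            "the parameter values are used for the physics")
  }
  invisible(TRUE)
}
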