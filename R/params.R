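# Model parameters and small closed-form helpers.
#
# User-facing fields keep the units in which they are conventionally
# reported (nm, /s, pN, pN/nm, pN.s/um, pN.um); the compiled core works in
# nm / s / pN and receives a converted vector from .par_vec().

# order must match ParIdx in src/sim.cpp
.par_names <- c(
  "r_M", "r_N", "R_b", "k_on_N", "k_off_N", "k_out_N",
  "k_on_O", "k_off_O", "k_in_O", "s_O", "L_r", "eps_r",
  "kappa_N", "kappa_O", "mu_M", "mu_N", "mu_O",
  "D_M", "D_N", "D_O", "m_max", "h_slow", "h_fast",
  "org_a", "org_b", "eps_double"
)

# parameters the event schedule is allowed to change at run time
.schedulable <- c(
  "k_on_N", "k_off_N", "k_out_N", "k_on_O", "k_off_O", "k_in_O",
  "m_max", "eps_r", "kappa_N", "kappa_O"
)

#' Model parameter set
#'
#' Builds the full parameter set of the cross-section model. Defaults are
#' the reference values for mammalian axons: particle geometry, motor
#' binding kinetics, repulsion and spring constants, drag coefficients and
#' the thermal energy from which diffusivities follow by the Einstein
#' relation.
#'
#' @param ... named overrides of any field listed below.
#'
#' @details Fields and units:
#' \describe{
#'   \item{r_N, r_M}{NF and MT disk radii (nm); 5 and 12.5.}
#'   \item{org_b, org_aspect}{organelle maximum cross-sectional radius b
#'     (nm; 25--200, default 140) and half-length-to-radius ratio a/b
#'     (default 10), so the spindle half-length is `a = org_aspect * org_b`.}
#'   \item{R_b}{motor capture (binding) radius, nm; 80.}
#'   \item{k_on_N, k_off_N, k_out_N}{NF binding, unbinding and departure
#'     rates (/s); 1e-2, 6.5e-2, 0.1.}
#'   \item{k_on_O, k_off_O, k_in_O}{organelle engagement, release and
#'     arrival rates (/s); 2, 2, 0.105.}
#'   \item{s_O}{organelle axial speed (um/s); 1.}
#'   \item{L_r, eps_r}{repulsion range (nm; 121.2) and scale (pN; 0.5).
#'     The single scale is used for every particle pair and the boundary.}
#'   \item{kappa_N, kappa_O}{motor spring constants (pN/nm); 0.18, 0.9.}
#'   \item{mu_N, mu_M, mu_O}{drag coefficients (pN.s/um); 73.5, 512, 40.3.}
#'   \item{kT}{thermal energy (pN.um); 4.11e-3 (about 298 K). Diffusivities
#'     are always derived as `kT / mu`.}
#'   \item{m_max}{maximum number of MTs one organelle may engage at once;
#'     `Inf` (no cap) by default.}
#'   \item{h_slow, h_fast}{integration steps (s): 1/50 when no organelle is
#'     present, 1/1600 otherwise.}
#'   \item{eps_double}{logical; double the repulsion prefactors of an
#'     organelle while it pushes into the section (z < 0), emulating the
#'     axoplasm it displaces.}
#' }
#'
#' @return An object of class `axc_params` (a validated named list).
#' @examples
#' p <- model_params(k_on_N = 0)      # neurofilament transport blocked
#' diffusivities(p)                   # um^2/s, via the Einstein relation
#' @export
model_params <- function(...) {
  p <- list(
    r_N = 5, r_M = 12.5,
    org_b = 140, org_aspect = 10,
    R_b = 80,
    k_on_N = 1.0e-2, k_off_N = 6.5e-2, k_out_N = 0.1,
    k_on_O = 2, k_off_O = 2, k_in_O = 0.105,
    s_O = 1,
    L_r = 121.2, eps_r = 0.5,
    kappa_N = 0.18, kappa_O = 0.9,
    mu_N = 73.5, mu_M = 512, mu_O = 40.3,
    kT = 4.11e-3,
    m_max = Inf,
    h_slow = 1 / 50, h_fast = 1 / 1600,
    eps_double = TRUE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p <- modifyList(p, dots)
  }
  class(p) <- "axc_params"
  validate_params(p)
  p
}

#' @export
print.axc_params <- function(x, ...) {
  cat("<axc_params> cross-section model parameters\n")
  cat(sprintf("  geometry : r_N=%g r_M=%g nm; organelle b=%g nm, a/b=%g\n",
              x$r_N, x$r_M, x$org_b, x$org_aspect))
  cat(sprintf("  NF rates : on=%g off=%g out=%g /s; R_b=%g nm\n",
              x$k_on_N, x$k_off_N, x$k_out_N, x$R_b))
  cat(sprintf("  org rates: on=%g off=%g in=%g /s; speed=%g um/s; m_max=%s\n",
              x$k_on_O, x$k_off_O, x$k_in_O, x$s_O,
              if (is.finite(x$m_max)) x$m_max else "unlimited"))
  cat(sprintf("  forces   : eps=%g pN, L_r=%g nm; kappa_N=%g kappa_O=%g pN/nm\n",
              x$eps_r, x$L_r, x$kappa_N, x$kappa_O))
  D <- diffusivities(x)
  cat(sprintf("  mobility : D_N=%.3g D_M=%.3g D_O=%.3g um^2/s (kT=%g pN.um)\n",
              D[["D_N"]], D[["D_M"]], D[["D_O"]], x$kT))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks positivity and basic consistency (rates, lengths, stiffnesses and
#' drags strictly positive; organelle half-length exceeding its radius;
#' non-negative thermal energy; integration steps ordered).
#'
#' @param p an `axc_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  pos <- c("r_N", "r_M", "org_b", "org_aspect", "R_b", "L_r", "eps_r",
           "kappa_N", "kappa_O", "mu_N", "mu_M", "mu_O", "s_O",
           "h_slow", "h_fast")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("parameter '", f, "' must be a single positive number")
    }
  }
  nonneg <- c("k_on_N", "k_off_N", "k_out_N", "k_on_O", "k_off_O", "k_in_O",
              "kT")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop("parameter '", f, "' must be a single non-negative number")
    }
  }
  if (p$org_aspect <= 1) {
    stop("organelle aspect ratio a/b must exceed 1 (spindle longer than wide)")
  }
  if (!(is.infinite(p$m_max) || (p$m_max >= 1 && p$m_max == round(p$m_max)))) {
    stop("m_max must be a positive integer or Inf")
  }
  if (p$h_fast > p$h_slow) stop("h_fast must not exceed h_slow")
  if (!is.logical(p$eps_double) || length(p$eps_double) != 1) {
    stop("eps_double must be TRUE or FALSE")
  }
  invisible(p)
}

#' Diffusion coefficient from the Einstein relation
#'
#' `D = kT / mu` for an overdamped particle: with the default thermal
#' energy 4.11e-3 pN.um (about 298 K) the drag coefficients 73.5, 512 and
#' 40.3 pN.s/um give 5.59e-5, 8.02e-6 and 1.02e-4 um^2/s for
#' neurofilaments, microtubules and organelles respectively.
#'
#' @param mu drag coefficient, pN.s/um (> 0).
#' @param kT thermal energy, pN.um (> 0).
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' einstein_diffusion(73.5, 4.11e-3) # 5.59e-5 um^2/s
#' @export
einstein_diffusion <- function(mu, kT = 4.11e-3) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (any(!is.finite(kT)) || any(kT <= 0)) stop("kT must be positive")
  kT / mu
}

#' Diffusivities of all three particle types
#'
#' @param p an `axc_params` object.
#' @return Named vector `D_N`, `D_M`, `D_O` in um^2/s.
#' @export
diffusivities <- function(p) {
  c(D_N = p$kT / p$mu_N, D_M = p$kT / p$mu_M, D_O = p$kT / p$mu_O)
}

#' Particle count from an areal density
#'
#' `floor(density * pi * R0^2)`: the experimentally observed densities of
#' 18 MT/um^2 and 115 NF/um^2 in a 1-um-radius section give 56 microtubules
#' and 361 neurofilaments.
#'
#' @param density particles per um^2 (> 0).
#' @param R0 domain radius in um (> 0).
#' @return Integer count.
#' @examples
#' counts_from_density(18, 1)   # 56
#' counts_from_density(115, 1)  # 361
#' @export
counts_from_density <- function(density, R0) {
  if (any(density <= 0)) stop("density must be positive")
  if (any(R0 <= 0)) stop("R0 must be positive")
  as.integer(floor(density * pi * R0^2))
}

#' Stationary bound-time fraction of a neurofilament near one microtubule
#'
#' Two-state on/off kinetics: the fraction of in-range time spent engaged is
#' `k_on / (k_on + k_off)`, about 0.13 at the default rates.
#'
#' @param p an `axc_params` object.
#' @return A probability.
#' @export
nf_bound_fraction <- function(p = model_params()) {
  p$k_on_N / (p$k_on_N + p$k_off_N)
}

#' Probability of simultaneous engagement with two microtubules
#'
#' Square of the single-track bound fraction (about 0.017 at the default
#' rates); its smallness is what justifies restricting each neurofilament
#' to a single microtubule at a time.
#'
#' @param p an `axc_params` object.
#' @return A probability.
#' @export
nf_dual_binding_prob <- function(p = model_params()) {
  nf_bound_fraction(p)^2
}

# ---- internal unit conversion -------------------------------------------

# named parameter vector in internal units (nm, s, pN), in .par_names order
.par_vec <- function(p) {
  stopifnot(inherits(p, "axc_params"))
  v <- c(
    r_M = p$r_M, r_N = p$r_N, R_b = p$R_b,
    k_on_N = p$k_on_N, k_off_N = p$k_off_N, k_out_N = p$k_out_N,
    k_on_O = p$k_on_O, k_off_O = p$k_off_O, k_in_O = p$k_in_O,
    s_O = p$s_O * 1e3,                 # um/s -> nm/s
    L_r = p$L_r, eps_r = p$eps_r,
    kappa_N = p$kappa_N, kappa_O = p$kappa_O,
    mu_M = p$mu_M / 1e3,               # pN.s/um -> pN.s/nm
    mu_N = p$mu_N / 1e3,
    mu_O = p$mu_O / 1e3,
    D_M = p$kT / p$mu_M * 1e6,         # um^2/s -> nm^2/s
    D_N = p$kT / p$mu_N * 1e6,
    D_O = p$kT / p$mu_O * 1e6,
    m_max = if (is.finite(p$m_max)) p$m_max else 0,  # 0 encodes "no cap"
    h_slow = p$h_slow, h_fast = p$h_fast,
    org_a = p$org_aspect * p$org_b,
    org_b = p$org_b,
    eps_double = as.numeric(p$eps_double)
  )
  stopifnot(identical(names(v), .par_names))
  v
}
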