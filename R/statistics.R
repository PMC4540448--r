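# Morphometric statistics: radial distribution function, occupancy
# probability distribution with Gaussian fit, pairwise MT distances.

# pairwise center distances under the domain metric (vector, each pair once)
.pair_dists <- function(pts, domain) {
  n <- nrow(pts)
  if (n < 2) return(numeric(0))
  if (domain$kind == "periodic") {
    L <- domain$size
    dx <- outer(pts[, 1], pts[, 1], "-")
    dy <- outer(pts[, 2], pts[, 2], "-")
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
    m <- sqrt(dx^2 + dy^2)
    m[upper.tri(m)]
  } else {
    as.numeric(dist(pts))
  }
}

.as_frames <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    lapply(points, .as_xy)
  } else {
    list(.as_xy(points))
  }
}

#' Radial distribution function g(r)
#'
#' Density of neighbors at distance r from a reference particle, relative
#' to a uniform pattern at the same mean density: `g = 1` for complete
#' spatial randomness, sharp peaks for lattices, and a liquid-like first
#' peak for repulsively interacting neurofilaments. Distances are binned
#' and the count in each annulus is divided by its expectation
#' `rho * pi * (r2^2 - r1^2)` per reference particle, averaged over frames.
#'
#' For a periodic square the minimum-image metric makes every particle an
#' unbiased reference (up to `r_max <= L/2`). For a bounded disk an edge
#' correction is applied by restricting reference particles to those at
#' least `r_max` from the boundary.
#'
#' @param points one `n x 2` matrix (nm) or a list of such matrices (one
#'   per frame).
#' @param domain a domain descriptor.
#' @param bin_width histogram bin width, nm.
#' @param r_max largest distance considered, nm; defaults to 40% of the
#'   domain size (at most `L/2` for a periodic square).
#' @return An object of class `axc_rdf`: data frame with bin centers `r`
#'   and `g`, with the frame count in `attr(, "frames")`.
#' @examples
#' set.seed(1)
#' pts <- matrix(runif(600) * 1000, ncol = 2)
#' g <- rdf(pts, periodic_domain(1000))
#' mean(g$g[g$r > 100]) # close to 1 for an uncorrelated pattern
#' @export
rdf <- function(points, domain, bin_width = 5, r_max = NULL) {
  frames <- .as_frames(points)
  if (any(vapply(frames, nrow, 1L) < 2)) {
    stop("each frame needs at least two particles")
  }
  if (is.null(r_max)) r_max <- 0.4 * domain$size
  if (domain$kind == "periodic" && r_max > domain$size / 2) {
    stop("r_max must not exceed half the box side for a periodic domain")
  }
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ann <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
  acc <- numeric(length(mids))
  expn <- 0
  A <- domain_area(domain)
  for (pts in frames) {
    n <- nrow(pts)
    rho <- n / A
    if (domain$kind == "periodic") {
      dd <- .pair_dists(pts, domain)
      h <- graphics::hist(dd[dd < r_max], breaks = breaks, plot = FALSE)
      # each unordered pair contributes two ordered (reference, neighbor)
      acc <- acc + 2 * h$counts
      expn <- expn + n * rho * ann
    } else {
      ref <- sqrt(rowSums(pts^2)) <= domain$size - r_max
      if (!any(ref)) {
        stop("no reference particles at least r_max from the boundary; ",
             "reduce r_max")
      }
      d2 <- outer(pts[ref, 1], pts[, 1], "-")^2 +
        outer(pts[ref, 2], pts[, 2], "-")^2
      dd <- sqrt(d2[d2 > 0])
      h <- graphics::hist(dd[dd < r_max], breaks = breaks, plot = FALSE)
      acc <- acc + h$counts
      expn <- expn + sum(ref) * rho * ann
    }
  }
  out <- data.frame(r = mids, g = acc / expn)
  attr(out, "frames") <- length(frames)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("axc_rdf", "data.frame")
  out
}

#' Location of the first peak of a radial distribution function
#'
#' The distance at which g(r) attains its maximum within `(0, search_max]`;
#' for liquid-like patterns the global maximum in this window is the first
#' coordination peak. By default the location is refined by a parabola
#' through the maximum bin and its neighbors, which localizes the peak
#' below the bin width; the plain bin center is returned with
#' `refine = FALSE`. Either way the estimate carries a resolution of about
#' half a bin.
#'
#' @param g an `axc_rdf`.
#' @param search_max upper end of the search window, nm.
#' @param refine logical; parabolic sub-bin refinement.
#' @return Peak location in nm.
#' @export
rdf_first_peak <- function(g, search_max = 100, refine = TRUE) {
  w <- which(g$r <= search_max)
  if (!length(w)) stop("no bins inside the search window")
  i <- w[which.max(g$g[w])]
  if (!refine || i == 1 || i == nrow(g)) return(g$r[i])
  ym <- g$g[i - 1]; y0 <- g$g[i]; yp <- g$g[i + 1]
  den <- ym - 2 * y0 + yp
  if (den >= 0) return(g$r[i]) # degenerate curvature; keep the bin center
  dr <- g$r[i + 1] - g$r[i]
  g$r[i] + 0.5 * dr * (ym - yp) / den
}

#' Occupancy probability distribution (OPD)
#'
#' Distribution `p_n` of the number of particles whose centers fall inside
#' a randomly placed circular observation window, pooled over windows and
#' frames, together with a least-squares Gaussian fit to the histogram
#' (the conventional summary for neurofilament packing). For a uniform
#' independent pattern the OPD is Poisson with mean
#' `rho * pi * window_radius^2`.
#'
#' Windows are placed uniformly; in a disk domain only fully interior
#' windows (center within `R0 - window_radius`) are used, in a periodic
#' domain anywhere.
#'
#' @param points one `n x 2` matrix (nm) or a list of such matrices.
#' @param domain a domain descriptor.
#' @param window_radius observation-window radius, nm.
#' @param n_windows windows sampled per frame.
#' @param seed seed for window placement.
#' @return An object of class `axc_opd`: list with `p` (named probability
#'   vector over counts 0, 1, ...), empirical `mean` and `var`, Gaussian
#'   fit `fit_mean` and `fit_sd`, and the sampling metadata.
#' @export
opd <- function(points, domain, window_radius = 60, n_windows = 2000,
                seed = 1) {
  frames <- .as_frames(points)
  if (window_radius >= domain$size) {
    stop("window radius must be smaller than the domain")
  }
  rng <- .opd_rng(seed)
  counts <- integer(0)
  for (pts in frames) {
    if (domain$kind == "periodic") {
      L <- domain$size
      cx <- rng(n_windows) * L
      cy <- rng(n_windows) * L
      dx <- outer(cx, pts[, 1], "-")
      dy <- outer(cy, pts[, 2], "-")
      dx <- dx - L * round(dx / L)
      dy <- dy - L * round(dy / L)
    } else {
      rmax <- domain$size - window_radius
      if (rmax <= 0) stop("window does not fit inside the disk")
      # uniform over the interior disk of radius rmax
      rr <- rmax * sqrt(rng(n_windows))
      th <- 2 * pi * rng(n_windows)
      cx <- rr * cos(th)
      cy <- rr * sin(th)
      dx <- outer(cx, pts[, 1], "-")
      dy <- outer(cy, pts[, 2], "-")
    }
    counts <- c(counts, rowSums(dx^2 + dy^2 <= window_radius^2))
  }
  tab <- tabulate(counts + 1L)
  p <- tab / sum(tab)
  names(p) <- as.character(seq_along(p) - 1L)
  n_vals <- seq_along(p) - 1
  emp_mean <- sum(n_vals * p)
  emp_var <- sum((n_vals - emp_mean)^2 * p)
  fit <- .gaussian_fit(n_vals, p, emp_mean, sqrt(max(emp_var, 1e-6)))
  structure(list(p = p, mean = emp_mean, var = emp_var,
                 fit_mean = fit[1], fit_sd = fit[2],
                 window_radius = window_radius,
                 n_windows = n_windows * length(frames),
                 frames = length(frames)),
            class = "axc_opd")
}

# small deterministic uniform stream so opd() does not touch .Random.seed
.opd_rng <- function(seed) {
  state <- as.numeric(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (16807 * state) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

# unweighted least squares of a Gaussian density to the histogram
.gaussian_fit <- function(n, p, m0, s0) {
  obj <- function(par) {
    if (par[2] <= 0) return(1e6)
    sum((p - dnorm(n, par[1], par[2]))^2)
  }
  fit <- optim(c(m0, s0), obj, method = "Nelder-Mead")
  c(fit$par[1], fit$par[2])
}

#' @export
print.axc_opd <- function(x, ...) {
  cat(sprintf(
    "<axc_opd> window %g nm, %d windows over %d frame(s)\n",
    x$window_radius, x$n_windows, x$frames))
  cat(sprintf("  mean %.3f var %.3f; Gaussian fit mean %.3f sd %.3f\n",
              x$mean, x$var, x$fit_mean, x$fit_sd))
  invisible(x)
}

#' Pairwise microtubule distances (PDMT)
#'
#' All center-to-center distances between microtubule pairs in one frame;
#' the per-frame mean is the standard order parameter for
#' microtubule-neurofilament segregation (about `0.8 * R0` for a healthy
#' interspersed configuration, dropping by tens of percent as microtubules
#' cluster).
#'
#' @param x an `axc_state`, or an `n x 2` matrix of MT positions (nm).
#' @param domain domain descriptor used for the metric when `x` is a bare
#'   matrix; ignored otherwise (taken from the state).
#' @return An object of class `axc_pdmt`: list with `distances`, `mean`,
#'   and `n_pairs`.
#' @examples
#' pdmt(matrix(c(0, 500, 0, 0), ncol = 2)) # one pair, 500 nm apart
#' @export
pdmt <- function(x, domain = disk_domain(1000)) {
  if (inherits(x, "axc_state")) {
    pts <- x$mt
    domain <- x$domain
  } else {
    pts <- .as_xy(x)
  }
  if (nrow(pts) < 2) stop("need at least two microtubules")
  dd <- .pair_dists(pts, domain)
  structure(list(distances = dd, mean = mean(dd), n_pairs = length(dd)),
            class = "axc_pdmt")
}

#' @export
print.axc_pdmt <- function(x, ...) {
  cat(sprintf("<axc_pdmt> %d pairs, mean %.1f nm\n", x$n_pairs, x$mean))
  invisible(x)
}

#' Mean PDMT over the snapshots of a trajectory
#'
#' @param traj an `axc_trajectory` with stored snapshots.
#' @return Data frame with columns `t` and `pdmt_mean` (nm).
#' @export
pdmt_series <- function(traj) {
  stopifnot(inherits(traj, "axc_trajectory"))
  if (!length(traj$snapshots)) {
    stop("trajectory has no snapshots; use the built-in series instead")
  }
  data.frame(
    t = vapply(traj$snapshots, function(s) s$t, numeric(1)),
    pdmt_mean = vapply(traj$snapshots,
                       function(s) pdmt(s$state)$mean, numeric(1))
  )
}
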