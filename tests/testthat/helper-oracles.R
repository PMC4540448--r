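# Test-internal fixtures and independent oracles. The force oracle below is
# a literal double-loop evaluation of the force laws in plain R, sharing no
# code with the compiled kernels it checks.

# brute-force O(N^2) force field evaluation
bf_forces <- function(state, bonds, params) {
  eps <- params$eps_r; Lr <- params$L_r; Rb <- params$R_b
  dom <- state$domain
  sepv <- function(a, b) {
    d <- b - a
    if (dom$kind == "periodic") d <- d - dom$size * round(d / dom$size)
    d
  }
  n_mt <- nrow(state$mt); n_nf <- nrow(state$nf); n_org <- nrow(state$org)
  pos <- rbind(state$mt, state$nf)
  rad <- c(rep(params$r_M, n_mt), rep(params$r_N, n_nf))
  org_r <- if (n_org) {
    organelle_radius(state$org$z, state$org$a, state$org$b)
  } else numeric(0)
  opos <- as.matrix(state$org[, c("x", "y"), drop = FALSE])
  push <- if (n_org) (state$org$z < 0) & params$eps_double else logical(0)
  n <- n_mt + n_nf
  F <- matrix(0, n, 2)
  FO <- matrix(0, n_org, 2)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dv <- sepv(pos[i, ], pos[j, ])
      r <- sqrt(sum(dv^2)); d <- r - rad[i] - rad[j]
      if (d <= 0) stop("contact")
      if (d <= Lr) {
        f <- eps * (Lr / d - 1) * dv / r
        F[i, ] <- F[i, ] - f; F[j, ] <- F[j, ] + f
      }
    }
  }
  for (k in seq_len(n_nf)) {
    m <- bonds$nf[k]
    if (!is.na(m)) {
      i <- n_mt + k
      dv <- sepv(pos[m, ], pos[i, ])
      r <- sqrt(sum(dv^2)); d <- r - params$r_M - params$r_N
      if (d > 0 && d <= Rb) {
        f <- params$kappa_N * d * dv / r
        F[m, ] <- F[m, ] + f; F[i, ] <- F[i, ] - f
      }
    }
  }
  for (o in seq_len(n_org)) {
    fo <- if (push[o]) 2 else 1
    for (i in seq_len(n)) {
      dv <- sepv(opos[o, ], pos[i, ])
      r <- sqrt(sum(dv^2)); d <- r - org_r[o] - rad[i]
      if (d <= 0) stop("contact")
      if (d <= Lr) {
        f <- fo * eps * (Lr / d - 1) * dv / r
        FO[o, ] <- FO[o, ] - f; F[i, ] <- F[i, ] + f
      }
    }
    for (m in bonds$org[[o]]) {
      dv <- sepv(opos[o, ], pos[m, ])
      r <- sqrt(sum(dv^2)); d <- r - org_r[o] - params$r_M
      if (d > 0 && d <= Rb) {
        f <- params$kappa_O * d * dv / r
        FO[o, ] <- FO[o, ] + f; F[m, ] <- F[m, ] - f
      }
    }
    if (o < n_org) {
      for (o2 in (o + 1):n_org) {
        fo2 <- if (push[o2]) 2 else 1
        dv <- sepv(opos[o, ], opos[o2, ])
        r <- sqrt(sum(dv^2)); d <- r - org_r[o] - org_r[o2]
        if (d <= 0) stop("contact")
        if (d <= Lr) {
          f <- fo * fo2 * eps * (Lr / d - 1) * dv / r
          FO[o, ] <- FO[o, ] - f; FO[o2, ] <- FO[o2, ] + f
        }
      }
    }
  }
  if (dom$kind == "disk") {
    R0 <- dom$size
    for (i in seq_len(n)) {
      rr <- sqrt(sum(pos[i, ]^2)); db <- R0 - rr - rad[i]
      if (db <= 0) stop("contact")
      if (db <= Lr && rr > 0) {
        F[i, ] <- F[i, ] - eps * (Lr / db - 1) * pos[i, ] / rr
      }
    }
    for (o in seq_len(n_org)) {
      rr <- sqrt(sum(opos[o, ]^2)); db <- R0 - rr - org_r[o]
      if (db <= 0) stop("contact")
      if (db <= Lr && rr > 0) {
        FO[o, ] <- FO[o, ] - eps * (Lr / db - 1) * opos[o, ] / rr
      }
    }
  }
  list(mt = F[seq_len(n_mt), , drop = FALSE],
       nf = F[n_mt + seq_len(n_nf), , drop = FALSE],
       org = FO)
}

# random overlap-free configuration by rejection sampling
random_state <- function(n_mt, n_nf, n_org = 0, domain = disk_domain(1000),
                         seed = 1, params = model_params(), min_gap = 2) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 2)
  rads <- numeric(0)
  draw <- function() {
    if (domain$kind == "disk") {
      r <- (domain$size - 160) * sqrt(runif(1))
      th <- runif(1) * 2 * pi
      c(r * cos(th), r * sin(th))
    } else {
      runif(2) * domain$size
    }
  }
  sepv <- function(a, b) {
    d <- b - a
    if (domain$kind == "periodic") d <- d - domain$size * round(d / domain$size)
    d
  }
  add <- function(r_new) {
    repeat {
      x <- draw()
      ok <- TRUE
      for (i in seq_len(nrow(pts))) {
        if (sqrt(sum(sepv(pts[i, ], x)^2)) - rads[i] - r_new < min_gap) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        pts <<- rbind(pts, x); rads <<- c(rads, r_new)
        return(x)
      }
    }
  }
  org <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    a = numeric(0), b = numeric(0))
  a <- params$org_aspect * params$org_b
  for (i in seq_len(n_org)) {
    z <- runif(1, -a, a)
    ro <- organelle_radius(z, a, params$org_b)
    x <- add(ro)
    org <- rbind(org, data.frame(x = x[1], y = x[2], z = z, a = a,
                                 b = params$org_b))
  }
  for (i in seq_len(n_mt)) add(params$r_M)
  for (i in seq_len(n_nf)) add(params$r_N)
  idx_mt <- n_org + seq_len(n_mt)
  idx_nf <- n_org + n_mt + seq_len(n_nf)
  particle_state(mt = pts[idx_mt, , drop = FALSE],
                 nf = pts[idx_nf, , drop = FALSE], org = org,
                 domain = domain, mt_radius = params$r_M,
                 nf_radius = params$r_N)
}

# random bonds over a state: each NF bound with prob p_nf, each organelle
# engaged with every MT within reach with prob p_org
random_bonds <- function(state, seed = 1, p_nf = 0.3, p_org = 0.7,
                         params = model_params()) {
  set.seed(seed)
  n_mt <- nrow(state$mt); n_nf <- nrow(state$nf); n_org <- nrow(state$org)
  nf <- rep(NA_integer_, n_nf)
  if (n_mt > 0 && n_nf > 0) {
    pick <- runif(n_nf) < p_nf
    nf[pick] <- sample.int(n_mt, sum(pick), replace = TRUE)
  }
  org <- lapply(seq_len(n_org), function(o) {
    if (n_mt == 0) return(integer(0))
    which(runif(n_mt) < p_org)
  })
  bond_set(n_nf, nf = nf, org = org)
}

# one MT and one NF at a prescribed surface gap, bonded
make_bonded_pair <- function(gap, params = model_params(),
                             domain = disk_domain(1000)) {
  cd <- params$r_M + params$r_N + gap
  st <- particle_state(mt = matrix(c(0, 0), ncol = 2),
                       nf = matrix(c(cd, 0), ncol = 2), domain = domain,
                       mt_radius = params$r_M, nf_radius = params$r_N)
  list(state = st, bonds = bond_set(1, nf = 1L))
}

# scalar net force toward the MT on the NF of a bonded pair at gap d:
# attraction kappa*d minus repulsion eps*(L_r/d - 1)
pair_net_attraction <- function(d, params = model_params()) {
  spring <- ifelse(d <= params$R_b, params$kappa_N * d, 0)
  rep_ <- ifelse(d <= params$L_r, params$eps_r * (params$L_r / d - 1), 0)
  spring - rep_
}

# equilibrium gap of the bonded pair by an independent root-finder
pair_equilibrium_gap <- function(params = model_params()) {
  uniroot(pair_net_attraction, c(1, params$R_b), params = params,
          tol = 1e-10)$root
}

# uniform independent point pattern (the RDF/OPD null model)
make_poisson_pattern <- function(density_per_um2, domain, seed = 1) {
  set.seed(seed)
  n <- rpois(1, density_per_um2 * domain_area(domain) / 1e6)
  if (domain$kind == "periodic") {
    matrix(runif(2 * n) * domain$size, ncol = 2)
  } else {
    r <- domain$size * sqrt(runif(n))
    th <- 2 * pi * runif(n)
    cbind(r * cos(th), r * sin(th))
  }
}
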