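# Discrete cargo kinetics: event probabilities, conservation laws, the
# engagement cap, and placement rules.

test_that("NF binding fires at rate k_on per tick and picks in-range tracks", {
  p <- model_params()
  # one NF within R_b of one MT (gap 40), another far away
  st <- particle_state(mt = matrix(c(0, 0), ncol = 2),
                       nf = rbind(c(12.5 + 5 + 40, 0), c(800, 0)),
                       domain = disk_domain(1500))
  bd <- empty_bonds(st)
  h <- 1 / 50
  n_trials <- 4000
  hits <- 0
  for (s in 1:n_trials) {
    out <- nf_binding_step(st, bd, p, h, seed = s)
    if (!is.na(out$bonds$nf[1])) hits <- hits + 1
    expect_true(is.na(out$bonds$nf[2])) # out of range, can never bind
  }
  prob <- p$k_on_N * h
  se <- sqrt(prob * (1 - prob) / n_trials)
  expect_lt(abs(hits / n_trials - prob), 3 * se + 1e-6)
})

test_that("NF just outside the binding radius cannot bind", {
  p <- model_params()
  st <- particle_state(mt = matrix(c(0, 0), ncol = 2),
                       nf = matrix(c(12.5 + 5 + 81, 0), ncol = 2),
                       domain = disk_domain(1500))
  bd <- empty_bonds(st)
  for (s in 1:50) {
    out <- nf_binding_step(st, bd, p, h = 0.5, seed = s)
    expect_true(is.na(out$bonds$nf[1]))
  }
})

test_that("bound NFs unbind/depart with the configured rates, at most one
           transition per tick", {
  p <- model_params()
  # bound pair, no other NF => departures have no eligible entry point and
  # are cancelled, so the bond survives exactly the unbinding events
  fx <- make_bonded_pair(40, p)
  h <- 1 / 50
  n_trials <- 4000
  unb <- 0; canc <- 0
  for (s in 1:n_trials) {
    out <- nf_binding_step(fx$state, fx$bonds, p, h, seed = s)
    ev <- out$events
    unb <- unb + ev[["unbinds"]]
    canc <- canc + ev[["cancelled"]]
    expect_lte(ev[["unbinds"]] + ev[["departs"]] + ev[["cancelled"]], 1)
  }
  pu <- p$k_off_N * h
  se <- sqrt(pu * (1 - pu) / n_trials)
  expect_lt(abs(unb / n_trials - pu), 3 * se + 1e-6)
  pd <- p$k_out_N * h
  sed <- sqrt(pd * (1 - pd) / n_trials)
  expect_lt(abs(canc / n_trials - pd), 3 * sed + 1e-6)
})

test_that("departing NFs are replaced next to an eligible MT, conserving the
           count", {
  p <- model_params()
  # two MTs: one with a companion NF (eligible), one isolated; the bound NF
  # at MT 1 will depart eventually
  st <- particle_state(
    mt = rbind(c(0, 0), c(600, 0)),
    nf = rbind(c(12.5 + 5 + 30, 0), c(-12.5 - 5 - 30, 0)),
    domain = disk_domain(1500))
  bd <- bond_set(2, nf = c(1L, NA))
  seen_depart <- FALSE
  for (s in 1:600) {
    out <- nf_binding_step(st, bd, p, h = 1 / 50, seed = s)
    expect_equal(nrow(out$state$nf), 2) # count conserved always
    if (out$events[["departs"]] > 0) {
      seen_depart <- TRUE
      moved <- out$state$nf[1, ]
      # entrant sits at gap R_b from one of the MTs and starts unbound
      gaps <- c(
        surface_distance(moved, p$r_N, st$mt[1, ], p$r_M),
        surface_distance(moved, p$r_N, st$mt[2, ], p$r_M))
      expect_lt(min(abs(gaps - p$R_b)), 1e-6)
      expect_true(is.na(out$bonds$nf[1]))
    }
  }
  expect_true(seen_depart)
})

test_that("no entry is possible when no MT has a neighboring NF", {
  p <- model_params()
  # single bound NF, isolated second MT far from everything: after the NF
  # departs there would be no NF near any MT, so departures must cancel
  fx <- make_bonded_pair(40, p)
  canc <- 0; dep <- 0
  for (s in 1:800) {
    out <- nf_binding_step(fx$state, fx$bonds, p, h = 1 / 50, seed = s)
    canc <- canc + out$events[["cancelled"]]
    dep <- dep + out$events[["departs"]]
  }
  expect_gt(canc, 0)
  expect_equal(dep, 0)
})

test_that("with binding switched off bonds only decay and never reform", {
  p <- model_params(k_on_N = 0)
  st <- random_state(6, 40, seed = 2, params = p)
  bd <- random_bonds(st, seed = 2, p_nf = 0.5, params = p)
  n0 <- sum(!is.na(bd$nf))
  expect_gt(n0, 0)
  cur <- bd
  for (s in 1:200) {
    out <- nf_binding_step(st, cur, p, h = 1 / 50, seed = s)
    n1 <- sum(!is.na(out$bonds$nf))
    expect_lte(n1, sum(!is.na(cur$nf)))
    cur <- out$bonds
    st <- out$state
  }
})

test_that("organelle arrivals fire at k_in per tick and enter at the rim of
           a track", {
  p <- model_params()
  st <- random_state(5, 20, seed = 3, params = p)
  bd <- empty_bonds(st)
  h <- 1 / 50
  n_trials <- 4000
  hits <- 0
  for (s in 1:n_trials) {
    out <- organelle_arrival_step(st, bd, p, h, seed = s)
    if (out$arrived > 0) {
      hits <- hits + 1
      og <- out$state$org
      expect_equal(nrow(og), 1)
      expect_equal(og$z, -og$a) # leading tip entering
      # engaged with exactly one MT, placed at gap R_b from it (radius 0)
      expect_equal(lengths(out$bonds$org), 1)
      m <- out$bonds$org[[1]]
      gap <- surface_distance(c(og$x, og$y), 0, st$mt[m, ], p$r_M)
      expect_lt(abs(gap - p$R_b), 1e-6)
    }
  }
  prob <- p$k_in_O * h
  se <- sqrt(prob * (1 - prob) / n_trials)
  expect_lt(abs(hits / n_trials - prob), 3 * se)
})

test_that("arrival without any microtubule is a no-op", {
  p <- model_params()
  st <- particle_state(mt = matrix(numeric(0), ncol = 2),
                       nf = matrix(c(0, 0), ncol = 2))
  out <- organelle_arrival_step(st, empty_bonds(st), p, h = 1, seed = 1)
  expect_equal(nrow(out$state$org), 0)
})

test_that("organelle transit is deterministic and ends after 2a/s_O", {
  p <- model_params()
  a <- p$org_aspect * p$org_b
  st <- particle_state(
    mt = matrix(c(0, 0), ncol = 2), nf = matrix(numeric(0), ncol = 2),
    org = data.frame(x = 300, y = 0, z = -a, a = a, b = p$org_b),
    domain = disk_domain(1500))
  bd <- bond_set(0, org = list(1L))
  h <- 0.1
  out <- list(state = st, bonds = bd)
  # half the transit brings it to the midpoint with maximal radius
  n_half <- round((a / (p$s_O * 1e3)) / h)
  for (i in seq_len(n_half)) out <- organelle_advance(out$state, out$bonds, p, h)
  expect_equal(out$state$org$z, 0, tolerance = 1e-9)
  expect_equal(organelle_radius(out$state$org$z, a, p$org_b), p$org_b)
  # the second half removes it, bonds included
  for (i in seq_len(n_half)) out <- organelle_advance(out$state, out$bonds, p, h)
  expect_equal(nrow(out$state$org), 0)
  expect_length(out$bonds$org, 0)
})

test_that("organelle engagement respects the m_max cap", {
  p <- model_params(m_max = 2)
  # organelle mid-passage surrounded by four MTs, all within reach
  a <- p$org_aspect * p$org_b
  st <- particle_state(
    mt = rbind(c(220, 0), c(-220, 0), c(0, 220), c(0, -220)),
    nf = matrix(numeric(0), ncol = 2),
    org = data.frame(x = 0, y = 0, z = 0, a = a, b = p$org_b),
    domain = disk_domain(1500))
  bd <- bond_set(0, org = list(integer(0)))
  for (s in 1:100) {
    out <- organelle_binding_step(st, bd, p, h = 1 / 2, seed = s)
    expect_lte(length(out$bonds$org[[1]]), 2)
    bd <- out$bonds
  }
  expect_equal(length(bd$org[[1]]), 2) # cap reached and held
})

test_that("uncapped engagement approaches the two-state stationary law", {
  p <- model_params() # k_on_O = k_off_O = 2 => stationary bound prob 0.5
  a <- p$org_aspect * p$org_b
  st <- particle_state(
    mt = rbind(c(220, 0), c(-220, 0), c(0, 220), c(0, -220)),
    nf = matrix(numeric(0), ncol = 2),
    org = data.frame(x = 0, y = 0, z = 0, a = a, b = p$org_b),
    domain = disk_domain(1500))
  h <- 1 / 50
  bd <- bond_set(0, org = list(integer(0)))
  n_bound <- 0; n_samp <- 0
  for (s in 1:6000) {
    out <- organelle_binding_step(st, bd, p, h = h, seed = s)
    bd <- out$bonds
    if (s > 500) { # discard burn-in
      n_bound <- n_bound + length(bd$org[[1]])
      n_samp <- n_samp + 4
    }
  }
  # tick-wise evaluation releases and re-engages within one tick, biasing
  # the stationary occupancy up by O(k h) ~ 0.01; allow for that plus ~3
  # standard errors of the autocorrelated average
  expect_lt(abs(n_bound / n_samp - 0.5), 0.06)
})
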