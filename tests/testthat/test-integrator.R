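# Euler-Maruyama integration: drift, diffusion, relaxation, step policy,
# and reproducibility.

test_that("noise-free step moves a particle by F/mu * h exactly", {
  p <- model_params(kT = 0)
  # bonded pair at gap 80: MT feels spring 14.4 pN minus repulsion
  fx <- make_bonded_pair(80, p)
  f0 <- total_forces(fx$state, fx$bonds, p)
  h <- 1 / 200
  out <- em_step(fx$state, fx$bonds, p, h = h, seed = 1)
  # drag in internal units is mu/1000 pN.s/nm
  expect_equal(out$state$mt[1, 1] - fx$state$mt[1, 1],
               f0$mt[1, 1] / (p$mu_M / 1000) * h, tolerance = 1e-12)
  expect_equal(out$state$nf[1, 1] - fx$state$nf[1, 1],
               f0$nf[1, 1] / (p$mu_N / 1000) * h, tolerance = 1e-12)
})

test_that("noise-free bonded pair relaxes to the equilibrium gap", {
  p <- model_params(kT = 0)
  dstar <- pair_equilibrium_gap(p)
  fx <- make_bonded_pair(60, p)
  s <- fx$state
  gaps <- numeric(0)
  for (i in 1:2500) {
    s <- em_step(s, fx$bonds, p, h = 1 / 200, seed = i)$state
    if (i %% 250 == 0) {
      gaps <- c(gaps, s$nf[1, 1] - s$mt[1, 1] - p$r_M - p$r_N)
    }
  }
  # monotone approach, converged to the independent root
  expect_true(all(diff(gaps) < 1e-9))
  expect_equal(gaps[length(gaps)], dstar, tolerance = 1e-3)
})

test_that("one-step drift error halves with the step (first-order scheme)", {
  p <- model_params(kT = 0)
  fx <- make_bonded_pair(60, p)
  # fine-step reference for the position after 1/100 s
  ref <- fx$state
  for (i in 1:256) ref <- em_step(ref, fx$bonds, p, h = 1 / 25600, seed = i)$state
  pos_h <- em_step(fx$state, fx$bonds, p, h = 1 / 100, seed = 1)$state
  half <- em_step(fx$state, fx$bonds, p, h = 1 / 200, seed = 1)$state
  pos_h2 <- em_step(half, fx$bonds, p, h = 1 / 200, seed = 2)$state
  e1 <- abs(pos_h$nf[1, 1] - ref$nf[1, 1])
  e2 <- abs(pos_h2$nf[1, 1] - ref$nf[1, 1])
  expect_lt(e2 / e1, 0.65) # close to the first-order ratio 0.5
})

test_that("free particles diffuse with MSD = 4 D tau", {
  p <- model_params()
  # isolated NFs on a sparse grid in a large periodic box: spacing far
  # beyond L_r, so they are independent random walkers
  g <- as.matrix(expand.grid(seq(500, 19500, by = 1000),
                             seq(500, 19500, by = 1000)))
  st <- particle_state(mt = matrix(numeric(0), ncol = 2), nf = g,
                       domain = periodic_domain(20000))
  tau <- 1
  tr <- run_sim(st, params = p, t_end = tau, series_dt = 0,
                snapshot_dt = tau, seed = 42)
  L <- 20000
  d <- tr$final_state$nf - st$nf
  d <- d - L * round(d / L) # min-image displacement
  msd <- mean(rowSums(d^2))
  D_nm <- p$kT / p$mu_N * 1e6
  expected <- 4 * D_nm * tau
  se <- expected * sqrt(2 / nrow(g)) # relative sd of chi^2 average
  expect_lt(abs(msd - expected), 3 * se)
})

test_that("step policy switches to the fast step only with organelles
           present", {
  p <- model_params()
  st <- random_state(5, 30, seed = 6, params = p)
  # no organelle flux: only slow steps
  p0 <- model_params(k_in_O = 0)
  tr0 <- run_sim(st, params = p0, t_end = 2, series_dt = 0, seed = 1)
  expect_equal(unname(tr0$counters[["fast_steps"]]), 0)
  # nominally one slow step per h_slow; the adaptive machinery may split
  # the occasional step near close contacts
  expect_gte(unname(tr0$counters[["slow_steps"]]), 2 / p0$h_slow)
  expect_lte(unname(tr0$counters[["slow_steps"]]), 1.2 * 2 / p0$h_slow)
  # an organelle present from the start: fast steps engaged
  a <- p$org_aspect * p$org_b
  st2 <- st
  st2$org <- data.frame(x = 0, y = 0, z = -a, a = a, b = p$org_b)
  ok <- FALSE
  for (shift in c(0, 50, 100, 150)) { # org may sit on top of a particle
    st2$org$x <- shift
    ok <- tryCatch({
      tr1 <- run_sim(st2, empty_bonds(st2), params = p0, t_end = 0.1,
                     series_dt = 0, seed = 1)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
  }
  expect_true(ok)
  expect_gt(unname(tr1$counters[["fast_steps"]]), 0)
})

test_that("runs are bitwise reproducible for a fixed seed", {
  p <- model_params()
  st <- random_state(6, 40, seed = 9, params = p)
  tr1 <- run_sim(st, params = p, t_end = 5, series_dt = 1, snapshot_dt = 5,
                 seed = 123)
  tr2 <- run_sim(st, params = p, t_end = 5, series_dt = 1, snapshot_dt = 5,
                 seed = 123)
  expect_identical(tr1$series, tr2$series)
  expect_identical(tr1$final_state$nf, tr2$final_state$nf)
  expect_identical(tr1$final_bonds, tr2$final_bonds)
  tr3 <- run_sim(st, params = p, t_end = 5, series_dt = 1, seed = 124)
  expect_false(identical(tr1$final_state$nf, tr3$final_state$nf))
})

test_that("zero-duration runs return only the initial record", {
  st <- random_state(4, 10, seed = 10)
  tr <- run_sim(st, t_end = 0, series_dt = 1, snapshot_dt = 1, seed = 1)
  expect_equal(nrow(tr$series), 1)
  expect_equal(tr$series$t, 0)
  expect_equal(tr$t_final, 0)
})

test_that("scheduled events change the kinetics at the right time", {
  p <- model_params()
  st <- random_state(6, 60, seed = 11, params = p)
  # block binding at t = 2 s: bonds can only decay afterwards
  sched <- event_schedule(2, "k_on_N", 0)
  tr <- run_sim(st, params = p, schedule = sched, t_end = 20,
                series_dt = 1, seed = 7)
  bf <- tr$series$bound_frac
  # with binding active some bonds typically form early; after blockage the
  # bound fraction must be non-increasing apart from nothing (no rebinding)
  after <- bf[tr$series$t >= 2]
  expect_true(all(diff(after) <= 1e-12))
})

test_that("NF count is conserved through full runs", {
  p <- model_params()
  st <- random_state(8, 60, seed = 12, params = p)
  tr <- run_sim(st, params = p, t_end = 30, series_dt = 0, snapshot_dt = 5,
                seed = 3)
  for (s in tr$snapshots) expect_equal(nrow(s$state$nf), 60)
  expect_equal(nrow(tr$final_state$nf), 60)
})

test_that("the engagement cap is never violated along a run", {
  p <- model_params(m_max = 2)
  st <- random_state(10, 40, seed = 13, params = p)
  tr <- run_sim(st, params = p, t_end = 60, series_dt = 0, snapshot_dt = 2,
                seed = 5)
  for (s in tr$snapshots) {
    if (length(s$bonds$org)) expect_lte(max(lengths(s$bonds$org)), 2)
  }
})
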