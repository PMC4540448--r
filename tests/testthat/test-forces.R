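# Force laws: scalar profiles, cutoffs, pair symmetry, and equivalence of
# the compiled kernel with the plain-R double-loop oracle.

test_that("repulsion profile diverges at contact and vanishes at the cutoff", {
  expect_equal(repulsion_force(121.2, 0.5, 121.2), 0)
  expect_equal(repulsion_force(121.2 / 2, 0.5, 121.2), 0.5)
  expect_equal(repulsion_force(2 * 121.2, 0.5, 121.2), 0)
  expect_error(repulsion_force(0), "contact")
  expect_error(repulsion_force(-5), "contact")
  # monotone decreasing, continuous at the cutoff
  d <- seq(1, 121.2, length.out = 50)
  f <- repulsion_force(d)
  expect_true(all(diff(f) < 0))
  expect_lt(repulsion_force(121.19), 1e-4)
})

test_that("spring profile is linear inside the binding radius, zero beyond", {
  expect_equal(spring_force(0, 0.18, 80), 0)
  expect_equal(spring_force(50, 0.18, 80), 9)
  expect_equal(spring_force(100, 0.18, 80), 0)
  expect_equal(spring_force(80, 0.18, 80), 0.18 * 80)
})

test_that("boundary force pushes inward with the repulsion profile", {
  p <- model_params()
  # deep interior: no force
  expect_equal(boundary_force(c(0, 0), 5, 1000), c(0, 0))
  # at gap L_r: exactly zero
  x <- c(1000 - 5 - 121.2, 0)
  expect_equal(boundary_force(x, 5, 1000), c(0, 0))
  # at gap L_r/2: inward magnitude eps
  x <- c(1000 - 5 - 121.2 / 2, 0)
  f <- boundary_force(x, 5, 1000)
  expect_equal(f, c(-0.5, 0))
  expect_error(boundary_force(c(995, 0), 5, 1000), "contact")
})

test_that("bonded pair balances spring against repulsion at the expected gap", {
  p <- model_params()
  dstar <- pair_equilibrium_gap(p)
  expect_equal(dstar, 17.012, tolerance = 1e-4)
  fx <- make_bonded_pair(dstar, p)
  f <- total_forces(fx$state, fx$bonds, p)
  expect_lt(abs(f$mt[1, 1]), 1e-9)
  # attraction dominates at wide gaps, repulsion at narrow ones
  f80 <- total_forces(make_bonded_pair(80, p)$state, bond_set(1, 1L), p)
  expect_gt(f80$mt[1, 1], 0) # MT pulled towards the NF (at +x)
  f5 <- total_forces(make_bonded_pair(5, p)$state, bond_set(1, 1L), p)
  expect_lt(f5$mt[1, 1], 0) # MT pushed away
  # magnitudes match the scalar laws
  expect_equal(f80$mt[1, 1], spring_force(80) - repulsion_force(80))
  expect_equal(f5$mt[1, 1], spring_force(5) - repulsion_force(5))
})

test_that("compiled force field matches the brute-force oracle", {
  p <- model_params()
  for (seed in 1:3) {
    st <- random_state(6, 40, n_org = 2, seed = seed, params = p)
    bd <- random_bonds(st, seed = seed, params = p)
    got <- total_forces(st, bd, p)
    want <- bf_forces(st, bd, p)
    expect_equal(got$mt, want$mt, tolerance = 1e-12)
    expect_equal(got$nf, want$nf, tolerance = 1e-12)
    expect_equal(got$org, want$org, tolerance = 1e-12)
  }
  # periodic metric too
  stp <- random_state(0, 60, domain = periodic_domain(1000), seed = 4,
                      params = p)
  gotp <- total_forces(stp, empty_bonds(stp), p)
  wantp <- bf_forces(stp, empty_bonds(stp), p)
  expect_equal(gotp$nf, wantp$nf, tolerance = 1e-12)
})

test_that("internal pair forces cancel (Newton's third law)", {
  p <- model_params()
  stp <- random_state(8, 60, domain = periodic_domain(1500), seed = 5,
                      params = p)
  bd <- random_bonds(stp, seed = 5, params = p)
  f <- total_forces(stp, bd, p)
  # periodic domain: no boundary force, so everything must cancel
  tot <- colSums(f$mt) + colSums(f$nf)
  if (nrow(f$org)) tot <- tot + colSums(f$org)
  expect_equal(tot, c(0, 0), tolerance = 1e-10)
})

test_that("repulsion prefactor doubles only while an organelle pushes in", {
  p <- model_params()
  mk <- function(z) {
    # organelle radius at |z| = 700 is 105; the NF at x = 200 sits at a
    # surface gap of 90 nm, inside the repulsion range
    particle_state(
      mt = matrix(numeric(0), ncol = 2),
      nf = matrix(c(200, 0), ncol = 2),
      org = data.frame(x = 0, y = 0, z = z, a = 1400, b = 140),
      domain = disk_domain(2000), mt_radius = p$r_M, nf_radius = p$r_N)
  }
  # same geometry: |z| equal so the radius is identical, only the sign flips
  f_in <- total_forces(mk(-700), params = p)
  f_out <- total_forces(mk(700), params = p)
  expect_equal(f_in$nf[1, 1], 2 * f_out$nf[1, 1], tolerance = 1e-12)
  expect_gt(f_in$nf[1, 1], 0) # pushed away from the organelle
  # doubling can be disabled
  p0 <- model_params(eps_double = FALSE)
  f_in0 <- total_forces(mk(-700), params = p0)
  expect_equal(f_in0$nf[1, 1], f_out$nf[1, 1], tolerance = 1e-12)
})

test_that("overlapping configurations raise a contact error", {
  st <- particle_state(mt = matrix(c(0, 0), ncol = 2),
                       nf = matrix(c(10, 0), ncol = 2))
  expect_error(total_forces(st), "contact")
})

test_that("single centered particle feels no force", {
  st <- particle_state(mt = matrix(c(0, 0), ncol = 2),
                       nf = matrix(numeric(0), ncol = 2))
  f <- total_forces(st)
  expect_equal(f$mt, matrix(0, 1, 2))
})
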