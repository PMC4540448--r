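# Domain types, units, and closed-form parameter relations.

test_that("surface distance follows the metric and is symmetric", {
  d <- disk_domain(1000)
  expect_equal(surface_distance(c(0, 0), 12.5, c(100, 0), 12.5, d), 75)
  expect_equal(surface_distance(c(0, 0), 5, c(0, 0), 5, d), -10)
  expect_equal(surface_distance(c(0, 0), 12.5, c(17.5, 0), 5, d), 0)
  # symmetry on random pairs
  set.seed(7)
  for (i in 1:20) {
    xi <- runif(2, -500, 500); xj <- runif(2, -500, 500)
    expect_equal(surface_distance(xi, 5, xj, 12.5, d),
                 surface_distance(xj, 12.5, xi, 5, d))
  }
})

test_that("periodic surface distance uses the minimum image", {
  p <- periodic_domain(1000)
  # wrap-around: centers at 10 and 990 are only 20 apart
  expect_equal(surface_distance(c(10, 0), 5, c(990, 0), 5, p), 10)
  # never exceeds half the box diagonal
  set.seed(8)
  for (i in 1:50) {
    xi <- runif(2) * 1000; xj <- runif(2) * 1000
    expect_lte(surface_distance(xi, 0, xj, 0, p),
               sqrt(2) * 500 + 1e-9)
  }
})

test_that("organelle cross-section radius follows the spindle profile", {
  expect_equal(organelle_radius(0, 1400, 140), 140)
  expect_equal(organelle_radius(1400, 1400, 140), 0)
  expect_equal(organelle_radius(-1400, 1400, 140), 0)
  expect_equal(organelle_radius(700, 1400, 140), 105)
  expect_error(organelle_radius(1500, 1400, 140), "out of range")
  # even in z, maximal at z = 0
  z <- seq(-1400, 1400, by = 100)
  r <- organelle_radius(z, 1400, 140)
  expect_equal(r, rev(r))
  expect_true(all(r <= r[z == 0]))
})

test_that("Einstein relation reproduces the reference diffusivities", {
  D <- einstein_diffusion(c(73.5, 512, 40.3), 4.11e-3)
  expect_lt(abs(D[1] - 5.59e-5) / 5.59e-5, 1.5e-3)
  expect_lt(abs(D[2] - 8.02e-6) / 8.02e-6, 1.5e-3)
  expect_lt(abs(D[3] - 1.02e-4) / 1.02e-4, 1.5e-3)
  # exact round trip
  expect_equal(einstein_diffusion(73.5, 4.11e-3) * 73.5, 4.11e-3)
  expect_error(einstein_diffusion(-1), "positive")
  expect_error(einstein_diffusion(73.5, 0), "positive")
})

test_that("counts from densities give the reference populations", {
  expect_identical(counts_from_density(18, 1), 56L)
  expect_identical(counts_from_density(115, 1), 361L)
  expect_identical(counts_from_density(0.1, 1), 0L)
  expect_error(counts_from_density(-1, 1), "positive")
})

test_that("two-state engagement kinetics give the expected fractions", {
  p <- model_params()
  expect_equal(nf_bound_fraction(p), 1 / (1 + 6.5))
  expect_equal(round(nf_bound_fraction(p), 2), 0.13)
  expect_lt(abs(nf_dual_binding_prob(p) - 0.017), 1e-3)
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(model_params(r_N = -5), "positive")
  expect_error(model_params(k_on_N = -1), "non-negative")
  expect_error(model_params(m_max = 2.5), "m_max")
  expect_error(model_params(m_max = 0), "m_max")
  expect_error(model_params(h_fast = 1, h_slow = 1 / 50), "h_fast")
  expect_error(model_params(org_aspect = 0.5), "aspect")
  expect_error(model_params(nonsense = 1), "unknown")
  # kT = 0 is allowed (noise-free mechanics for deterministic checks)
  expect_s3_class(model_params(kT = 0), "axc_params")
})

test_that("the internal unit conversion is coherent", {
  p <- model_params()
  v <- axoncross:::.par_vec(p)
  expect_equal(unname(v["s_O"]), 1000)            # nm/s
  expect_equal(unname(v["mu_N"]), 73.5 / 1000)    # pN.s/nm
  expect_equal(unname(v["D_N"]), 4.11e-3 / 73.5 * 1e6) # nm^2/s
  expect_equal(unname(v["org_a"]), 1400)
  expect_equal(unname(v["m_max"]), 0)             # Inf encoded as 0
})

test_that("event schedules are validated", {
  s <- event_schedule(c(3600, 13 * 3600), c("k_on_N", "k_on_N"), c(0, 1e-2))
  expect_equal(nrow(s), 2)
  expect_error(event_schedule(c(2, 1), c("k_on_N", "k_on_N"), c(0, 0)),
               "non-decreasing")
  expect_error(event_schedule(1, "r_M", 5), "not schedulable")
})

test_that("particle states validate organelle axial offsets", {
  expect_error(
    particle_state(matrix(0, 1, 2), matrix(c(100, 0), 1, 2),
                   org = data.frame(x = 0, y = 0, z = 2000, a = 1400,
                                    b = 140)),
    "half-length")
})
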