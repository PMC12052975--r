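test_that("landscape archetypes evaluate to their closed forms", {
  h <- landscape("harmonic", list(k = 2, z0 = 0))
  e <- evaluate_landscape(h, 1)
  expect_equal(e$energy, 1.0)
  expect_equal(e$force, -2.0)

  dw <- landscape("double_well", list(barrier = 12, minima = 0.8))
  expect_equal(evaluate_landscape(dw, c(-0.8, 0, 0.8))$energy, c(0, 12, 0))
  expect_equal(evaluate_landscape(dw, c(-0.8, 0.8))$force, c(0, 0))

  tab <- landscape("tabulated", grid = c(0, 1), values = c(0, 4))
  e <- evaluate_landscape(tab, 0.5)
  expect_equal(e$energy, 2.0)
  expect_equal(e$force, -4.0)

  expect_equal(evaluate_landscape(landscape("flat"), c(-1, 0, 2))$energy,
               c(0, 0, 0))
})

test_that("landscape forces agree with finite differences", {
  for (kind in c("substrate_downhill", "nonsubstrate_entry_barrier",
                 "double_well")) {
    land <- make_landscape(kind)
    f <- function(z) evaluate_landscape(land, z)$energy
    for (z in seq(-1.0, 1.9, by = 0.37))
      expect_equal(evaluate_landscape(land, z)$force, fd_force(f, z),
                   tolerance = 1e-6)
  }
})

test_that("landscape validation rejects bad configurations", {
  expect_error(landscape("bogus"), "unknown landscape kind")
  expect_error(landscape("tabulated", grid = c(1, 0), values = c(0, 1)),
               "strictly increasing")
  expect_error(landscape("tabulated", grid = c(0, 1), values = 1),
               ">= 2 nodes")
  expect_warning(evaluate_landscape(landscape("flat"), 99), "clamped")
})

test_that("wall energy is one-sided, continuous and pushes back", {
  w <- wall_spec()
  inside <- wall_energy(w, c(-1.1, 0, 2))
  expect_equal(inside$energy, c(0, 0, 0))
  expect_equal(inside$force, c(0, 0, 0))
  expect_equal(wall_energy(w, 2.1)$energy, 5.0)
  expect_equal(wall_energy(w, -1.2)$force, 100) # pushes up
  # finite-difference sign/magnitude check
  ew <- function(z) wall_energy(w, z)$energy
  expect_equal(wall_energy(w, -1.2)$force, fd_force(ew, -1.2),
               tolerance = 1e-5)
  # continuity at the bound
  expect_lt(wall_energy(w, 2.0 + 1e-9)$energy, 1e-12)
  expect_error(wall_spec(exponent = 3))
  expect_error(wall_spec(lower_at = 2, upper_at = 1))
})

test_that("Langevin runs are deterministic and frozen at zero temperature", {
  dw <- make_landscape("double_well")
  a <- run_langevin(dw, langevin_params(), wall_spec(), NULL, 2000, 0.3,
                    seed = 5)
  b <- run_langevin(dw, langevin_params(), wall_spec(), NULL, 2000, 0.3,
                    seed = 5)
  expect_identical(a$z, b$z)
  expect_identical(a$velocity, b$velocity)
  c <- run_langevin(dw, langevin_params(), wall_spec(), NULL, 2000, 0.3,
                    seed = 6)
  expect_false(identical(a$z, c$z))
  expect_equal(a$time, seq(0, 4, by = 0.002))

  cold <- run_langevin(dw, langevin_params(temperature = 1e-300),
                       wall_spec(), NULL, 1000, 0.8, seed = 1, v0 = 0)
  expect_lt(max(abs(cold$z - 0.8)), 1e-7)
})

test_that("harmonic-well sampling satisfies equipartition", {
  h <- landscape("harmonic", list(k = 10, z0 = 0))
  tr <- run_langevin(h, langevin_params(), wall_spec(-5, 5, 0), NULL, 2e6,
                     0, seed = 1, stride = 10)
  expect_equal(var(tr$z), kB_ref * 303.15 / 10, tolerance = 0.05)
  expect_equal(var(tr$velocity), kB_ref * 303.15 / 50, tolerance = 0.05)
})

test_that("wall confinement bounds excursions", {
  # steep downhill towards the lower wall: excursion energy stays << 20 kT
  land <- make_landscape("substrate_downhill")
  walls <- wall_spec()
  tr <- run_langevin(land, langevin_params(), walls, NULL, 2e5, 1.9,
                     seed = 9, stride = 10)
  exc <- pmax(tr$z - walls$upper_at, walls$lower_at - tr$z, 0)
  expect_lt(max(0.5 * walls$kappa * exc^2), 20 * kB_ref * 303.15)
})

test_that("function-valued biases follow the same propagation law", {
  # at T -> 0 the propagation is a deterministic ODE, so a harmonic bias
  # function (R path) must reproduce a harmonic landscape (compiled path)
  cold <- langevin_params(temperature = 1e-300)
  bias <- function(z) list(energy = 0.5 * 10 * (z - 0.3)^2,
                           force = -10 * (z - 0.3))
  tr_r <- run_langevin(make_landscape("flat"), cold, wall_spec(-5, 5, 0),
                       bias, 2000, 0.8, seed = 4, v0 = 0.05)
  tr_c <- run_langevin(landscape("harmonic", list(k = 10, z0 = 0.3)), cold,
                       wall_spec(-5, 5, 0), NULL, 2000, 0.8, seed = 4,
                       v0 = 0.05)
  expect_equal(tr_r$z, tr_c$z, tolerance = 1e-10)
  expect_equal(tr_r$bias_energy, 0.5 * 10 * (tr_r$z - 0.3)^2)
  # stochastic sanity: the biased flat landscape samples the bias's well
  tr_s <- run_langevin(make_landscape("flat"), langevin_params(),
                       wall_spec(-5, 5, 0), bias, 2e4, 0.3, seed = 9,
                       stride = 10)
  expect_lt(abs(mean(tr_s$z) - 0.3), 0.25)
})

test_that("COLVAR round trip is lossless", {
  dw <- make_landscape("double_well")
  tr <- run_langevin(dw, langevin_params(), wall_spec(), NULL, 500, 0.1,
                     seed = 2, stride = 10)
  path <- tempfile(fileext = ".colvar")
  write_colvar(tr, path)
  back <- read_colvar(path)
  expect_equal(back$z, tr$z)
  expect_equal(back$time, tr$time)
  expect_equal(back$total_force, tr$total_force)
  expect_equal(readLines(path, n = 1), "#! FIELDS time dz bias force velocity")
})
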