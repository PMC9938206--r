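test_that("reference parameter set reproduces the printed derived scales", {
  p <- pf_params()
  g <- nondimensionalize(p)
  # sharp-interface bending rigidity: (4 eps^3 / 3 sqrt 2) kappa_B = 2.0 aJ
  expect_equal(g$K_B, 2.0, tolerance = 0.01)
  expect_equal(derive_bending_rigidity(432, 0.17), g$K_B)
  # adhesion energy per area at the weak setting: 17.1 aJ/um^2
  expect_equal(adhesion_energy_per_area(8.0, 0.17), 17.1, tolerance = 0.01)
  # reduced volume of the target cell: 0.614 at printed rounding
  expect_equal(reduced_volume(197, 160), 0.614, tolerance = 0.003)
  # timescale tau = 1/(M kappa_B)
  expect_equal(g$tau, 1 / (0.074 * 432), tolerance = 1e-12)
  expect_equal(g$gamma_prime, 138 / 432)
  expect_equal(g$eta_prime, 8 / (432 * 0.17^2))
  expect_equal(g$v_prime, 0.57 / (0.074 * 432 * 0.17))
})

test_that("unit conversion round-trips every display value to >= 6 digits", {
  p <- pf_params()
  back <- params_display(p)
  for (nm in names(back)) {
    expect_equal(back[[nm]], p$display[[nm]], tolerance = 1e-10, label = nm)
  }
})

test_that("derived quantities obey their scaling laws", {
  set.seed(11)
  for (i in 1:20) {
    k <- runif(1, 10, 1000)
    e <- runif(1, 0.05, 0.5)
    eta <- runif(1, 0.5, 50)
    s <- runif(1, 1.1, 4)
    # linear in kappa_B, cubic in epsilon
    expect_equal(derive_bending_rigidity(s * k, e),
                 s * derive_bending_rigidity(k, e))
    expect_equal(derive_bending_rigidity(k, s * e),
                 s^3 * derive_bending_rigidity(k, e))
    # linear in eta, inversely proportional to epsilon
    expect_equal(adhesion_energy_per_area(s * eta, e),
                 s * adhesion_energy_per_area(eta, e))
    expect_equal(adhesion_energy_per_area(eta, s * e),
                 adhesion_energy_per_area(eta, e) / s)
  }
  # zero coefficients give zero energies
  expect_identical(derive_bending_rigidity(0, 0.17), 0)
  expect_identical(adhesion_energy_per_area(0, 0.17), 0)
})

test_that("reduced volume is exact on spheres, linear in V, and guards the sphere bound", {
  for (R in c(0.3, 1, 4.2)) {
    expect_equal(reduced_volume(4 * pi * R^2, 4 / 3 * pi * R^3), 1)
  }
  expect_equal(reduced_volume(197, 80), reduced_volume(197, 160) / 2)
  expect_warning(reduced_volume(4 * pi, 4 / 3 * pi * 1.01),
                 "exceeds 1")
})

test_that("invalid parameters are rejected", {
  expect_error(derive_bending_rigidity(432, 0), "epsilon")
  expect_error(derive_bending_rigidity(432, -1), "epsilon")
  expect_error(adhesion_energy_per_area(8, 0), "epsilon")
  expect_error(reduced_volume(0, 1), "S and V")
  expect_error(pf_params(epsilon = 0), "epsilon")
  expect_error(pf_params(kappa_B = -1), "non-negative")
  expect_error(nondimensionalize(pf_params(M = 0)), "timescale")
})

test_that("parameter objects are immutable and overrides create new instances", {
  p <- pf_params()
  q <- update_params(p, eta = 2.7e-11)
  expect_equal(p$display$eta, 8.0e-12)
  expect_equal(q$display$eta, 2.7e-11)
  expect_equal(q$internal$eta, 27)
  expect_equal(q$display$kappa_B, p$display$kappa_B)
  expect_error(update_params(p, bogus = 1), "unknown parameter")
  # strong adhesion is 3.375x the weak one, as is its energy per area
  expect_equal(adhesion_energy_per_area(27, 0.17),
               3.375 * adhesion_energy_per_area(8, 0.17))
})

test_that("configuration files parse with sections, units and overrides", {
  cfg_file <- tempfile(fileext = ".cfg")
  writeLines(c("# run configuration",
               "[physics]",
               "kappa_B = 432 J/m^3",
               "eta     = 8.0e-12 J/m",
               "[grid]",
               "n  = 48 48 64",
               "dx = 0.17 um",
               "[protocol]",
               "offset_d = 3.06 um",
               "total_time = 2.5 s"), cfg_file)
  cfg <- read_config(cfg_file, overrides = "physics.eta=2.7e-11")
  expect_equal(cfg$physics$kappa_B, 432)
  expect_equal(cfg$physics$eta, 2.7e-11)
  expect_equal(cfg$grid$n, c(48, 48, 64))
  obj <- config_objects(cfg)
  expect_s3_class(obj$params, "pf_params")
  expect_equal(obj$grid$n, c(48L, 48L, 64L))
  expect_equal(obj$protocol$offset_d, 3.06)
  expect_equal(obj$protocol$eta, 2.7e-11)
  unlink(cfg_file)
})
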