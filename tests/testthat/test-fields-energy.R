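test_that("interpolation function h has the required anchors and derivative", {
  expect_identical(h_interp(-1), 0)
  expect_identical(h_interp(1), 1)
  expect_identical(h_interp(0), 0.5)
  expect_equal(h_interp(0.5), 0.84375) # 1/4 * 1.5^2 * 1.5
  # h' = (3/4)(1 - phi^2): vanishes in both bulk phases
  x <- seq(-1.2, 1.2, by = 0.05)
  num <- (h_interp(x + 1e-6) - h_interp(x - 1e-6)) / 2e-6
  expect_equal(num, 0.75 * (1 - x^2), tolerance = 1e-8)
})

test_that("tanh spheres recover analytic area and volume within 2%", {
  g <- grid_spec(c(64, 64, 64))
  for (R in c(2, 3, 4)) {
    f <- make_tanh_field(cell_init_spec(g$box / 2, "sphere", R), g, EPS,
                         margin = 0.5)
    expect_equal(surface_of(f, EPS), 4 * pi * R^2, tolerance = 0.02)
    expect_equal(volume_of(f), 4 / 3 * pi * R^3, tolerance = 0.02)
  }
  # uniform outside phase: no interface, no volume
  empty <- pf_field(array(-1, g$n), g)
  expect_equal(surface_of(empty, EPS), 0, tolerance = 1e-10)
  expect_equal(volume_of(empty), 0)
  full <- pf_field(array(1, g$n), g)
  expect_equal(volume_of(full), prod(g$box))
})

test_that("geometry error shrinks as the interface is refined", {
  # refine dx and the interface width together (the lattice resolves one
  # interface width by construction); the sharp-interface error is O(eps^2)
  R <- 2
  err <- sapply(c(0.34, 0.17), function(eps) {
    g <- grid_spec(rep(round(6.8 / eps), 3), dx = eps)
    f <- make_tanh_field(cell_init_spec(g$box / 2, "sphere", R), g, eps,
                         margin = 0.3)
    abs(volume_of(f) - 4 / 3 * pi * R^3)
  })
  expect_lt(err[2], 0.6 * err[1])
})

test_that("bending energy of tanh spheres is radius-independent (Helfrich sphere)", {
  g <- grid_spec(c(64, 64, 64))
  p <- ref_params()
  eb <- sapply(c(2, 3, 4), function(R) {
    f <- make_tanh_field(cell_init_spec(g$box / 2, "sphere", R), g, EPS,
                         margin = 0.5)
    far <- pf_field(array(-1, g$n), g, 2L)
    free_energy(f, far, update_params(p, alpha_S = 0, alpha_V = 0))$bending
  })
  expect_lt(max(eb) / min(eb) - 1, 0.05)
})

test_that("separated cells have negligible interaction energy", {
  sp <- sphere_pair(n = 40, R = 1.0, surface_gap = 2.0) # surface gap 2 um > 10 eps
  en <- free_energy(sp$f1, sp$f2, ref_params())
  expect_lt(abs(en$repulsion), 1e-3)
  # the adhesion integral carries a small spectral-ringing floor from the
  # marginally resolved interface, independent of separation
  expect_lt(abs(en$adhesion), 5e-3)
  expect_equal(en$total,
               en$bending + en$repulsion + en$adhesion +
                 en$surface_penalty + en$volume_penalty)
  expect_gte(en$bending, 0)
})

test_that("slab pair in full contact reproduces the sharp-interface adhesion constant", {
  sl <- slab_pair()
  p <- ref_params()
  en <- free_energy(sl$f1, sl$f2, p)
  expected <- -adhesion_energy_per_area(p$internal$eta, EPS) * sl$cross_section
  expect_equal(en$adhesion, expected, tolerance = 0.02)
  # adhesion is negative for anti-parallel interfaces with eta > 0
  expect_lt(en$adhesion, 0)
  # and exactly linear in eta
  en2 <- free_energy(sl$f1, sl$f2, update_params(p, eta = 1.6e-11))
  expect_equal(en2$adhesion, 2 * en$adhesion)
})

test_that("drift matches the finite-difference functional derivative", {
  sp <- sphere_pair(n = 28, R = 1.2, surface_gap = -0.75)
  p <- update_params(ref_params(),
                     S_target = surface_of(sp$f1, EPS) * 0.98,
                     V_target = volume_of(sp$f1) * 0.98)
  M <- p$internal$M
  drift <- variational_derivative(sp$f1, sp$f2, p)
  set.seed(3)
  act <- which(abs(drift) > 0.02 * max(abs(drift)))
  idx <- sample(act, 20)
  delta <- 1e-5
  for (q in idx) {
    a <- sp$f1; a$values[q] <- a$values[q] + delta
    b <- sp$f1; b$values[q] <- b$values[q] - delta
    fd <- -M * (free_energy(a, sp$f2, p)$total -
                  free_energy(b, sp$f2, p)$total) / (2 * delta * sp$grid$dV)
    expect_equal(drift[q], fd, tolerance = 1e-4)
  }
})

test_that("drift vanishes on the homogeneous outside state and respects mirror symmetry", {
  g <- grid_spec(c(24, 24, 24))
  p <- ref_params()
  hom <- pf_field(array(-1, g$n), g)
  expect_lt(max(abs(variational_derivative(hom, hom, p))), 1e-10)
  sp <- sphere_pair(n = 28, R = 1.2, surface_gap = -0.75)
  d <- variational_derivative(sp$f1, sp$f2, p)
  m1 <- mirror_field(sp$f1, 3); m2 <- mirror_field(sp$f2, 3)
  dm <- variational_derivative(m1, m2, p)
  expect_equal(dm, mirror_field(pf_field(d, sp$grid), 3)$values, tolerance = 1e-10)
})

test_that("field constructors validate their inputs", {
  g <- grid_spec(c(16, 16, 16))
  expect_error(pf_field(array(0, c(8, 8, 8)), g), "dimensions")
  expect_error(grid_spec(c(15, 16, 16)), "even")
  expect_error(make_tanh_field(cell_init_spec(c(1, 1, 1), "sphere", 2), g, EPS),
               "margin")
  expect_error(cell_init_spec(c(0, 0, 0), "sphere", -1), "semi_axes")
  # mismatched grids refused by the energy
  g2 <- grid_spec(c(24, 24, 24))
  f1 <- pf_field(array(-1, g$n), g)
  f2 <- pf_field(array(-1, g2$n), g2)
  expect_error(free_energy(f1, f2, ref_params()), "share one grid")
})

test_that("mirror-symmetric seeds give mirror-symmetric fields and embedding preserves content", {
  g <- grid_spec(c(32, 32, 32))
  f <- make_tanh_field(cell_init_spec(g$box / 2, "sphere", 1.5), g, EPS,
                       margin = 0.4)
  expect_equal(mirror_field(f, 1)$values, f$values, tolerance = 1e-12)
  # centre is inside, corner outside
  ctr <- round(g$n / 2)
  expect_gt(f$values[ctr[1], ctr[2], ctr[3]], 0.99)
  expect_lt(f$values[2, 2, 2], -0.99)
  big <- grid_spec(c(48, 48, 48))
  emb <- embed_field(f, big)
  expect_equal(volume_of(emb), volume_of(f), tolerance = 1e-10)
})
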