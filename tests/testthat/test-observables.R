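test_that("interaction force vanishes for separated cells", {
  sp <- sphere_pair(n = 40, R = 1.0, surface_gap = 2.0)
  fr <- interaction_force(sp$f1, sp$f2, ref_params())
  expect_lt(sqrt(sum(fr$F1^2)), 1)
  expect_lt(sqrt(sum(fr$F2^2)), 1)
})

test_that("force obeys action-reaction, decomposition and eta-linearity", {
  # approaching membranes, not yet past the adhesion minimum (coincident
  # interfaces): the adhesion part pulls the upper cell down while any
  # repulsion part pushes it up
  sp <- sphere_pair(n = 32, R = 1.2, surface_gap = 0.15)
  p <- ref_params()
  fr <- interaction_force(sp$f1, sp$f2, p)
  fmax <- max(abs(c(fr$F1, fr$F2)))
  expect_gt(fmax, 1) # the fixture does interact
  expect_lt(max(abs(fr$F1 + fr$F2)), 0.01 * fmax)
  expect_equal(fr$F1, fr$F1_rep + fr$F1_adh, tolerance = 1e-12)
  expect_gt(fr$F2_rep[3], -1e-6)
  expect_lt(fr$F2_adh[3], 0)
  # doubling eta doubles exactly the adhesion part and leaves repulsion
  fr2 <- interaction_force(sp$f1, sp$f2, update_params(p, eta = 1.6e-11))
  expect_equal(fr2$F2_adh, 2 * fr$F2_adh, tolerance = 1e-12)
  expect_equal(fr2$F2_rep, fr$F2_rep, tolerance = 1e-12)
})

test_that("force z-component matches the virtual-work central difference", {
  sp <- sphere_pair(n = 32, R = 1.4, surface_gap = -1.0)
  p <- ref_params()
  fr <- interaction_force(sp$f1, sp$f2, p)
  inter_energy <- function(f2) {
    en <- free_energy(sp$f1, f2, p)
    en$repulsion + en$adhesion
  }
  dz <- sp$grid$dx
  eup <- inter_energy(shift_field(sp$f2, c(0, 0, 1)))
  edn <- inter_energy(shift_field(sp$f2, c(0, 0, -1)))
  virtual <- -(eup - edn) / (2 * dz) # aJ/um = pN, force on cell 2
  expect_equal(fr$F2[3], virtual, tolerance = 0.05)
})

test_that("contact area reduces to the patch area on slabs and to zero when apart", {
  sl <- slab_pair()
  expect_equal(contact_area(sl$f1, sl$f2, EPS), sl$cross_section,
               tolerance = 0.05)
  sp <- sphere_pair(n = 40, R = 1.0, surface_gap = 2.0)
  expect_lt(contact_area(sp$f1, sp$f2, EPS), 0.05)
})

test_that("detachment work integrates attractive force over the retraction", {
  proto <- collision_protocol(total_time = 3, reversal_time = 1, speed_v = 0.57)
  tt <- seq(0, 3, by = 0.05)
  # triangular attractive pulse of peak P over (1, 1+T) during retraction
  P <- 120; Tw <- 1
  fz <- ifelse(tt > 1 & tt < 1 + Tw,
               -P * (1 - abs((tt - 1 - Tw / 2) / (Tw / 2))), 0)
  traj <- structure(list(protocol = proto,
                         force = data.frame(t = tt, F2z = fz)),
                    class = "pf_trajectory")
  expect_equal(detachment_work(traj),
               2 * 0.57 * P * Tw / 2 / 1000, tolerance = 0.01)
  traj0 <- traj; traj0$force$F2z <- 0
  expect_equal(detachment_work(traj0), 0)
  # no retraction coverage -> error
  early <- traj; early$force <- early$force[early$force$t < 0.5, ]
  expect_error(detachment_work(early), "retraction")
})

test_that("trajectory outputs round-trip exactly and the manifest hash tracks parameters", {
  proto <- collision_protocol(total_time = 2, reversal_time = 1)
  g <- grid_spec(c(16, 16, 16))
  traj <- structure(list(
    protocol = proto, params = ref_params(), grid = g,
    force = data.frame(t = c(0, 0.5), F2z = c(pi, -exp(1)), F1x = c(1e-17, 2)),
    energy = data.frame(t = c(0, 0.5), total = c(1.23456789012345678, 2)),
    contact = data.frame(t = c(0, 0.5), contact_area = c(0, 55.5)),
    geometry = NULL,
    snapshots = list(list(t = 0, phi1 = array(-1, g$n), phi2 = array(-1, g$n)))),
    class = "pf_trajectory")
  dest <- tempfile()
  write_outputs(traj, dest)
  back <- read_outputs(dest)
  expect_identical(back$force$F2z, traj$force$F2z)
  expect_identical(back$energy$total, traj$energy$total)
  expect_equal(length(list.files(dest, pattern = "snapshot.*vtk")), 1L)
  # hash invariance / sensitivity
  m1 <- rbcphase:::run_manifest(traj)
  traj2 <- traj
  m2 <- rbcphase:::run_manifest(traj2)
  expect_identical(m1$parameter_hash, m2$parameter_hash)
  traj2$params <- update_params(traj$params, eta = 2.7e-11)
  m3 <- rbcphase:::run_manifest(traj2)
  expect_false(identical(m1$parameter_hash, m3$parameter_hash))
  unlink(dest, recursive = TRUE)
})

test_that("VTK snapshots carry the grid header and all fields", {
  g <- grid_spec(c(8, 8, 8))
  path <- tempfile(fileext = ".vtk")
  write_vtk_fields(path, g, list(a = array(0, g$n), b = array(1, g$n)))
  lines <- readLines(path)
  expect_true(any(grepl("DIMENSIONS 8 8 8", lines)))
  expect_true(any(grepl("SCALARS a double 1", lines)))
  expect_true(any(grepl("SCALARS b double 1", lines)))
  expect_equal(sum(grepl("LOOKUP_TABLE", lines)), 2L)
  unlink(path)
})
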