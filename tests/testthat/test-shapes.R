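test_that("ellipsoid seeds match requested area and volume", {
  for (kind in c("oblate", "prolate")) {
    nu <- if (kind == "oblate") 0.614 else 0.9
    S <- 197
    V <- nu * (4 / 3) * pi * (S / (4 * pi))^1.5
    ax <- ellipsoid_axes_for(S, V, kind)
    expect_equal(4 / 3 * pi * prod(ax), V, tolerance = 1e-6)
    # area check on a fine tanh realisation
    g <- grid_spec(c(96, 96, 96))
    f <- make_tanh_field(cell_init_spec(g$box / 2, kind, ax), g, EPS,
                         margin = 0.5)
    expect_equal(surface_of(f, EPS), S, tolerance = 0.02)
    if (kind == "oblate") expect_lt(ax[3], ax[1]) else expect_gt(ax[3], ax[1])
  }
})

test_that("inertia-based classification labels analytic shapes", {
  g <- grid_spec(c(72, 72, 72))
  mk <- function(axes) make_tanh_field(
    cell_init_spec(g$box / 2, "ellipsoid", axes), g, EPS, margin = 0.4)
  expect_equal(suppressWarnings(classify_shape(mk(c(3, 3, 3)), EPS))$label, "sphere-like")
  expect_equal(classify_shape(mk(c(4, 4, 1)), EPS)$label, "oblate")
  expect_equal(classify_shape(mk(c(1.5, 1.5, 4.5)), EPS)$label, "prolate")
  # oblate with the flat axis along x classifies identically
  expect_equal(classify_shape(mk(c(1, 4, 4)), EPS)$label, "oblate")
})

test_that("cup-shaped field classifies as stomatocyte", {
  g <- grid_spec(c(64, 64, 64))
  cup <- make_cup_field(g$box / 2 - c(0, 0, 1), 3.2, g, EPS, margin = 0.4)
  cl <- classify_shape(cup, EPS)
  expect_equal(cl$label, "stomatocyte")
  expect_gt(cl$diagnostics$face_asymmetry, 0.3)
})

test_that("classification refuses fields with several components", {
  sp <- sphere_pair(n = 40, R = 1.0, surface_gap = 2.0)
  both <- pf_field(pmax(sp$f1$values, sp$f2$values), sp$grid)
  expect_error(classify_shape(both, EPS), "connected")
})

test_that("two-cell placement honours offset, gap and symmetry", {
  cell <- discocyte()
  p <- ref_params()
  g <- grid_spec(c(72L, 96L, 72L))
  proto <- collision_protocol(offset_d = 3.06, total_time = 2.4)
  st <- setup_two_cells(proto, p, g, cell, dt = 0.05 * nondimensionalize(p)$tau)
  g1 <- geometry_of(st$phi1, EPS); g2 <- geometry_of(st$phi2, EPS)
  # centre-to-centre y projection equals the offset exactly (lattice snap)
  expect_equal(abs(g2$centroid[2] - g1$centroid[2]), 3.06, tolerance = 1e-6)
  # initial interaction at the interface-tail level only: no overlap
  # (true interpenetration costs ~138 aJ/um^3), forces far below the
  # collision scale
  en <- free_energy(st$phi1, st$phi2, p)
  expect_lt(en$repulsion, 1)
  fr <- interaction_force(st$phi1, st$phi2, p)
  expect_lt(max(abs(c(fr$F1, fr$F2))), 20)
  # approach velocities
  expect_equal(st$velocities$v1, c(0, 0, 0.57))
  expect_equal(st$velocities$v2, c(0, 0, -0.57))
  # aligned placement is mirror-symmetric in x and y
  proto0 <- collision_protocol(offset_d = 0, total_time = 2.4)
  st0 <- setup_two_cells(proto0, p, grid_spec(c(72L, 72L, 72L)), cell)
  expect_equal(mirror_field(st0$phi1, 1)$values, st0$phi1$values,
               tolerance = 1e-12)
  expect_equal(mirror_field(st0$phi1, 2)$values, st0$phi1$values,
               tolerance = 1e-12)
  # facing surfaces exactly initial_gap apart along the aligned axis
  expect_equal(rbcphase:::min_gap_z(st0$phi1, st0$phi2),
               proto0$initial_gap, tolerance = 0.17)
})

test_that("protocol constructor validates its timing", {
  expect_error(collision_protocol(offset_d = -1), "offset_d")
  expect_error(collision_protocol(total_time = 1, reversal_time = 2),
               "total_time")
  expect_silent(collision_protocol(offset_d = 1.02))
})
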