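test_that("implicit spectral operators damp unconditionally", {
  g <- grid_spec(c(16, 16, 16))
  p <- ref_params()
  ops <- build_operators(g, p, dt = 1e-3)
  expect_equal(ops$denominator[1, 1, 1], 1) # k = 0: the mean is untouched
  expect_true(all(ops$denominator >= 1))
  # monotone in |k|^4 and linear in dt
  o <- order(ops$k2)
  expect_true(all(diff(ops$denominator[o]) >= -1e-12))
  ops2 <- build_operators(g, p, dt = 2e-3)
  expect_equal(ops2$denominator - 1, 2 * (ops$denominator - 1), tolerance = 1e-12)
  mask <- build_operators(g, p, 1e-3, dealias = TRUE)$dealias_mask
  expect_type(mask, "logical")
  expect_true(mask[1, 1, 1])
  expect_false(mask[9, 1, 1]) # Nyquist excluded by the 2/3 rule
})

test_that("homogeneous outside state is a fixed point of the stepper", {
  g <- grid_spec(c(24, 24, 24))
  p <- ref_params()
  u <- pf_field(array(-1, g$n), g)
  st <- solver_state(u, pf_field(array(-1, g$n), g, 2L), params = p)
  st <- rbcphase::step(st, p)
  expect_lt(max(abs(st$phi1$values + 1)), 1e-8)
  expect_lt(max(abs(st$phi2$values + 1)), 1e-8)
})

test_that("pure advection transports the cell at the imposed speed", {
  g <- grid_spec(c(32, 32, 32))
  # interaction and penalties off, bending negligible: method of
  # characteristics says the profile translates rigidly
  p <- pf_params(kappa_B = 1e-3, gamma = 0, eta = 0, alpha_S = 0, alpha_V = 0)
  f <- make_tanh_field(cell_init_spec(g$box / 2, "sphere", 1.2), g, EPS,
                       margin = 0.4)
  v <- c(0, 0, 1.4) # um/s
  st <- solver_state(f, pf_field(array(-1, g$n), g, 2L), dt = 2e-3,
                     velocities = list(v1 = v, v2 = c(0, 0, 0)))
  c0 <- suppressWarnings(geometry_of(st$phi1, EPS)$centroid)
  Tend <- 0.5
  st <- run_until(st, p, t_end = Tend, obs_dt = 0.25, drift_warn = Inf)
  c1 <- suppressWarnings(geometry_of(st$phi1, EPS)$centroid)
  expect_equal(c1 - c0, v * Tend, tolerance = 0.01)
})

test_that("free energy is non-increasing under the relaxation dynamics", {
  g <- grid_spec(c(32, 32, 32))
  p <- ref_params()
  f <- make_tanh_field(cell_init_spec(g$box / 2, "sphere", 1.6), g, EPS,
                       margin = 0.4)
  # perturb the shape, keep targets at the perturbed cell's own S/V scale
  ax <- grid_axes(g)
  X <- array(rep(ax[[1]], times = g$n[2] * g$n[3]), g$n)
  f$values <- f$values + 0.05 * (1 - f$values^2) * sin(2 * pi * X / g$box[1])
  p <- update_params(p, gamma = 0, eta = 0, v = 0,
                     S_target = surface_of(f, EPS),
                     V_target = volume_of(f))
  far <- pf_field(f$values, g, 2L)
  st <- solver_state(f, far, params = p)
  e_prev <- free_energy(st$phi1, st$phi2, p)$total
  worst <- -Inf
  for (i in 1:100) {
    st <- rbcphase::step(st, p)
    e <- free_energy(st$phi1, st$phi2, p)$total
    worst <- max(worst, (e - e_prev) / abs(e_prev))
    e_prev <- e
  }
  expect_lt(worst, 1e-6)
})

test_that("stepping is translation-equivariant on the periodic grid", {
  g <- grid_spec(c(24, 24, 24))
  p <- ref_params()
  sp <- sphere_pair(n = 28, R = 1.2, surface_gap = -0.75)
  pq <- update_params(p, S_target = surface_of(sp$f1, EPS),
                      V_target = volume_of(sp$f1))
  sft <- c(3L, -2L, 5L)
  st_a <- solver_state(sp$f1, sp$f2, params = pq)
  st_b <- solver_state(shift_field(sp$f1, sft), shift_field(sp$f2, sft),
                       params = pq)
  for (i in 1:10) {
    st_a <- rbcphase::step(st_a, pq)
    st_b <- rbcphase::step(st_b, pq)
  }
  expect_equal(st_b$phi1$values, shift_field(st_a$phi1, sft)$values,
               tolerance = 1e-10)
})

test_that("velocity schedules switch at step boundaries and bookkeeping is exact", {
  g <- grid_spec(c(16, 16, 16))
  p <- ref_params()
  u <- pf_field(array(-1, g$n), g)
  st <- solver_state(u, pf_field(array(-1, g$n), g, 2L), dt = 0.01)
  sch <- schedule_approach_retract(v = 0.57, reversal_time = 0.055)
  seen <- list()
  obs <- function(s) seen[[length(seen) + 1]] <<- list(t = s$t, v = s$velocities)
  st <- run_until(st, p, t_end = 0.1, schedule = sch, observer = obs,
                  obs_dt = 0.02, drift_warn = Inf)
  expect_equal(st$step_count, 10L)
  expect_equal(st$t, 0.1)
  # before reversal the cells approach (v1z > 0), after it they retract
  expect_equal(seen[[1]]$v$v1[3], 0.57)
  expect_equal(seen[[length(seen)]]$v$v1[3], -0.57)
  # the schedule itself switches at its stated time; run_until snaps the
  # change to the first step boundary at or beyond it (t = 0.06 here)
  expect_equal(sch(0.0549)$v1[3], 0.57)
  expect_equal(sch(0.055)$v1[3], -0.57)
})

test_that("NaN blow-up is reported as an error with diagnostics", {
  g <- grid_spec(c(16, 16, 16))
  p <- ref_params()
  set.seed(1)
  bad <- pf_field(array(rnorm(prod(g$n), sd = 100), g$n), g)
  st <- solver_state(bad, pf_field(array(-1, g$n), g, 2L), dt = 1000)
  expect_error(for (i in 1:8) st <- rbcphase::step(st, p), "non-finite")
})
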