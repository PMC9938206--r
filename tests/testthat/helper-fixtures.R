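# Shared fixtures for the test suite. Expensive objects (relaxed cells,
# collision trajectories) are built once per session and memoised here so
# several test files can interrogate the same physics run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ref_params <- function(...) pf_params(...)

# interface width shared by all fixtures
EPS <- 0.17

# a pair of tanh spheres on a small grid; surface_gap is the z-clearance
# between the two surfaces (negative = interpenetrating, which activates
# the interaction terms for the oracle tests)
sphere_pair <- function(n = 28, R = 1.2, surface_gap = -0.75) {
  g <- grid_spec(c(n, n, n))
  off <- c(0, 0, R + surface_gap / 2)
  f1 <- make_tanh_field(cell_init_spec(g$box / 2 - off, "sphere", R), g, EPS,
                        margin = 0.2)
  f2 <- make_tanh_field(cell_init_spec(g$box / 2 + off, "sphere", R), g, EPS,
                        margin = 0.2, cell_id = 2L)
  list(grid = g, f1 = f1, f2 = f2)
}

# two adjacent slabs sharing one flat anti-parallel interface; the far
# interfaces are separated by many interface widths so only the shared one
# contributes to the interaction
slab_pair <- function(n = c(16, 16, 64)) {
  g <- grid_spec(n)
  ax <- grid_axes(g)
  z <- array(rep(ax[[3]], each = n[1] * n[2]), dim = g$n)
  a <- sqrt(2) * EPS
  zmid <- g$box[3] / 2
  z1lo <- zmid - 2.6
  z2hi <- zmid + 2.6
  sd1 <- pmin(z - z1lo, zmid - z)  # slab [z1lo, zmid]
  sd2 <- pmin(z - zmid, z2hi - z)  # slab [zmid, z2hi]
  list(grid = g,
       f1 = pf_field(tanh(sd1 / a), g, 1L),
       f2 = pf_field(tanh(sd2 / a), g, 2L),
       cross_section = g$box[1] * g$box[2])
}

# --- expensive shared fixtures -------------------------------------------

# grid used to relax single cells (cell diameter ~9.9 um)
equil_grid <- function() grid_spec(c(72L, 72L, 40L))

# reference relaxed discocyte (Table-defaults cell), built once
discocyte <- function() {
  cached("discocyte", {
    p <- ref_params()
    tau <- nondimensionalize(p)$tau
    ax <- ellipsoid_axes_for(p$internal$S_target, p$internal$V_target, "oblate")
    g <- equil_grid()
    seed <- make_tanh_field(cell_init_spec(g$box / 2, "oblate", ax), g, EPS,
                            margin = 0.4)
    equilibrate_cell(seed, p, tol = 3e-4, dt = 0.05 * tau, max_steps = 20000)
  })
}

# scaled-down aligned collision at the weak adhesion setting, shared by the
# force/contact/energy acceptance checks
aligned_run <- function() {
  cached("aligned_run", {
    p <- ref_params()
    tau <- nondimensionalize(p)$tau
    proto <- collision_protocol(offset_d = 0, total_time = 2.4)
    run_collision(proto, p, grid_spec(c(72L, 72L, 64L)),
                  cell_field = discocyte(), dt = 0.05 * tau, obs_dt = 0.05)
  })
}

# offset collisions (y-offset sweep); shortened to just past the adhesion
# peak, with a sparser observation cadence
offset_run <- function(d, eta = 8.0e-12, total_time = 2.4) {
  cached(sprintf("offset_run_%04.0f_%g_%g", d * 100, eta, total_time), {
    p <- ref_params()
    tau <- nondimensionalize(p)$tau
    proto <- collision_protocol(offset_d = d, total_time = total_time,
                                eta = eta)
    run_collision(proto, p, grid_spec(c(72L, 96L, 64L)),
                  cell_field = discocyte(), dt = 0.05 * tau, obs_dt = 0.05,
                  keep_geometry = FALSE)
  })
}

# single cells across the reduced-volume shape diagram; V set from nu at
# the reference area
cell_at_nu <- function(nu, kind) {
  cached(sprintf("cell_nu_%03.0f", nu * 100), {
    p0 <- ref_params()
    S <- p0$internal$S_target
    V <- nu * (4 / 3) * pi * (S / (4 * pi))^1.5
    p <- update_params(p0, V_target = V)
    tau <- nondimensionalize(p)$tau
    if (kind == "cup") {
      g <- grid_spec(c(72L, 72L, 72L))
      R <- sqrt(S / (4 * pi))
      seed <- make_cup_field(g$box / 2 - c(0, 0, 1.2), R, g, EPS, margin = 0.4)
    } else {
      g <- if (kind == "prolate") grid_spec(c(48L, 48L, 80L)) else equil_grid()
      ax <- ellipsoid_axes_for(S, V, kind)
      seed <- make_tanh_field(cell_init_spec(g$box / 2, kind, ax), g, EPS,
                              margin = 0.4)
    }
    equilibrate_cell(seed, p, tol = 3e-4, dt = 0.05 * tau)
  })
}
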