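#' Ellipsoid semi-axes matching a target area and volume
#'
#' Solves for the axisymmetric ellipsoid (oblate c < a = b, or prolate
#' c > a = b) with the requested surface area and volume; used to seed
#' relaxation runs close to the target constraints so the penalty terms only
#' have to hold, not build, the cell.
#'
#' @param S target area, um^2.
#' @param V target volume, um^3.
#' @param kind \code{"oblate"} or \code{"prolate"}.
#' @return Semi-axes c(a, b, c) in um (axis of symmetry along z).
#' @export
ellipsoid_axes_for <- function(S, V, kind = c("oblate", "prolate")) {
  kind <- match.arg(kind)
  nu <- reduced_volume(S, V)
  if (nu > 0.999) return(rep((3 * V / (4 * pi))^(1 / 3), 3))
  area <- function(r) { # r = c/a (oblate) or a/c (prolate), in (0,1)
    if (kind == "oblate") {
      a <- (3 * V / (4 * pi * r))^(1 / 3)
      e <- sqrt(1 - r^2)
      2 * pi * a^2 * (1 + (1 - e^2) / e * atanh(e))
    } else {
      c_ <- (3 * V / (4 * pi * r^2))^(1 / 3)
      a <- r * c_
      e <- sqrt(1 - r^2)
      2 * pi * a^2 * (1 + (1 / (r * e)) * asin(e))
    }
  }
  f <- function(r) area(r) - S
  sol <- uniroot(f, c(0.02, 0.999), tol = 1e-10)
  r <- sol$root
  if (kind == "oblate") {
    a <- (3 * V / (4 * pi * r))^(1 / 3)
    c(a, a, r * a)
  } else {
    c_ <- (3 * V / (4 * pi * r^2))^(1 / 3)
    c(r * c_, r * c_, c_)
  }
}

#' Cup-shaped (stomatocyte-biased) seed field
#'
#' A sphere with a spherical invagination on its +z face. Used to bias
#' relaxation toward the stomatocyte branch at low reduced volume, where the
#' oblate and stomatocyte branches can both be locally stable.
#'
#' @param center cup centre, um.
#' @param R outer radius, um.
#' @param grid a \code{\link{grid_spec}}.
#' @param epsilon interface width, um.
#' @param bite_frac centre offset of the invaginating sphere as a fraction of
#'   R along +z.
#' @param bite_radius radius of the invaginating sphere as a fraction of R.
#'   The defaults give a deep cup whose area and volume sit close to the
#'   reference-area stomatocyte targets (nu ~ 0.45), so the constraint
#'   terms only have to trim, not rebuild, the shape.
#' @param margin clearance to box faces, um.
#' @return A \code{\link{pf_field}}.
#' @export
make_cup_field <- function(center, R, grid, epsilon, bite_frac = 0.6,
                           bite_radius = 0.95, margin = 0.5) {
  outer_f <- make_tanh_field(cell_init_spec(center, "sphere", R), grid,
                             epsilon, margin = margin)
  bite_c <- center + c(0, 0, bite_frac * R)
  bite <- make_tanh_field(cell_init_spec(bite_c, "sphere", bite_radius * R),
                          grid, epsilon, margin = 0)
  pf_field(pmin(outer_f$values, -bite$values), grid)
}

#' Relax an isolated cell to its equilibrium shape
#'
#' Integrates the single-cell dynamics (advection and cell-cell interaction
#' switched off) until the relative free-energy change per timescale tau
#' falls below \code{tol}. With the reference parameterisation
#' (nu = 0.614) the relaxed shape is the characteristic biconcave discocyte.
#'
#' @param seed a \code{\link{pf_field}} (e.g. from
#'   \code{\link{make_tanh_field}} with \code{\link{ellipsoid_axes_for}}
#'   axes) or a \code{\link{cell_init_spec}}.
#' @param params a \code{\link{pf_params}} (its S_target/V_target are the
#'   constraints; alpha_S, alpha_V must be > 0).
#' @param grid grid to relax on (required when \code{seed} is a spec).
#' @param tol relative energy change per tau below which the shape is
#'   declared converged. Default 1e-7.
#' @param dt time step, s (default 0.01 tau).
#' @param max_steps step budget; exceeding it raises an error carrying the
#'   energy trace.
#' @return The relaxed \code{\link{pf_field}}, with attributes
#'   \code{energy_trace} (data.frame of t and total single-cell energy) and
#'   \code{converged}.
#' @export
equilibrate_cell <- function(seed, params, grid = NULL, tol = 1e-7,
                             dt = NULL, max_steps = 40000L) {
  stopifnot(inherits(params, "pf_params"))
  p <- params$internal
  if (p$alpha_S <= 0 || p$alpha_V <= 0)
    stop("equilibration requires positive alpha_S and alpha_V")
  if (inherits(seed, "pf_cellspec")) {
    if (is.null(grid)) stop("grid required when seeding from a spec")
    seed <- make_tanh_field(seed, grid, p$epsilon, margin = 0.5)
  }
  stopifnot(inherits(seed, "pf_field"))
  grid <- seed$grid
  tau <- nondimensionalize(params)$tau
  if (is.null(dt)) dt <- 0.01 * tau
  relax_params <- update_params(params, gamma = 0, eta = 0, v = 0)
  # the partner slot carries an identical, non-interacting copy: both fields
  # then relax under the same well-posed constrained dynamics
  phi2 <- pf_field(seed$values, grid, cell_id = 2L)
  state <- solver_state(seed, phi2, dt = dt)
  chunk <- max(1L, as.integer(round(tau / dt)))
  e_prev <- single_cell_energy(state$phi1, params)
  trace_t <- state$t
  trace_e <- e_prev
  converged <- FALSE
  while (state$step_count < max_steps) {
    state <- advance(state, relax_params, chunk)
    e_now <- single_cell_energy(state$phi1, params)
    trace_t <- c(trace_t, state$t)
    trace_e <- c(trace_e, e_now)
    if (abs(e_now - e_prev) < tol * abs(e_now)) {
      converged <- TRUE
      break
    }
    e_prev <- e_now
  }
  trace <- data.frame(t = trace_t, energy = trace_e)
  if (!converged) {
    cond <- simpleError(sprintf(
      "cell failed to equilibrate within %d steps (last relative energy change %.3g)",
      max_steps, abs(e_now - e_prev) / abs(e_now)))
    cond$energy_trace <- trace
    stop(cond)
  }
  out <- state$phi1
  check_field_band(out$values, context = "equilibrated cell")
  attr(out, "energy_trace") <- trace
  attr(out, "converged") <- TRUE
  out
}

# bending + own penalty terms of one isolated cell (interaction-free), aJ
single_cell_energy <- function(field, params) {
  p <- params$internal
  g <- field$grid
  a <- field$values
  mu <- -a + a^3 - p$epsilon^2 * spectral_laplacian(a, g)
  bending <- p$kappa_B * sum(mu^2) * g$dV
  S <- surface_of(field, p$epsilon)
  V <- volume_of(field)
  bending + p$alpha_S * (p$S_target - S)^2 + p$alpha_V * (p$V_target - V)^2
}

#' Classify the morphology of a relaxed cell
#'
#' Classification uses the eigenvalues (lambda1 <= lambda2 <= lambda3) of the
#' second-moment (inertia) tensor of h(phi): prolate when the largest
#' eigenvalue dominates (lambda3/lambda2 > 1.5 and lambda2/lambda1 < 1.2),
#' oblate when the smallest is isolated (lambda2/lambda1 > 1.5 and
#' lambda3/lambda2 < 1.2), sphere-like when all ratios are below 1.1.
#' Oblate-like shapes are split by a face-asymmetry score: the dimple depths
#' d+ and d- on the two faces along the symmetry axis give
#' score = |d+ - d-| / max(d+, d-); a score above 0.3 marks the one-sided
#' invagination of a stomatocyte, below it the symmetric biconcave discocyte
#' counts as oblate.
#'
#' @param field a \code{\link{pf_field}} containing one connected cell
#'   (multiple connected components are an error).
#' @param epsilon interface width, um.
#' @return Object of class \code{pf_shape}: list with \code{label} (one of
#'   stomatocyte, oblate, prolate, sphere-like, unclassified) and
#'   \code{diagnostics} (eigenvalues, ratios, face-asymmetry score, dimple
#'   depths).
#' @export
classify_shape <- function(field, epsilon) {
  stopifnot(inherits(field, "pf_field"))
  if (!single_component(field$values > 0))
    stop("field contains multiple connected components")
  geo <- geometry_of(field, epsilon)
  ei <- eigen(geo$inertia, symmetric = TRUE)
  ord <- order(ei$values)
  ev <- ei$values[ord]
  r32 <- ev[3] / ev[2]
  r21 <- ev[2] / ev[1]
  asym <- NA_real_
  dplus <- NA_real_
  dminus <- NA_real_
  label <- "unclassified"
  if (ev[3] / ev[1] < 1.1) {
    label <- "sphere-like"
  } else if (r32 > 1.5 && r21 < 1.2) {
    label <- "prolate"
  } else if (r21 > 1.5 && r32 < 1.2) {
    # symmetry axis = eigenvector of the smallest eigenvalue
    axis_vec <- ei$vectors[, ord[1]]
    axis <- which.max(abs(axis_vec))
    dd <- dimple_depths(field, axis, geo$centroid)
    dplus <- dd[1]; dminus <- dd[2]
    asym <- abs(dplus - dminus) / max(dplus, dminus, field$grid$dx)
    label <- if (is.finite(asym) && asym > 0.3) "stomatocyte" else "oblate"
  }
  structure(list(label = label,
                 diagnostics = list(eigenvalues = ev, ratio_32 = r32,
                                    ratio_21 = r21, face_asymmetry = asym,
                                    dimple_depths = c(dplus, dminus))),
            class = "pf_shape")
}

#' @export
print.pf_shape <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("shape: %s (eigenvalue ratios %.2f / %.2f, face asymmetry %s)\n",
              x$label, d$ratio_32, d$ratio_21,
              ifelse(is.na(d$face_asymmetry), "-", sprintf("%.2f", d$face_asymmetry))))
  invisible(x)
}

# depth of the concavity on each face along `axis`: distance between the
# extreme surface height over the footprint and the height at the centroid
# column. Returns c(d_plus, d_minus) in um.
dimple_depths <- function(field, axis, centroid) {
  g <- field$grid
  n <- g$n
  perm <- c(setdiff(1:3, axis), axis)
  v <- aperm(field$values, perm) # cols along chosen axis last
  dim(v) <- c(prod(n[perm[1:2]]), n[axis])
  inside <- v > 0
  any_in <- rowSums(inside) > 0
  zidx <- seq_len(n[axis])
  top <- apply(inside[any_in, , drop = FALSE], 1, function(r) max(zidx[r]))
  bot <- apply(inside[any_in, , drop = FALSE], 1, function(r) min(zidx[r]))
  # centroid column in the permuted (row) indexing
  ci <- pmin(pmax(round(centroid / g$dx) + 1, 1), n)
  rowpos <- (ci[perm[1]] - 1) + n[perm[1]] * (ci[perm[2]] - 1) + 1
  rows <- which(any_in)
  at_c <- match(rowpos, rows)
  if (is.na(at_c)) return(c(NA_real_, NA_real_))
  d_plus <- (max(top) - top[at_c]) * g$dx
  d_minus <- (bot[at_c] - min(bot)) * g$dx
  c(d_plus, d_minus)
}

# TRUE if the TRUE voxels of `mask` form one 6-connected component
# (periodic). Grown by repeated neighbour dilation from one seed voxel.
single_component <- function(mask) {
  total <- sum(mask)
  if (total == 0) return(TRUE)
  seed <- array(FALSE, dim = dim(mask))
  seed[which.max(mask)] <- TRUE
  grown <- seed
  repeat {
    nb <- shift_l(grown, 1, 1) | shift_l(grown, -1, 1) |
      shift_l(grown, 1, 2) | shift_l(grown, -1, 2) |
      shift_l(grown, 1, 3) | shift_l(grown, -1, 3)
    nxt <- (grown | nb) & mask
    if (sum(nxt) == sum(grown)) break
    grown <- nxt
  }
  sum(grown) == total
}

shift_l <- function(a, by, axis) {
  n <- dim(a)
  idx <- lapply(1:3, function(d) {
    if (d == axis) ((seq_len(n[d]) - 1 - by) %% n[d]) + 1L else seq_len(n[d])
  })
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Collision protocol description
#'
#' Encodes one approach-retraction experiment: the cells sit with their
#' symmetry axes along z, offset by \code{offset_d} along y, approach at
#' \code{speed_v} each (relative speed 2 speed_v) until
#' \code{reversal_time}, then retract at the same speed until
#' \code{total_time}.
#'
#' @param offset_d y-offset of the cell centres, um (reference values 0,
#'   1.02, 2.04, 3.06, 4.08).
#' @param speed_v per-cell speed, um/s (default 0.57).
#' @param reversal_time s (default 1.18).
#' @param total_time s (> reversal_time).
#' @param eta protocol-level adhesion coefficient override, display units
#'   J/m (default keeps the parameter set's value).
#' @param initial_gap initial z-clearance between the facing surfaces, um.
#'   The default, 4 epsilon = 0.68, lets adhesive contact begin about a
#'   quarter second into the approach so that the reference reversal time
#'   (1.18 s at relative speed 1.14 um/s) produces roughly 0.7 um of mutual
#'   compression -- the regime in which the force curve shows its
#'   attraction dip, repulsion maximum and post-reversal adhesion peak. A
#'   wider gap delays or suppresses contact entirely at the same reversal
#'   time.
#' @return Object of class \code{pf_protocol}.
#' @export
collision_protocol <- function(offset_d = 0, speed_v = 0.57,
                               reversal_time = 1.18, total_time = 2.5,
                               eta = NULL, initial_gap = 0.68) {
  if (offset_d < 0) stop("offset_d must be >= 0")
  if (!(total_time > reversal_time && reversal_time > 0))
    stop("need total_time > reversal_time > 0")
  if (initial_gap <= 0) stop("initial_gap must be > 0")
  structure(list(offset_d = offset_d, speed_v = speed_v,
                 reversal_time = reversal_time, total_time = total_time,
                 eta = eta, initial_gap = initial_gap, approach_axis = "z"),
            class = "pf_protocol")
}

#' Place two relaxed cells for a collision run
#'
#' Embeds two copies of a relaxed cell into the protocol box: symmetry axes
#' along z, centre-to-centre y-projection equal to the protocol offset
#' (snapped to the lattice), and facing surfaces \code{initial_gap} apart
#' along z so that the interaction terms start out negligible. Cell 1 sits at
#' lower z and moves up; cell 2 ("right-hand" cell of the force convention)
#' sits at higher z and moves down.
#'
#' @param protocol a \code{\link{collision_protocol}}.
#' @param params a \code{\link{pf_params}}.
#' @param grid protocol box \code{\link{grid_spec}}.
#' @param cell_field relaxed single cell (any grid not larger than
#'   \code{grid} with the same spacing).
#' @param dt solver step, s (default 0.01 tau).
#' @return A \code{\link{solver_state}} with approach velocities assigned.
#' @export
setup_two_cells <- function(protocol, params, grid, cell_field, dt = NULL) {
  stopifnot(inherits(protocol, "pf_protocol"), inherits(cell_field, "pf_field"))
  p <- params$internal
  vals <- cell_field$values
  ns <- cell_field$grid$n
  nt <- grid$n
  inz <- which(apply(vals > 0, 3, any))
  if (!length(inz)) stop("cell field contains no interior region")
  # placement in whole voxels so offsets and gaps land exactly on the
  # lattice: gapvox empty layers separate cell 1's top inside voxel from
  # cell 2's bottom inside voxel, centred on the box mid-plane
  gapvox <- max(1L, as.integer(round(protocol$initial_gap / grid$dx)))
  dvox <- as.integer(round(protocol$offset_d / grid$dx))
  mid <- nt[3] / 2
  top1 <- as.integer(round(mid - gapvox / 2))
  bot2 <- top1 + gapvox
  s1 <- c(as.integer(round((nt[1] - ns[1]) / 2)),
          as.integer(round((nt[2] - ns[2]) / 2 - dvox / 2)),
          top1 - max(inz))
  s2 <- c(s1[1], s1[2] + dvox, bot2 - min(inz))
  place <- function(start, id) {
    at <- (start + ns / 2) * grid$dx
    embed_field(cell_field, grid, at = at, cell_id = id)
  }
  phi1 <- place(s1, 1L)
  phi2 <- place(s2, 2L)
  # overlap check: repulsion energy and interaction force are clean
  # indicators (the adhesion integral carries a small far-field baseline
  # from bulk-phase ripples of relaxed cells, irrespective of separation)
  # true interpenetration costs ~gamma (138 aJ) per um^3 of overlap;
  # interface-tail contact at the default gap stays in the single-aJ range
  en <- free_energy(phi1, phi2, params)
  if (en$repulsion > 5)
    stop(sprintf("cells overlap at placement (repulsion %.3g aJ): increase the box or the gap",
                 en$repulsion))
  v <- protocol$speed_v
  solver_state(phi1, phi2, params = params, dt = dt,
               velocities = list(v1 = c(0, 0, v), v2 = c(0, 0, -v)))
}

#' Run one collision experiment
#'
#' Executes the full approach-retraction protocol and records force,
#' contact, geometry and energy observables at a fixed cadence, plus optional
#' field snapshots.
#'
#' @param protocol a \code{\link{collision_protocol}}.
#' @param params a \code{\link{pf_params}} (the protocol's \code{eta}
#'   override, if any, is applied on top).
#' @param grid protocol box.
#' @param cell_field optional pre-relaxed cell; when NULL a cell is relaxed
#'   inline on \code{equil_grid} from the matched oblate seed.
#' @param dt solver step, s (default 0.01 tau).
#' @param obs_dt observation cadence, s (default 0.05).
#' @param snapshot_times times (s) at which to store field snapshots;
#'   default none. Values are snapped to observation times.
#' @param equil_grid grid for inline relaxation (default: the protocol
#'   grid).
#' @param keep_geometry record per-cell geometry at each observation
#'   (moderate extra cost).
#' @param quiet suppress progress output.
#' @return A \code{pf_trajectory}: list with \code{protocol}, \code{params},
#'   \code{force}, \code{contact}, \code{energy}, \code{geometry} data
#'   frames, \code{snapshots}, and the final \code{state}.
#' @export
run_collision <- function(protocol, params, grid, cell_field = NULL,
                          dt = NULL, obs_dt = 0.05,
                          snapshot_times = numeric(0), equil_grid = NULL,
                          keep_geometry = TRUE, quiet = TRUE) {
  stopifnot(inherits(protocol, "pf_protocol"), inherits(params, "pf_params"))
  if (!is.null(protocol$eta)) params <- update_params(params, eta = protocol$eta)
  if (is.null(cell_field)) {
    if (is.null(equil_grid)) equil_grid <- grid
    axes <- ellipsoid_axes_for(params$internal$S_target,
                               params$internal$V_target, "oblate")
    seed <- make_tanh_field(
      cell_init_spec(equil_grid$box / 2, "oblate", axes),
      equil_grid, params$internal$epsilon, margin = 0.5)
    cell_field <- equilibrate_cell(seed, params, dt = dt)
  }
  state <- setup_two_cells(protocol, params, grid, cell_field, dt = dt)
  schedule <- schedule_approach_retract(protocol$speed_v,
                                        protocol$reversal_time)
  rec <- new.env(parent = emptyenv())
  rec$force <- list(); rec$contact <- list(); rec$energy <- list()
  rec$geometry <- list(); rec$snapshots <- list()
  snap_left <- sort(snapshot_times)
  p <- params$internal
  observe <- function(s) {
    fr <- interaction_force(s$phi1, s$phi2, params)
    en <- free_energy(s$phi1, s$phi2, params)
    ca <- contact_area(s$phi1, s$phi2, p$epsilon)
    mg <- min_gap_z(s$phi1, s$phi2)
    vec3 <- function(prefix, v) stats::setNames(v, paste0(prefix, c("x", "y", "z")))
    rec$force[[length(rec$force) + 1L]] <-
      c(t = s$t, vec3("F1", fr$F1), vec3("F2", fr$F2),
        vec3("F1_rep_", fr$F1_rep), vec3("F1_adh_", fr$F1_adh),
        vec3("F2_rep_", fr$F2_rep), vec3("F2_adh_", fr$F2_adh))
    rec$contact[[length(rec$contact) + 1L]] <-
      c(t = s$t, contact_area = ca, adhesion_energy = en$adhesion,
        min_gap = mg)
    rec$energy[[length(rec$energy) + 1L]] <-
      c(t = s$t, bending = en$bending, repulsion = en$repulsion,
        adhesion = en$adhesion, surface_penalty = en$surface_penalty,
        volume_penalty = en$volume_penalty, total = en$total)
    if (keep_geometry) {
      for (ci in 1:2) {
        f <- if (ci == 1) s$phi1 else s$phi2
        geo <- geometry_of(f, p$epsilon)
        rec$geometry[[length(rec$geometry) + 1L]] <-
          c(t = s$t, cell = ci, S = geo$S, V = geo$V, nu = geo$nu,
            cx = geo$centroid[1], cy = geo$centroid[2], cz = geo$centroid[3])
      }
    }
    if (length(snap_left) && s$t >= snap_left[1] - obs_dt / 2) {
      rec$snapshots[[length(rec$snapshots) + 1L]] <-
        list(t = s$t, phi1 = s$phi1$values, phi2 = s$phi2$values)
      snap_left <<- snap_left[-1]
    }
    if (!quiet)
      message(sprintf("t = %.3f s  Fz(right) = %.1f pN  contact = %.1f um^2",
                      s$t, fr$F2[3], ca))
  }
  if (0 %in% snapshot_times || any(snapshot_times < obs_dt / 2)) observe(state)
  state <- run_until(state, params, t_end = protocol$total_time,
                     schedule = schedule, observer = observe, obs_dt = obs_dt)
  as_df <- function(lst) as.data.frame(do.call(rbind, lst))
  structure(list(protocol = protocol, params = params, grid = grid,
                 force = as_df(rec$force), contact = as_df(rec$contact),
                 energy = as_df(rec$energy),
                 geometry = if (keep_geometry) as_df(rec$geometry) else NULL,
                 snapshots = rec$snapshots, state = state),
            class = "pf_trajectory")
}

#' @export
print.pf_trajectory <- function(x, ...) {
  cat(sprintf("collision trajectory: offset %.2f um, eta %.3g J/m, %d observations to t = %.2f s\n",
              x$protocol$offset_d,
              if (!is.null(x$protocol$eta)) x$protocol$eta else x$params$display$eta,
              nrow(x$force), max(x$force$t)))
  pk <- peak_forces(x)
  cat(sprintf("  peak repulsive Fz %.1f pN, peak attractive |Fz| %.1f pN (post-reversal %.1f pN)\n",
              pk$repulsion_peak, pk$attraction_peak, pk$post_reversal_attraction_peak))
  invisible(x)
}
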