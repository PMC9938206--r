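#' Solver state for the coupled two-cell dynamics
#'
#' @param phi1,phi2 \code{\link{pf_field}}s on one grid.
#' @param dt time step, s. The default, 0.01 tau with
#'   tau = 1/(M kappa_B), resolves the advection comfortably (about 0.1
#'   lattice units per tau at the reference speed) and keeps the explicit
#'   terms well inside their stability region; coarser steps up to about
#'   0.05 tau remain stable and are used for reduced-cost runs.
#' @param t elapsed time, s.
#' @param velocities list with 3-vectors \code{v1}, \code{v2} (um/s).
#' @param params a \code{\link{pf_params}} (used only for the default dt).
#' @return Object of class \code{pf_state}.
#' @export
solver_state <- function(phi1, phi2, params = NULL, dt = NULL, t = 0,
                         velocities = list(v1 = c(0, 0, 0), v2 = c(0, 0, 0))) {
  stopifnot(inherits(phi1, "pf_field"), inherits(phi2, "pf_field"))
  if (!identical(phi1$grid$n, phi2$grid$n))
    stop("fields must share one grid")
  if (is.null(dt)) {
    if (is.null(params)) stop("give dt or params (for the default 0.01 tau)")
    dt <- 0.01 * nondimensionalize(params)$tau
  }
  if (dt <= 0) stop("dt must be > 0")
  structure(list(phi1 = phi1, phi2 = phi2, t = t, dt = dt,
                 step_count = 0L, velocities = velocities),
            class = "pf_state")
}

#' @export
print.pf_state <- function(x, ...) {
  cat(sprintf("solver state: t = %.4g s (%d steps of dt = %.3g s), |v1| = %.3g, |v2| = %.3g um/s\n",
              x$t, x$step_count, x$dt,
              sqrt(sum(x$velocities$v1^2)), sqrt(sum(x$velocities$v2^2))))
  invisible(x)
}

# advance nsteps with the C++ spectral core; errors on NaN/Inf
advance <- function(state, params, nsteps, dealias = FALSE) {
  if (nsteps <= 0) return(state)
  g <- state$phi1$grid
  res <- cpp_run_segment(state$phi1$values, state$phi2$values,
                         as.integer(g$n), g$dx, params$internal,
                         as.numeric(state$velocities$v1),
                         as.numeric(state$velocities$v2),
                         as.integer(nsteps), state$dt, isTRUE(dealias))
  if (!res$finite)
    stop(sprintf("non-finite field after step %d of segment (t = %.4g s, max|phi| = %g)",
                 res$steps_done, state$t + res$steps_done * state$dt, res$max_abs))
  state$phi1$values <- res$phi1
  state$phi2$values <- res$phi2
  state$t <- state$t + nsteps * state$dt
  state$step_count <- state$step_count + as.integer(nsteps)
  attr(state, "diagnostics") <- list(S = res$S, V = res$V,
                                     max_abs = res$max_abs)
  state
}

#' Advance the dynamics by one time step
#'
#' One semi-implicit spectral update: the nonlinear, penalty and advection
#' terms are evaluated at the current step (nonlinear products in real
#' space), transformed, and each mode is divided by the implicit denominator
#' of \code{\link{build_operators}}.
#'
#' @param state a \code{\link{solver_state}}.
#' @param params a \code{\link{pf_params}}.
#' @param dealias apply the optional 2/3-rule mask to the explicit terms.
#' @return Updated \code{pf_state} (time advanced by dt).
#' @export
step <- function(state, params, dealias = FALSE) {
  stopifnot(inherits(state, "pf_state"), inherits(params, "pf_params"))
  advance(state, params, 1L, dealias = dealias)
}

#' Piecewise-constant velocity schedule
#'
#' @param times segment start times, s (first must be 0), sorted.
#' @param v1,v2 lists (one 3-vector per segment) of per-cell velocities.
#' @return Function mapping t to \code{list(v1=, v2=)}, with attributes used
#'   by \code{\link{run_until}} to snap switch times to step boundaries.
#' @export
velocity_schedule <- function(times, v1, v2) {
  stopifnot(length(times) == length(v1), length(times) == length(v2),
            times[1] == 0, !is.unsorted(times))
  f <- function(t) {
    i <- findInterval(t, times)
    list(v1 = as.numeric(v1[[i]]), v2 = as.numeric(v2[[i]]))
  }
  attr(f, "switch_times") <- times
  f
}

#' Approach-then-retract schedule along z
#'
#' Cells 1 (lower z) and 2 (upper z) move towards each other at speed
#' \code{v} each (relative speed 2v) until \code{reversal_time}, then the
#' motion reverses.
#'
#' @param v per-cell speed, um/s.
#' @param reversal_time reversal time, s.
#' @return A \code{\link{velocity_schedule}}.
#' @export
schedule_approach_retract <- function(v, reversal_time) {
  velocity_schedule(c(0, reversal_time),
                    v1 = list(c(0, 0, v), c(0, 0, -v)),
                    v2 = list(c(0, 0, -v), c(0, 0, v)))
}

#' Run the dynamics to a target time
#'
#' Steps the solver until \code{t_end}, applying a piecewise-constant
#' velocity schedule (switches take effect at the first step boundary at or
#' after the switch time) and invoking an observer callback at a fixed
#' cadence. Warns when a cell's area or volume drifts more than
#' \code{drift_warn} relative from target at any observation.
#'
#' @param state a \code{\link{solver_state}}.
#' @param params a \code{\link{pf_params}}.
#' @param t_end target time, s (> state$t).
#' @param schedule a \code{\link{velocity_schedule}}, or NULL to keep the
#'   state's current velocities.
#' @param observer optional \code{function(state)} called at each
#'   observation time (including t_end).
#' @param obs_dt observation cadence, s (snapped to whole steps; default 25
#'   steps).
#' @param drift_warn relative S/V drift that triggers a warning (default 2\%).
#' @param dealias apply the 2/3-rule mask.
#' @return Final \code{pf_state}.
#' @export
run_until <- function(state, params, t_end, schedule = NULL, observer = NULL,
                      obs_dt = NULL, drift_warn = 0.02, dealias = FALSE) {
  stopifnot(inherits(state, "pf_state"))
  if (t_end <= state$t) stop("t_end must exceed state$t")
  dt <- state$dt
  nsteps_total <- as.integer(round((t_end - state$t) / dt))
  if (is.null(obs_dt)) obs_dt <- 25 * dt
  obs_every <- max(1L, as.integer(round(obs_dt / dt)))
  t0 <- state$t
  # breakpoints in units of steps from t0
  switches <- if (!is.null(schedule)) {
    st <- attr(schedule, "switch_times")
    st <- st[st > t0 & st < t_end]
    as.integer(ceiling((st - t0) / dt - 1e-9))
  } else integer()
  obs_pts <- seq(obs_every, nsteps_total, by = obs_every)
  breaks <- sort(unique(c(switches, obs_pts, nsteps_total)))
  prev <- 0L
  p <- params$internal
  for (bp in breaks) {
    if (!is.null(schedule))
      state$velocities <- schedule(t0 + prev * dt)
    state <- advance(state, params, bp - prev, dealias = dealias)
    prev <- bp
    at_obs <- (bp %% obs_every == 0L) || bp == nsteps_total
    if (at_obs) {
      dgn <- attr(state, "diagnostics")
      if (!is.null(dgn)) {
        relS <- abs(dgn$S - p$S_target) / p$S_target
        relV <- abs(dgn$V - p$V_target) / p$V_target
        if (any(relS > drift_warn) || any(relV > drift_warn))
          warning(sprintf("S/V drift beyond %.1f%% at t = %.3g s (S rel %.3g/%.3g, V rel %.3g/%.3g)",
                          100 * drift_warn, state$t, relS[1], relS[2],
                          relV[1], relV[2]))
      }
      if (!is.null(observer)) observer(state)
    }
  }
  state
}
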