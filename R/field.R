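#' Order-parameter field for one cell
#'
#' A smooth scalar field on the periodic grid with value about +1 inside the
#' cell, about -1 outside, crossing 0 at the membrane midsurface. Values may
#' transiently overshoot [-1, 1] slightly; overshoot is monitored, never
#' clipped, because clipping would break the variational structure.
#'
#' @param values 3D numeric array matching \code{grid$n}.
#' @param grid a \code{\link{grid_spec}}.
#' @param cell_id integer cell label (1 or 2).
#' @return Object of class \code{pf_field} (list with \code{values},
#'   \code{grid}, \code{cell_id}).
#' @export
pf_field <- function(values, grid, cell_id = 1L) {
  stopifnot(inherits(grid, "pf_grid"))
  if (!identical(dim(values), as.integer(grid$n)))
    stop("field dimensions do not match the grid")
  structure(list(values = values, grid = grid, cell_id = as.integer(cell_id)),
            class = "pf_field")
}

#' @export
print.pf_field <- function(x, ...) {
  cat(sprintf("order-parameter field (cell %d) on %d x %d x %d grid, range [%.3f, %.3f]\n",
              x$cell_id, x$grid$n[1], x$grid$n[2], x$grid$n[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# warn (not clip) when the field leaves the healthy band
check_field_band <- function(values, delta = 0.1, context = "field") {
  r <- range(values)
  if (r[1] < -1 - delta || r[2] > 1 + delta)
    warning(sprintf("%s overshoots [-1,1] beyond %.2f (range %.3f..%.3f)",
                    context, delta, r[1], r[2]))
  invisible(NULL)
}

#' Seed-shape specification for a single cell
#'
#' @param center cell centre, um (3-vector).
#' @param shape \code{"sphere"}, \code{"oblate"}, \code{"prolate"} or
#'   \code{"ellipsoid"}.
#' @param semi_axes semi-axes in um: a single radius for a sphere, otherwise
#'   a length-3 vector (a, b, c) along x, y, z.
#' @return Object of class \code{pf_cellspec}.
#' @export
cell_init_spec <- function(center, shape = c("sphere", "oblate", "prolate", "ellipsoid"),
                           semi_axes) {
  shape <- match.arg(shape)
  if (length(center) != 3) stop("center must be a 3-vector")
  semi_axes <- as.numeric(semi_axes)
  if (shape == "sphere") {
    if (length(semi_axes) == 1) semi_axes <- rep(semi_axes, 3)
  }
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("semi_axes must be positive (length 1 for a sphere, else 3)")
  structure(list(center = as.numeric(center), shape = shape,
                 semi_axes = semi_axes),
            class = "pf_cellspec")
}

#' Build a tanh-profile field from a seed shape
#'
#' The equilibrium 1D interface profile of the adopted bending term is
#' \code{phi = tanh(d / (sqrt(2) epsilon))} with d the signed distance to the
#' surface (positive inside). Spheres use the exact signed distance; for
#' ellipsoids a first-order normal approximation of the distance is used,
#' which is accurate near the interface where it matters (the profile
#' saturates elsewhere).
#'
#' @param spec a \code{\link{cell_init_spec}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param epsilon interface width, um.
#' @param margin required clearance (um) between the seed surface and every
#'   box face; placement failing it is an error. The reference box uses 3 um;
#'   reduced boxes may pass less.
#' @param cell_id cell label.
#' @return A \code{\link{pf_field}}.
#' @examples
#' g <- grid_spec(c(48, 48, 48))
#' f <- make_tanh_field(cell_init_spec(c(4, 4, 4), "sphere", 3), g,
#'                      epsilon = 0.17, margin = 0.5)
#' @export
make_tanh_field <- function(spec, grid, epsilon, margin = 3, cell_id = 1L) {
  stopifnot(inherits(spec, "pf_cellspec"), inherits(grid, "pf_grid"))
  lo <- spec$center - spec$semi_axes
  hi <- spec$center + spec$semi_axes
  if (any(lo < margin) || any(hi > grid$box - margin))
    stop(sprintf("seed shape does not fit the box with a %g um margin", margin))
  ax <- grid_axes(grid)
  n <- grid$n
  X <- array(rep(ax[[1]] - spec$center[1], times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ax[[2]] - spec$center[2], each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(ax[[3]] - spec$center[3], each = n[1] * n[2]), dim = n)
  s <- spec$semi_axes
  if (all(s == s[1])) {
    d <- s[1] - sqrt(X^2 + Y^2 + Z^2)
  } else {
    f <- sqrt((X / s[1])^2 + (Y / s[2])^2 + (Z / s[3])^2)
    gradf <- sqrt((X / s[1]^2)^2 + (Y / s[2]^2)^2 + (Z / s[3]^2)^2)
    d <- (1 - f) * f / pmax(gradf, 1e-12)
    d[f < 1e-6] <- max(s) # deep interior: exact value irrelevant, tanh saturates
  }
  phi <- tanh(d / (sqrt(2) * epsilon))
  pf_field(phi, grid, cell_id = cell_id)
}

#' Translate a field by whole lattice sites (periodic)
#'
#' @param field a \code{pf_field}.
#' @param shift integer 3-vector of lattice sites.
#' @return Shifted \code{pf_field}.
#' @export
shift_field <- function(field, shift) {
  stopifnot(inherits(field, "pf_field"))
  n <- field$grid$n
  shift <- as.integer(round(shift))
  idx <- lapply(1:3, function(a) ((seq_len(n[a]) - 1 - shift[a]) %% n[a]) + 1L)
  pf_field(field$values[idx[[1]], idx[[2]], idx[[3]]], field$grid, field$cell_id)
}

#' Embed a field into a larger box
#'
#' A relaxed cell computed on a small box (field value -1 near its faces) can
#' be re-used on a larger protocol box by copying its voxels into a -1
#' background. The source box must be no larger than the target along every
#' axis and share the lattice spacing.
#'
#' @param field a \code{pf_field} on the source grid.
#' @param grid target \code{\link{grid_spec}}.
#' @param at target position (um) of the source field's centre-of-box,
#'   snapped to the lattice; default centres it.
#' @param cell_id cell label for the result.
#' @return A \code{pf_field} on \code{grid}.
#' @export
embed_field <- function(field, grid, at = NULL, cell_id = field$cell_id) {
  stopifnot(inherits(field, "pf_field"), inherits(grid, "pf_grid"))
  if (abs(field$grid$dx - grid$dx) > 1e-12)
    stop("lattice spacings differ")
  ns <- field$grid$n
  nt <- grid$n
  if (any(ns > nt)) stop("source grid larger than target grid")
  if (is.null(at)) at <- grid$box / 2
  start <- as.integer(round(at / grid$dx - ns / 2)) # 0-based
  vals <- array(-1, dim = nt)
  idx <- lapply(1:3, function(a) ((start[a] + 0:(ns[a] - 1)) %% nt[a]) + 1L)
  vals[idx[[1]], idx[[2]], idx[[3]]] <- field$values
  pf_field(vals, grid, cell_id = cell_id)
}

#' Mirror a field through a mid-plane of the box
#'
#' @param field a \code{pf_field}.
#' @param axis axis (1, 2 or 3) normal to the mirror plane.
#' @return Mirrored \code{pf_field}. The reflection maps lattice site i to
#'   n - i (mod n), which fixes the plane through the origin and the
#'   mid-plane of the periodic box.
#' @export
mirror_field <- function(field, axis = 3L) {
  n <- field$grid$n
  idx <- lapply(1:3, function(a) {
    if (a == axis) c(1L, rev(seq_len(n[a])[-1])) else seq_len(n[a])
  })
  pf_field(field$values[idx[[1]], idx[[2]], idx[[3]]], field$grid, field$cell_id)
}
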