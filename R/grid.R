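#' Periodic uniform grid specification
#'
#' The fields live on a fixed periodic lattice whose spacing equals the
#' interface width epsilon, so one lattice cell resolves one interface width.
#' The reference box is 90 x 90 x 90 points at dx = 0.17 um, i.e.
#' 15.3 x 15.3 x 15.3 um^3; smaller boxes are used for reduced-cost runs.
#'
#' @param n integer vector of points per axis (length 1 or 3); each must be
#'   even (spectral convenience).
#' @param dx lattice spacing, um.
#' @return Object of class \code{pf_grid} with elements \code{n}, \code{dx},
#'   \code{box} (physical extent per axis, um) and \code{dV} (voxel volume).
#' @examples
#' grid_spec(c(64, 64, 64))
#' @export
grid_spec <- function(n = c(90L, 90L, 90L), dx = 0.17) {
  if (length(n) == 1L) n <- rep(n, 3L)
  n <- as.integer(n)
  if (length(n) != 3L || any(n < 8L)) stop("n must give >= 8 points per axis")
  if (any(n %% 2L != 0L)) stop("points per axis must be even")
  if (dx <= 0) stop("dx must be > 0")
  structure(list(n = n, dx = dx, box = n * dx, dV = dx^3,
                 boundary = "periodic"),
            class = "pf_grid")
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("periodic grid %d x %d x %d, dx = %g um (box %g x %g x %g um^3)\n",
              x$n[1], x$n[2], x$n[3], x$dx, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Axis coordinates of a grid
#'
#' @param grid a \code{pf_grid}.
#' @return List of three coordinate vectors (um), starting at 0.
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(a) (seq_len(grid$n[a]) - 1) * grid$dx)
}

# Angular DFT wavenumbers along one axis.
axis_wavenumbers <- function(n, dx) {
  f <- c(0:(n / 2), -(n / 2 - 1):-1)
  2 * pi * f / (n * dx)
}

#' Spectral wavenumber arrays for a grid
#'
#' @param grid a \code{pf_grid}.
#' @return List with per-axis wavenumber vectors \code{kx,ky,kz} and the full
#'   \code{k2} array (|k|^2 per mode, um^-2).
#' @export
wavenumbers <- function(grid) {
  key <- paste0(paste(grid$n, collapse = "x"), "@", format(grid$dx, digits = 17))
  cached <- .pf_cache[[key]]
  if (!is.null(cached)) return(cached)
  kx <- axis_wavenumbers(grid$n[1], grid$dx)
  ky <- axis_wavenumbers(grid$n[2], grid$dx)
  kz <- axis_wavenumbers(grid$n[3], grid$dx)
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  out <- list(kx = kx, ky = ky, kz = kz, k2 = k2)
  .pf_cache[[key]] <- out
  out
}

.pf_cache <- new.env(parent = emptyenv())
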