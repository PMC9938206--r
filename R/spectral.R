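#' Fast 3D Fourier transform on the simulation grid
#'
#' Thin wrapper over the package's FFTW backend with the same conventions as
#' \code{stats::fft}: the forward transform uses \code{exp(-i k r)} and
#' neither direction is normalised. All spectral operators in the package
#' (solver and observables alike) are built on this one transform so that
#' energies, forces and dynamics share identical discrete derivatives.
#'
#' @param z numeric or complex 3D array.
#' @param inverse logical; if TRUE computes the unnormalised inverse.
#' @return Complex array of the same dimensions.
#' @export
spec_fft <- function(z, inverse = FALSE) {
  d <- dim(z)
  if (is.null(d) || length(d) != 3L) stop("z must be a 3D array")
  if (!is.complex(z)) z <- as.complex(z)
  cpp_fft3(z, as.integer(d), isTRUE(inverse))
}

# Real part of the inverse transform, normalised.
ifft_real <- function(zh) {
  Re(spec_fft(zh, inverse = TRUE)) / length(zh)
}

#' Spectral Laplacian of a real field
#' @param arr 3D numeric array on \code{grid}.
#' @param grid a \code{\link{grid_spec}}.
#' @return Array of the same shape.
#' @export
spectral_laplacian <- function(arr, grid) {
  w <- wavenumbers(grid)
  ifft_real(-w$k2 * spec_fft(arr))
}

#' Spectral gradient components of a real field
#' @param arr 3D numeric array on \code{grid}.
#' @param grid a \code{\link{grid_spec}}.
#' @param axes which components to return (subset of 1:3).
#' @return List of arrays, one per requested axis.
#' @export
spectral_gradient <- function(arr, grid, axes = 1:3) {
  w <- wavenumbers(grid)
  zh <- spec_fft(arr)
  n <- grid$n
  out <- vector("list", length(axes))
  for (i in seq_along(axes)) {
    a <- axes[i]
    ka <- switch(a,
                 rep(w$kx, times = n[2] * n[3]),
                 rep(rep(w$ky, each = n[1]), times = n[3]),
                 rep(w$kz, each = n[1] * n[2]))
    g <- zh
    g[] <- complex(real = -ka * Im(zh), imaginary = ka * Re(zh))
    out[[i]] <- ifft_real(g)
  }
  names(out) <- c("x", "y", "z")[axes]
  out
}

#' Precompute the semi-implicit spectral operators
#'
#' The stiffest linear term of the dynamics, the squared-Laplacian bending
#' contribution \code{-2 M kappa_B epsilon^4 lap^2 phi}, is treated
#' implicitly: each Fourier mode is divided by
#' \code{1 + 2 dt M kappa_B epsilon^4 |k|^4} after the explicit update.
#' The denominator is >= 1 for every mode, so the implicit part damps
#' unconditionally and never amplifies.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param params a \code{\link{pf_params}}.
#' @param dt time step, s.
#' @param dealias if TRUE also return a 2/3-rule mask (off by default in the
#'   solver).
#' @return List with \code{k2} (array), \code{denominator} (array) and
#'   optionally \code{dealias_mask} (logical array of modes kept).
#' @export
build_operators <- function(grid, params, dt, dealias = FALSE) {
  stopifnot(inherits(grid, "pf_grid"), inherits(params, "pf_params"))
  if (dt <= 0) stop("dt must be > 0")
  w <- wavenumbers(grid)
  i <- params$internal
  den <- 1 + 2 * dt * i$M * i$kappa_B * i$epsilon^4 * w$k2^2
  out <- list(k2 = w$k2, denominator = den)
  if (dealias) {
    kmax <- (2 / 3) * pi / grid$dx
    keepx <- abs(w$kx) <= kmax
    keepy <- abs(w$ky) <= kmax
    keepz <- abs(w$kz) <= kmax
    out$dealias_mask <- outer(outer(keepx, keepy, `&`), keepz, `&`)
  }
  out
}
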