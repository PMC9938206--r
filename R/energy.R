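#' Volume-fraction interpolation function
#'
#' \code{h(phi) = (1/4) (1 + phi)^2 (2 - phi)} maps the bulk phases to
#' h(-1) = 0 and h(1) = 1 with h(0) = 1/2 and h'(phi) = (3/4)(1 - phi^2),
#' so h' vanishes in both bulk phases. It converts the order parameter into
#' a local volume fraction, moderates the hard-core repulsion term, and its
#' gradient carries the adhesion coupling.
#'
#' @param phi numeric scalar or array.
#' @return Same shape as \code{phi}.
#' @examples
#' h_interp(c(-1, 0, 1))
#' @export
h_interp <- function(phi) {
  0.25 * (1 + phi)^2 * (2 - phi)
}

#' Membrane area of a field
#'
#' Phase-field surface functional
#' \code{S = (3 / (2 sqrt(2))) epsilon integral (grad phi)^2 dr}, evaluated
#' with spectral gradients (Parseval form). For a tanh interface this
#' measures exactly the area of the midsurface in the sharp-interface limit.
#'
#' @param field a \code{\link{pf_field}}.
#' @param epsilon interface width, um.
#' @return Area in um^2.
#' @export
surface_of <- function(field, epsilon) {
  stopifnot(inherits(field, "pf_field"))
  g <- field$grid
  w <- wavenumbers(g)
  zh <- spec_fft(field$values)
  gradsq <- sum(w$k2 * (Re(zh)^2 + Im(zh)^2)) / length(zh)
  3 * epsilon / (2 * sqrt(2)) * gradsq * g$dV
}

#' Enclosed volume of a field
#'
#' Phase-field volume functional \code{V = integral h(phi) dr}.
#'
#' @param field a \code{\link{pf_field}}.
#' @return Volume in um^3.
#' @export
volume_of <- function(field) {
  stopifnot(inherits(field, "pf_field"))
  sum(h_interp(field$values)) * field$grid$dV
}

#' Geometric summary of a cell field
#'
#' @param field a \code{\link{pf_field}}.
#' @param epsilon interface width, um.
#' @return List with \code{S} (um^2), \code{V} (um^3), \code{nu} (reduced
#'   volume), \code{centroid} (um, h-weighted), and \code{inertia} (3x3
#'   second-moment tensor of h(phi) about the centroid, um^2 x volume).
#' @export
geometry_of <- function(field, epsilon) {
  g <- field$grid
  h <- h_interp(field$values)
  Vtot <- sum(h) * g$dV
  S <- surface_of(field, epsilon)
  ax <- grid_axes(g)
  n <- g$n
  X <- array(rep(ax[[1]], times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ax[[2]], each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(ax[[3]], each = n[1] * n[2]), dim = n)
  m <- sum(h)
  cen <- c(sum(h * X), sum(h * Y), sum(h * Z)) / m
  dX <- X - cen[1]; dY <- Y - cen[2]; dZ <- Z - cen[3]
  I <- matrix(c(sum(h * dX * dX), sum(h * dX * dY), sum(h * dX * dZ),
                sum(h * dX * dY), sum(h * dY * dY), sum(h * dY * dZ),
                sum(h * dX * dZ), sum(h * dY * dZ), sum(h * dZ * dZ)),
              3, 3) * g$dV
  nu <- if (S > 0 && Vtot > 0) reduced_volume(S, Vtot) else NA_real_
  list(S = S, V = Vtot, nu = nu, centroid = cen, inertia = I)
}

#' Free energy of the two-cell system
#'
#' Evaluates the five contributions of the model free energy on the current
#' fields:
#' \itemize{
#'   \item bending: \code{integral kappa_B sum_i (-phi_i + phi_i^3 -
#'     epsilon^2 lap phi_i)^2 dr} (the convention whose 1D tanh kink has zero
#'     bending integrand);
#'   \item repulsion: \code{integral gamma h(phi_1) h(phi_2) dr};
#'   \item adhesion: \code{integral eta grad h(phi_1) . grad h(phi_2) dr}
#'     (negative for anti-parallel interfaces in contact);
#'   \item surface penalty: \code{alpha_S sum_i (S_target - S[phi_i])^2};
#'   \item volume penalty: \code{alpha_V sum_i (V_target - V[phi_i])^2}.
#' }
#'
#' @param phi1,phi2 \code{\link{pf_field}} objects on the same grid.
#' @param params a \code{\link{pf_params}}.
#' @return Object of class \code{pf_energy}: list with \code{bending},
#'   \code{repulsion}, \code{adhesion}, \code{surface_penalty},
#'   \code{volume_penalty} and \code{total}, all in aJ.
#' @export
free_energy <- function(phi1, phi2, params) {
  stopifnot(inherits(phi1, "pf_field"), inherits(phi2, "pf_field"),
            inherits(params, "pf_params"))
  if (!identical(phi1$grid$n, phi2$grid$n) ||
      abs(phi1$grid$dx - phi2$grid$dx) > 1e-12)
    stop("fields must share one grid")
  g <- phi1$grid
  p <- params$internal
  e2 <- p$epsilon^2
  a <- phi1$values
  b <- phi2$values
  mu1 <- -a + a^3 - e2 * spectral_laplacian(a, g)
  mu2 <- -b + b^3 - e2 * spectral_laplacian(b, g)
  bending <- p$kappa_B * sum(mu1^2 + mu2^2) * g$dV
  h1 <- h_interp(a)
  h2 <- h_interp(b)
  repulsion <- p$gamma * sum(h1 * h2) * g$dV
  # adhesion integral in the integrated-by-parts form -h1 lap(h2): identical
  # in the continuum, and discretely the exact antiderivative of the drift
  # term used by the dynamics (the gradient form would silently drop the
  # Nyquist content of the marginally resolved interface profile)
  adhesion <- -p$eta * sum(h1 * spectral_laplacian(h2, g)) * g$dV
  S1 <- surface_of(phi1, p$epsilon); S2 <- surface_of(phi2, p$epsilon)
  V1 <- volume_of(phi1); V2 <- volume_of(phi2)
  surfpen <- p$alpha_S * ((p$S_target - S1)^2 + (p$S_target - S2)^2)
  volpen <- p$alpha_V * ((p$V_target - V1)^2 + (p$V_target - V2)^2)
  structure(list(bending = bending, repulsion = repulsion,
                 adhesion = adhesion, surface_penalty = surfpen,
                 volume_penalty = volpen,
                 total = bending + repulsion + adhesion + surfpen + volpen),
            class = "pf_energy")
}

#' @export
print.pf_energy <- function(x, ...) {
  cat(sprintf("free energy (aJ): bending %.4g, repulsion %.4g, adhesion %.4g,\n",
              x$bending, x$repulsion, x$adhesion))
  cat(sprintf("  surface penalty %.4g, volume penalty %.4g, total %.4g\n",
              x$surface_penalty, x$volume_penalty, x$total))
  invisible(x)
}

#' Deterministic drift of the order-parameter dynamics
#'
#' Returns \code{-M dF/dphi_1} evaluated with spectral operators: the full
#' right-hand side of the evolution equation at zero advection velocity,
#' i.e. the instantaneous rate of change of \code{phi1}. The partner cell's
#' drift follows by exchanging the fields.
#'
#' @param phi1,phi2 \code{\link{pf_field}}s on one grid (\code{phi1} is the
#'   cell being evolved).
#' @param params a \code{\link{pf_params}}.
#' @return 3D numeric array, units 1/s.
#' @export
variational_derivative <- function(phi1, phi2, params) {
  stopifnot(inherits(phi1, "pf_field"), inherits(phi2, "pf_field"))
  if (!identical(phi1$grid$n, phi2$grid$n))
    stop("fields must share one grid")
  g <- phi1$grid
  p <- params$internal
  e2 <- p$epsilon^2
  a <- phi1$values
  b <- phi2$values
  lap1 <- spectral_laplacian(a, g)
  mu1 <- -a + a^3 - e2 * lap1
  h2 <- h_interp(b)
  S1 <- surface_of(phi1, p$epsilon)
  V1 <- volume_of(phi1)
  drift <- -2 * p$M * p$kappa_B * (3 * a^2 - 1) * mu1 +
    2 * p$M * p$kappa_B * e2 * spectral_laplacian(mu1, g) -
    0.75 * p$M * p$gamma * (1 - a^2) * h2 +
    0.75 * p$M * p$eta * (1 - a^2) * spectral_laplacian(h2, g) -
    3 * sqrt(2) * p$M * p$epsilon * p$alpha_S * (p$S_target - S1) * lap1 +
    1.5 * p$M * p$alpha_V * (p$V_target - V1) * (1 - a^2)
  drift
}
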