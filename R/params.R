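#' Physical parameters of the two-cell phase-field model
#'
#' Collects every physical coefficient of the model in one immutable object
#' and converts them once into the package's internal unit system:
#' micrometre (length), second (time), attojoule (energy). In these units all
#' default coefficients are of order 1e-2 to 1e5, comfortably inside double
#' range, and the interaction force comes out directly in piconewtons
#' (1 aJ/um = 1 pN).
#'
#' Arguments are given in the customary display units of the erythrocyte
#' membrane literature, listed below. The defaults are the model's reference
#' parameterisation for two healthy erythrocytes bridged by fibrinogen.
#'
#' @param kappa_B bending rigidity coefficient, J/m^3 (numerically equal to
#'   aJ/um^3). Default 432.
#' @param epsilon interface width, equal to the lattice spacing, um.
#'   Default 0.17.
#' @param gamma hard-core repulsion coefficient, J/m^3. Default 138.
#' @param eta cell-cell adhesion coefficient, J/m. Default 8.0e-12
#'   (the weaker of the two reference adhesion strengths; 2.7e-11 J/m is the
#'   strong-adhesion setting).
#' @param alpha_S area-penalty coefficient, J/mm^4. Default 1.8e-2.
#' @param alpha_V volume-penalty coefficient, J/mm^6. Default 5.9e4.
#' @param S_target target membrane area, um^2. Default 197.
#' @param V_target target cell volume, um^3. Default 160.
#' @param M mobility, m^3 J^-1 s^-1. Default 7.4e-2.
#' @param v advection speed applied to each cell, um/s. Default 0.57
#'   (relative approach speed 2v = 1.14 um/s).
#'
#' @return An object of class \code{pf_params}: a list with elements
#'   \code{display} (the constructor arguments, display units) and
#'   \code{internal} (um / s / aJ values used by all numerics). Treat it as
#'   immutable; derive variants with \code{\link{update_params}}.
#' @examples
#' p <- pf_params()
#' p$internal$eta    # 8 aJ/um
#' nondimensionalize(p)$K_B  # sharp-interface bending rigidity, ~2 aJ
#' @export
pf_params <- function(kappa_B = 432, epsilon = 0.17, gamma = 138,
                      eta = 8.0e-12, alpha_S = 1.8e-2, alpha_V = 5.9e4,
                      S_target = 197, V_target = 160, M = 7.4e-2, v = 0.57) {
  display <- list(kappa_B = kappa_B, epsilon = epsilon, gamma = gamma,
                  eta = eta, alpha_S = alpha_S, alpha_V = alpha_V,
                  S_target = S_target, V_target = V_target, M = M, v = v)
  for (nm in names(display)) {
    val <- display[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number")
    if (val < 0) stop("parameter '", nm, "' must be non-negative")
  }
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (S_target <= 0 || V_target <= 0)
    stop("S_target and V_target must be > 0")
  internal <- list(
    kappa_B = kappa_B,          # J/m^3 == aJ/um^3
    epsilon = epsilon,          # um
    gamma   = gamma,            # J/m^3 == aJ/um^3
    eta     = eta * 1e12,       # J/m   -> aJ/um
    alpha_S = alpha_S * 1e6,    # J/mm^4 -> aJ/um^4
    alpha_V = alpha_V,          # J/mm^6 == aJ/um^6
    S_target = S_target,        # um^2
    V_target = V_target,        # um^3
    M = M,                      # m^3/(J s) == um^3/(aJ s)
    v = v                       # um/s
  )
  structure(list(display = display, internal = internal),
            class = "pf_params")
}

#' Create a modified copy of a parameter set
#'
#' Parameter objects are immutable; protocol-level overrides (for instance an
#' adhesion-coefficient sweep) create new instances so that logged runs remain
#' reproducible.
#'
#' @param params a \code{\link{pf_params}} object.
#' @param ... named replacements in display units, e.g. \code{eta = 2.7e-11}.
#' @return A new \code{pf_params} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "pf_params"))
  repl <- list(...)
  args <- params$display
  unknown <- setdiff(names(repl), names(args))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  args[names(repl)] <- repl
  do.call(pf_params, args)
}

#' Recover display-unit values from internal values
#'
#' Inverse of the conversion applied by \code{\link{pf_params}}; the round
#' trip is exact to well beyond 6 significant digits.
#'
#' @param params a \code{pf_params} object.
#' @return Named list in display units.
#' @export
params_display <- function(params) {
  stopifnot(inherits(params, "pf_params"))
  i <- params$internal
  list(kappa_B = i$kappa_B, epsilon = i$epsilon, gamma = i$gamma,
       eta = i$eta * 1e-12, alpha_S = i$alpha_S * 1e-6,
       alpha_V = i$alpha_V, S_target = i$S_target, V_target = i$V_target,
       M = i$M, v = i$v)
}

#' @export
print.pf_params <- function(x, ...) {
  d <- x$display
  cat("Two-cell phase-field model parameters\n")
  fmt <- function(v) format(v, digits = 6)
  cat(sprintf("  kappa_B  %s J/m^3     epsilon  %s um\n",
              fmt(d$kappa_B), fmt(d$epsilon)))
  cat(sprintf("  gamma    %s J/m^3     eta      %s J/m\n",
              fmt(d$gamma), fmt(d$eta)))
  cat(sprintf("  alpha_S  %s J/mm^4   alpha_V  %s J/mm^6\n",
              fmt(d$alpha_S), fmt(d$alpha_V)))
  cat(sprintf("  S_target %s um^2      V_target %s um^3\n",
              fmt(d$S_target), fmt(d$V_target)))
  cat(sprintf("  M        %s m^3/(J s)  v        %s um/s\n",
              fmt(d$M), fmt(d$v)))
  g <- nondimensionalize(x)
  cat(sprintf("  derived: tau = %.4g s, K_B = %.4g aJ, v' = %.4g, gamma' = %.4g, eta' = %.4g\n",
              g$tau, g$K_B, g$v_prime, g$gamma_prime, g$eta_prime))
  invisible(x)
}

#' Sharp-interface bending rigidity
#'
#' In the sharp-interface limit the phase-field bending term reduces to the
#' Canham-Helfrich mean-curvature energy with rigidity
#' \code{K_B = (4 epsilon^3 / (3 sqrt(2))) kappa_B}.
#'
#' @param kappa_B bending rigidity coefficient, aJ/um^3 (numerically equal to
#'   J/m^3).
#' @param epsilon interface width, um.
#' @return Bending rigidity K_B in aJ. The default parameterisation
#'   (432, 0.17) gives 2.0 aJ, inside the 0.2-3 aJ range reported for
#'   erythrocyte membranes.
#' @examples
#' derive_bending_rigidity(432, 0.17)
#' @export
derive_bending_rigidity <- function(kappa_B, epsilon) {
  if (!is.numeric(epsilon) || any(epsilon <= 0))
    stop("epsilon must be > 0")
  if (any(kappa_B < 0)) stop("kappa_B must be >= 0")
  4 * epsilon^3 / (3 * sqrt(2)) * kappa_B
}

#' Adhesion energy per unit contact area
#'
#' Integrating the adhesion term across two equilibrium tanh interfaces in
#' full anti-parallel contact gives an adhesion energy per unit membrane area
#' of \code{(9 sqrt(2) / (35 epsilon)) eta}.
#'
#' @param eta adhesion coefficient, aJ/um (Table value 8.0e-12 J/m equals
#'   8.0 aJ/um).
#' @param epsilon interface width, um.
#' @return Adhesion energy density in aJ/um^2 (17.1 aJ/um^2 at the default
#'   weak-adhesion setting).
#' @examples
#' adhesion_energy_per_area(8.0, 0.17)
#' @export
adhesion_energy_per_area <- function(eta, epsilon) {
  if (!is.numeric(epsilon) || any(epsilon <= 0))
    stop("epsilon must be > 0")
  9 * sqrt(2) / (35 * epsilon) * eta
}

#' Reduced volume of a closed membrane
#'
#' Ratio of the enclosed volume to the volume of the sphere having the same
#' surface area. The reduced volume selects the equilibrium vesicle branch:
#' stomatocyte for nu below about 0.55, oblate/discocyte near 0.60, prolate
#' above about 0.65.
#'
#' @param S membrane area, um^2.
#' @param V enclosed volume, um^3.
#' @return Dimensionless reduced volume in (0, 1] for realisable shapes. A
#'   value exceeding 1 by more than 1e-6 relative triggers a warning, since no
#'   closed surface can hold more volume than a sphere of equal area.
#' @examples
#' reduced_volume(197, 160)  # ~0.615, the discocyte regime
#' @export
reduced_volume <- function(S, V) {
  if (any(S <= 0) || any(V <= 0)) stop("S and V must be > 0")
  nu <- V / ((4 / 3) * pi * (S / (4 * pi))^(3 / 2))
  if (any(nu > 1 + 1e-6))
    warning("reduced volume exceeds 1: no closed surface encloses more volume than the equal-area sphere")
  nu
}

#' Dimensionless groups and derived scales
#'
#' @param params a \code{\link{pf_params}} object.
#' @return List with \code{tau} (simulation timescale 1/(M kappa_B), s),
#'   \code{v_prime} (advection speed in interface widths per tau),
#'   \code{gamma_prime} = gamma/kappa_B, \code{eta_prime} =
#'   eta/(kappa_B epsilon^2), and \code{K_B} (sharp-interface bending
#'   rigidity, aJ).
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "pf_params"))
  i <- params$internal
  if (i$M * i$kappa_B == 0)
    stop("M * kappa_B must be > 0: the timescale is undefined")
  list(tau = 1 / (i$M * i$kappa_B),
       v_prime = i$v / (i$M * i$kappa_B * i$epsilon),
       gamma_prime = i$gamma / i$kappa_B,
       eta_prime = i$eta / (i$kappa_B * i$epsilon^2),
       K_B = derive_bending_rigidity(i$kappa_B, i$epsilon))
}
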