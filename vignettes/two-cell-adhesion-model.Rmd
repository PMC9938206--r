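---
title: "A two-cell phase-field model of erythrocyte adhesion: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-cell phase-field model of erythrocyte adhesion: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rbcphase` simulates the mechanical interaction of two erythrocytes, each
represented by a scalar order parameter $\phi_i(\vec r)$ on a periodic 3D
lattice, with $\phi_i \approx +1$ inside the cell, $\approx -1$ outside, and
the membrane at the level set $\phi_i = 0$. The interface has a fixed
diffuse width $\epsilon$ equal to the lattice spacing, with the equilibrium
1D profile $\phi = \tanh(d/\sqrt{2}\epsilon)$ in the signed distance $d$.

The free energy contains five contributions:

$$
F = \int \kappa_B \sum_i \big({-\phi_i} + \phi_i^3 - \epsilon^2
\nabla^2\phi_i\big)^2 \mathrm{d}\vec r
  + \int \big(\gamma\, h(\phi_1) h(\phi_2) + \eta\, \nabla h(\phi_1) \cdot
  \nabla h(\phi_2)\big) \mathrm{d}\vec r
  + \alpha_S \sum_i (S_\mathrm{t} - S[\phi_i])^2
  + \alpha_V \sum_i (V_\mathrm{t} - V[\phi_i])^2
$$

* **Bending.** The squared term is the phase-field form of the
  Canham–Helfrich mean-curvature energy. In the sharp-interface limit its
  rigidity is $K_B = (4\epsilon^3/3\sqrt2)\,\kappa_B$; with the defaults
  ($\kappa_B = 432$ J/m³, $\epsilon = 0.17$ µm) this gives
  $K_B = 2.0$ aJ, inside the 0.2–3 aJ range measured for erythrocyte
  membranes. The Gaussian-curvature term is omitted: for closed vesicles of
  fixed topology it is a constant by the Gauss–Bonnet theorem. No
  spontaneous curvature and no explicit cytoskeletal shear elasticity are
  included; the bending term alone stabilises the discocyte.
* **Hard-core repulsion** ($\gamma$) penalises overlap of the two interiors
  through $h(\phi) = \tfrac14(1+\phi)^2(2-\phi)$, a volume-fraction
  interpolation with $h(-1)=0$, $h(1)=1$ and $h'(\phi) =
  \tfrac34(1-\phi^2)$, which vanishes in both bulk phases so the
  interaction never pushes $\phi$ out of $[-1,1]$.
* **Adhesion** ($\eta$) lowers the energy when the two interface gradients
  are anti-parallel, i.e. membranes in contact — the model's proxy for
  fibrinogen bridging. Integrated across two coincident equilibrium
  interfaces it yields an adhesion energy per unit area of
  $(9\sqrt2/35\epsilon)\,\eta$ (17.1 aJ/µm² at $\eta = 8\times10^{-12}$
  J/m). The two reference settings, $\eta = 8.0\times10^{-12}$ and
  $2.7\times10^{-11}$ J/m, bracket weak and strong bridging.
* **Area and volume penalties** hold each cell at $S_\mathrm{t} = 197$ µm²
  and $V_\mathrm{t} = 160$ µm³, using the functionals
  $S[\phi] = (3\epsilon/2\sqrt2)\int(\nabla\phi)^2$ and
  $V[\phi] = \int h(\phi)$. The reduced volume
  $\nu = V_\mathrm{t} / \big(\tfrac43\pi (S_\mathrm{t}/4\pi)^{3/2}\big)
  \approx 0.614$ places the equilibrium shape on the oblate (discocyte)
  branch of the vesicle shape diagram: stomatocytes below $\nu \approx
  0.55$, oblates near $0.60$, prolates above $\approx 0.65$.

A printed form of the bending integrand with the opposite Laplacian sign
circulates in the field; this package uses
$-\phi+\phi^3-\epsilon^2\nabla^2\phi$ throughout, since only that
combination vanishes on the tanh kink (making a flat interface bending-free)
and reproduces both sharp-interface constants above. Energy and dynamics
use the same convention, so the evolution is an exact gradient flow of the
implemented functional.

Each field evolves by relaxational dynamics with imposed advection,

$$\partial_t \phi_1 + \vec v_1\cdot\nabla\phi_1 = -M\,\delta F/\delta\phi_1,$$

and the same with indices exchanged. The mobility $M$ sets the timescale
$\tau = 1/(M\kappa_B) \approx 31$ ms. Velocities are imposed, not
hydrodynamic: the reference protocol moves the cells at $\pm v$ with
$v = 0.57$ µm/s (relative speed 1.14 µm/s), matching the piezo speed of the
micropipette assay the model is calibrated against.

The interaction force on cell 1 is measured as
$\vec F_1 = -\int \phi_1 \nabla\big(\delta F_\mathrm{int}/\delta\phi_1\big)
\mathrm{d}\vec r$ with $\delta F_\mathrm{int}/\delta\phi_1 =
\tfrac34(1-\phi_1^2)\big[\gamma h(\phi_2) - \eta\nabla^2 h(\phi_2)\big]$.
In the package's internal units (µm, s, aJ) forces come out directly in pN.
The $\gamma$-only and $\eta$-only parts are reported separately; they sum
to the total exactly.

## Numerical scheme

The solver is a fixed-grid Fourier-spectral semi-implicit integrator
(`src/pf_core.cpp`, FFTW backend). All spatial derivatives are spectral on
the periodic lattice; both real fields share each complex transform by
packing $\phi_1 + i\phi_2$. Per step:

1. the nonlinear, interaction and advection terms are evaluated at the
   current time (products in real space, derivatives in Fourier space);
2. the update is divided mode-by-mode by
   $1 + 2\,\Delta t\, M \kappa_B \epsilon^4 |k|^4$, i.e. the time
   derivative and the stiff squared-Laplacian part of the bending force are
   implicit. The denominator is $\ge 1$ for every mode, so the implicit
   part damps unconditionally.

**Constraint splitting.** The printed penalty stiffnesses are deliberately
extreme: linearising the constraint feedback gives relaxation rates of
order $10^5\,\mathrm{s^{-1}}$ for the volume error and larger for area —
their explicit product with any practical $\Delta t$ exceeds the Euler
stability bound by orders of magnitude, and they are not diagonal in
Fourier space, so they cannot join the implicit denominator. They are
therefore integrated by operator splitting. Per step and per cell, the
two scalar errors $E_S = S_\mathrm{t}-S$, $E_V = V_\mathrm{t}-V$ obey
$\dot E = -A E$ with $A$ the positive-semidefinite overlap (Gram) matrix of
the two constraint forces; this 2×2 linear system is solved in closed form
over $\Delta t$. The field update realising those relaxed errors is then
computed along the two constraint-force directions $-\nabla^2\phi$ and
$1-\phi^2$, using the fact that $S$ is an exact quadratic and $V$ an exact
cubic polynomial in the two amplitudes — a two-variable Newton solve with a
trust region, typically converging in 3–5 iterations to machine precision.
Each integration segment ends with one such projection, so observed states
sit on the constraint manifold: recorded $S$ and $V$ equal their targets to
10 significant digits, and the recorded energy decreases monotonically in
relaxation runs. Two guards make the substep robust: the per-step
constraint move is capped at 2% of the target, so a seed far from its
targets (for instance a cup seed for a low-reduced-volume run) walks onto
the constraint manifold over tens of steps instead of demanding one large
update outside the polynomial model's trust region; and a field with no
interface content (the empty half of the state in single-cell runs) is
skipped, since no shape update can satisfy a volume constraint there.

**Step size.** The default is $\Delta t = 0.01\tau \approx 3.1\times
10^{-4}$ s, which resolves the advection (about 0.1 lattice units per
$\tau$) and keeps all explicit terms deep inside their stability region.
The scheme remains stable and accurate for the shape and force observables
up to $\Delta t = 0.05\tau$, which the test suite and the acceptance
script use for relaxation and collision runs (the acceptance collision uses
$0.025\tau$). Halving $\Delta t$ moves the recorded force peaks by under
2%.

**Grids.** The reference box is $90^3$ points at $\mathrm{d}x = \epsilon$
(15.3 µm per side). The relaxed discocyte measures 9.9 µm across and
2.0 µm thick, so reduced boxes are chosen per protocol as the smallest
lattice that keeps every interface at least ~1 µm from its nearest periodic
image: $72\times72\times40$ for single-cell relaxation,
$72\times72\times64$ for aligned collisions, and $72\times96\times64$
when the offset displaces the pair along $y$ ($96$ accommodates the
4.08 µm offset). Boundary conditions are periodic
(forced by the spectral method; the physical setup is two cells in open
plasma, so box-size effects are controlled by those margins). Dealiasing by
the 2/3 rule is available behind a flag but off by default; the nonlinear
terms are cubic and well resolved at $\mathrm{d}x=\epsilon$, and switching
the mask on changes no reported observable beyond the stated tolerances.

**Discrete-consistency choices.** The adhesion energy is evaluated in the
integrated-by-parts form $-\eta\int h_1\nabla^2h_2$, which is identical to
the gradient form in the continuum and, discretely, is the exact
antiderivative of the adhesion term of the dynamics: the central-difference
functional-derivative test then agrees with the implemented drift to
$10^{-4}$ relative. (The gradient form with real-projected spectral
gradients silently drops Nyquist content of the marginally resolved
interface and disagrees by a few percent.) The interface profile is never
clipped to $[-1,1]$; overshoot is only monitored, because clipping would
break the variational structure.

## Shape preparation and classification

Single cells are relaxed from matched seeds: an axisymmetric ellipsoid with
exactly the target area and volume (solved by bisection on the aspect
ratio), placed as a tanh profile of the approximate signed distance.
Relaxation integrates the single-cell dynamics ($\vec v = 0$, interaction
off; the partner slot carries an identical non-interacting copy so both
packed fields see well-posed constraints) until the relative energy change
per $\tau$ falls below a tolerance ($10^{-7}$ by default; $3\times10^{-4}$
in the scaled-down test and acceptance runs, which stops after roughly
200$\tau$ — the constraints are then exact by projection, the shape label
is stable, and the bending energy is within about 10% of its long-time
asymptote).
Near $\nu \approx 0.6$ the oblate and stomatocyte branches can both be
locally stable, so the seed biases the outcome: the oblate seed is the
default, and a cup-shaped seed (`make_cup_field`) reaches the stomatocyte
branch at low $\nu$.

Shapes are classified from the eigenvalues $\lambda_1\le\lambda_2\le
\lambda_3$ of the second-moment tensor of $h(\phi)$: prolate if
$\lambda_3/\lambda_2 > 1.5$ and $\lambda_2/\lambda_1 < 1.2$, oblate-like if
$\lambda_2/\lambda_1 > 1.5$ and $\lambda_3/\lambda_2 < 1.2$, sphere-like if
all ratios are within 1.1. Oblate-like shapes are split by a
face-asymmetry score comparing the dimple depths $d_\pm$ on the two faces
along the symmetry axis ($|d_+-d_-|/\max(d_+,d_-)$): above 0.3 the shape is
a one-sided invagination (stomatocyte), below it the symmetric biconcave
discocyte. The thresholds are package choices; the labels they produce are
validated on analytic ellipsoids and cups in the test suite.

## Collision protocols

`setup_two_cells` embeds two copies of the relaxed cell into the protocol
box, symmetry axes along $z$, centres offset by $d$ along $y$ and facing
surfaces separated by an initial gap along $z$, all placed in whole lattice
units so offsets and gaps are exact. The relative approach travels
$2v \times 1.18\,\mathrm{s} = 1.35$ µm by the reversal time, so the gap
fixes the compression depth: the default gap of $4\epsilon = 0.68$ µm puts
first adhesive contact about a quarter second into the approach and leaves
$\sim$0.7 µm of mutual compression at reversal — deep enough to flatten
the facing dimples, produce the repulsion maximum and bring the bonded
contact into the 50–100 µm² range. (A gap of $10\epsilon$ or more, with
the same reversal time, never reaches geometric contact: the force curve
then shows a single $\sim$270 pN attraction hump from interface-tail
overlap, no repulsion phase, and $\sim$1 µm² of contact.) Forces are
reported on the right-hand (upper-$z$, initially downward-moving) cell, so
negative $F_z$ is attraction toward its partner: the aligned force curve
reads, in order, an attraction dip while the membranes zip together, a
repulsion maximum at reversal, a post-reversal adhesion extremum, and decay
to zero at separation.

Observables are recorded at a fixed cadence (default 0.05 s): Eq.-3 forces
with their repulsion/adhesion decomposition, the energy breakdown, contact
area (interface area of cell 1 weighted by the partner's interface
indicator $1-\phi_2^2 > 0.1$ — a package definition chosen so that two
coincident membranes count their full contact patch; a threshold on the
partner's bulk fraction $h(\phi_2)$ would cut roughly half of the profile
weight at a coincident interface), a
columnwise minimum surface gap, per-cell geometry, and optional volumetric
snapshots. Detachment work integrates the attractive part of $F_z$ times
the relative speed from reversal until the force first falls below 1 pN,
mirroring how work is read off an AFM retraction curve.

## Scope of the synthetic conditions

All inputs are generated internally: the model's own relaxed shapes under
the reference parameters are the initial data, and the collision protocols
are deterministic (no thermal noise term exists in the dynamics, so runs
are bit-reproducible given a configuration). What passing tests show is
internal consistency of the implemented model — sharp-interface constants,
gradient-flow monotonicity, constraint conservation, force-curve structure
and scales — at reduced boxes and coarsened steps. They do not show
agreement with any particular cell pair in an experiment: real erythrocytes
have cytoskeletal shear elasticity, membrane viscosity, thermal
fluctuations and hydrodynamic coupling, all outside this model, and the
simulated force scale is set by calibrating $\eta$ against the AFM range
rather than predicted from molecular parameters.

## The force scale

With the reference parameters the simulated force peaks are nanonewton-
scale, an order of magnitude above the $\sim$300 pN AFM detachment forces
the adhesion coefficient is calibrated against. This is not a resolution
artefact (halving the step or refining the box moves the peaks by under
2%); it follows from the model's own energy bookkeeping. The adhesion
energy of a bonded patch is $w A$ with $w = 17.1$ aJ/µm²; at $A \approx
58$ µm² that is $\approx 1.2$ fJ, and the pair separates within about one
micron of retraction, so the mean attractive force during detachment must
be of order 1 nN. A $\sim$300 pN peak arises in this model only when the
bonded area stays near 1 µm² (barely-touching protocols), which
simultaneously eliminates the repulsion phase and the tens-of-µm² contact.
The femtojoule quantities — adhesion energy at maximal contact
($\approx 1.2$ fJ) and detachment work ($\approx 1.3$ fJ) — do land on
the experimentally measured scale. In AFM experiments the separation
extends over several microns of peeling and tether extrusion, spreading the
same femtojoules over a 5–10× longer distance; the model's imposed rigid
advection compresses detachment into one micron and concentrates the force
accordingly.

## Known limitations

* Imposed advection means momentum is not conserved and the surrounding
  fluid exerts no drag; separation dynamics at strong adhesion are
  therefore indicative, not quantitative.
* The contact-area definition is threshold-based; values quoted at maximal
  compression vary by a few percent with the threshold.
* At $\mathrm{d}x = \epsilon$ the interface is marginally resolved by
  design (one lattice unit per width); observables that probe fourth
  derivatives of $\phi$ carry a few-percent discretisation error, which the
  radius-independence and refinement tests bound.
* The constraint projection enforces $S$ and $V$ exactly at observation
  times; between substeps within a step the errors transiently reach the
  first-order splitting scale (well under 1% at the default step).
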