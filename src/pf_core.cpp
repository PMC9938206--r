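// Spectral semi-implicit integrator for the two-cell phase-field dynamics.
//
// The order parameters phi_1, phi_2 live on a periodic uniform grid and are
// advanced by the coupled gradient-flow/advection equation
//
//   d(phi_i)/dt + v_i . grad(phi_i) = -M dF/dphi_i
//
// with F the bending + interaction + surface/volume-penalty free energy.
// The linear time derivative and the squared-Laplacian bending contribution
// (-2 M kappa_B eps^4 lap^2 phi) are treated implicitly in Fourier space;
// every other term is evaluated explicitly at the current step.
//
// All quantities are in internal units: micrometre, second, attojoule.
// Both real fields are packed into one complex array (phi1 + i phi2), so a
// single complex FFT transforms both cells at once.

#include <Rcpp.h>
#include <fftw3.h>
#include <vector>
#include <map>
#include <tuple>
#include <cmath>

using namespace Rcpp;

static const double SQRT2 = 1.4142135623730951;

namespace {

struct FFT3 {
  int nx, ny, nz;
  R_xlen_t N;
  fftw_complex *buf;
  fftw_plan pf, pb;
  FFT3(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_) {
    N = (R_xlen_t)nx * ny * nz;
    buf = fftw_alloc_complex(N);
    // R arrays are column-major (x fastest); FFTW expects row-major, so the
    // dimensions are declared reversed. Plans are tuned once per grid shape
    // and cached for the life of the process.
    pf = fftw_plan_dft_3d(nz, ny, nx, buf, buf, FFTW_FORWARD, FFTW_MEASURE);
    pb = fftw_plan_dft_3d(nz, ny, nx, buf, buf, FFTW_BACKWARD, FFTW_MEASURE);
  }
  ~FFT3() {
    fftw_destroy_plan(pf);
    fftw_destroy_plan(pb);
    fftw_free(buf);
  }
};

FFT3 &fft_for(int nx, int ny, int nz) {
  static std::map<std::tuple<int, int, int>, FFT3 *> cache;
  auto key = std::make_tuple(nx, ny, nz);
  auto it = cache.find(key);
  if (it == cache.end())
    it = cache.emplace(key, new FFT3(nx, ny, nz)).first;
  return *(it->second);
}

inline double hfun(double p) {
  return 0.25 * (1.0 + p) * (1.0 + p) * (2.0 - p);
}

// DFT wavenumber (angular) for index i of n points spaced dx apart.
inline double wavenum(int i, int n, double dx) {
  int f = (i <= n / 2) ? i : i - n;
  return 2.0 * M_PI * f / (n * dx);
}

} // namespace

// Unnormalised 3D complex DFT matching stats::fft conventions
// (forward uses exp(-i k r); neither direction divides by N).
// [[Rcpp::export]]
ComplexVector cpp_fft3(ComplexVector z, IntegerVector dim, bool inverse) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  FFT3 &f = fft_for(nx, ny, nz);
  if (z.size() != f.N) stop("length of z does not match dim");
  std::memcpy(f.buf, &(z[0]), sizeof(fftw_complex) * f.N);
  fftw_execute(inverse ? f.pb : f.pf);
  ComplexVector out(f.N);
  std::memcpy(&(out[0]), f.buf, sizeof(fftw_complex) * f.N);
  out.attr("dim") = dim;
  return out;
}

// Advance both order-parameter fields by nsteps steps of size dt.
// par must hold (internal units): M, kappa_B, epsilon, gamma, eta,
// alpha_S, alpha_V, S_target, V_target. v1, v2 are per-cell advection
// velocities (um/s). Returns the updated fields plus diagnostics.
// [[Rcpp::export]]
List cpp_run_segment(NumericVector phi1_, NumericVector phi2_,
                     IntegerVector dim, double dx, List par,
                     NumericVector v1, NumericVector v2,
                     int nsteps, double dt, bool dealias) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (phi1_.size() != N || phi2_.size() != N) stop("field size mismatch");

  const double M = par["M"], kB = par["kappa_B"], eps = par["epsilon"];
  const double gam = par["gamma"], eta = par["eta"];
  const double aS = par["alpha_S"], aV = par["alpha_V"];
  const double St = par["S_target"], Vt = par["V_target"];
  const double e2 = eps * eps, e4 = e2 * e2;
  const double dV = dx * dx * dx;
  const double cS = 3.0 * eps / (2.0 * SQRT2); // surface functional prefactor

  FFT3 &f = fft_for(nx, ny, nz);

  // wavenumber tables and implicit denominator
  std::vector<double> kx(nx), ky(ny), kz(nz);
  for (int i = 0; i < nx; ++i) kx[i] = wavenum(i, nx, dx);
  for (int j = 0; j < ny; ++j) ky[j] = wavenum(j, ny, dx);
  for (int k = 0; k < nz; ++k) kz[k] = wavenum(k, nz, dx);
  std::vector<double> k2(N), invden(N);
  std::vector<unsigned char> keep;
  if (dealias) keep.assign(N, 1);
  {
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          double kk = kx[i] * kx[i] + ky[j] * ky[j] + kz[k] * kz[k];
          k2[idx] = kk;
          invden[idx] = 1.0 / (1.0 + 2.0 * dt * M * kB * e4 * kk * kk);
          if (dealias) {
            bool ok = std::abs(kx[i]) <= (2.0 / 3.0) * M_PI / dx &&
                      std::abs(ky[j]) <= (2.0 / 3.0) * M_PI / dx &&
                      std::abs(kz[k]) <= (2.0 / 3.0) * M_PI / dx;
            keep[idx] = ok ? 1 : 0;
          }
        }
  }
  // index of the conjugate mode (-k), used to unpack |phi_hat_i|^2 from the
  // packed transform when accumulating the Parseval surface integral
  std::vector<R_xlen_t> rev(N);
  {
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      int rk = (nz - k) % nz;
      for (int j = 0; j < ny; ++j) {
        int rj = (ny - j) % ny;
        for (int i = 0; i < nx; ++i, ++idx) {
          int ri = (nx - i) % nx;
          rev[idx] = (R_xlen_t)ri + nx * ((R_xlen_t)rj + (R_xlen_t)ny * rk);
        }
      }
    }
  }

  std::vector<double> p1(phi1_.begin(), phi1_.end());
  std::vector<double> p2(phi2_.begin(), phi2_.end());
  std::vector<double> lap1(N), lap2(N), lg1(N), lg2(N), h1(N), h2(N);
  std::vector<double> lh1, lh2, adv1, adv2;
  const bool need_adh = (eta != 0.0);
  if (need_adh) { lh1.assign(N, 0.0); lh2.assign(N, 0.0); }
  bool movex = (v1[0] != 0.0 || v2[0] != 0.0);
  bool movey = (v1[1] != 0.0 || v2[1] != 0.0);
  bool movez = (v1[2] != 0.0 || v2[2] != 0.0);
  const bool need_adv = movex || movey || movez;
  if (need_adv) { adv1.assign(N, 0.0); adv2.assign(N, 0.0); }

  std::vector<fftw_complex> zst(N); // spectral state: FFT(p1 + i p2)
  for (R_xlen_t q = 0; q < N; ++q) { f.buf[q][0] = p1[q]; f.buf[q][1] = p2[q]; }
  fftw_execute(f.pf);
  std::memcpy(zst.data(), f.buf, sizeof(fftw_complex) * N);

  const double inorm = 1.0 / (double)N;
  double S1 = NA_REAL, S2 = NA_REAL, V1 = NA_REAL, V2 = NA_REAL;
  double maxabs = 0.0;
  int done = 0;
  bool finite = true;

  auto parseval_S = [&](double &s1o, double &s2o) {
    double a1 = 0.0, a2 = 0.0;
    for (R_xlen_t q = 0; q < N; ++q) {
      double ar = zst[q][0], ai = zst[q][1];
      double br = zst[rev[q]][0], bi = zst[rev[q]][1];
      double f1r = 0.5 * (ar + br), f1i = 0.5 * (ai - bi);
      double f2r = 0.5 * (ai + bi), f2i = -0.5 * (ar - br);
      a1 += k2[q] * (f1r * f1r + f1i * f1i);
      a2 += k2[q] * (f2r * f2r + f2i * f2i);
    }
    // Parseval: sum_r |grad phi|^2 = (1/N) sum_k k^2 |phi_hat_k|^2
    s1o = cS * dV * inorm * a1;
    s2o = cS * dV * inorm * a2;
  };

  // Constants of the penalty (constraint) terms. Their relaxation rates at
  // the reference coefficients are of order 1e5 1/s -- far stiffer than any
  // practical dt -- so they are handled by operator splitting: per step the
  // two-scalar error dynamics dE/dt = -A E (A = overlap Gram matrix of the
  // two constraint forces, a contraction) is solved in closed form over dt,
  // and the field update reaching the relaxed errors is found by a 2D
  // Newton iteration on the exact polynomial response of S and V along the
  // constraint force directions.
  const double csS = 3.0 * SQRT2 * M * eps * aS; // surface-force coefficient
  const double cv = 1.5 * M * aV;                // volume-force coefficient
  const double gS = (3.0 / SQRT2) * eps;         // dS/dphi = -gS * lap(phi)

  // One constraint substep for one cell. The update direction is the span
  // of the two constraint forces, U1 = -lap(phi) (surface) and
  // U2 = 1 - phi^2 (volume). Along phi' = phi + a U1 + b U2, S[phi'] is an
  // exact quadratic and V[phi'] an exact cubic polynomial in (a, b), so the
  // amplitudes that land the constraints on their linearly relaxed values
  // are found by a scalar 2D Newton iteration -- no shape-frozen impulse
  // overshoot. `gip` are the six gradient inner products
  // <grad x, grad y> for x,y in {phi, U1, U2} (order: pp, p1, p2, 11, 12,
  // 22), computed spectrally by the caller.
  auto penalty_substep = [&](std::vector<double> &p, std::vector<double> &lap,
                             double S, double V, const double *gip) {
    const double cSf = 3.0 * eps / (2.0 * SQRT2);
    // local moments for the volume polynomial
    double m1 = 0, m2 = 0, q11 = 0, q12 = 0, q22 = 0;
    double c111 = 0, c112 = 0, c122 = 0, c222 = 0;
    double Qn = 0, Rn = 0, Pn = 0;
    for (R_xlen_t q = 0; q < N; ++q) {
      double u1 = -lap[q];
      double u2 = 1.0 - p[q] * p[q];
      double hp = 0.75 * u2;        // h'(phi)
      double hpp = -1.5 * p[q];     // h''(phi)
      m1 += hp * u1;       m2 += hp * u2;
      q11 += hpp * u1 * u1; q12 += hpp * u1 * u2; q22 += hpp * u2 * u2;
      c111 += u1 * u1 * u1; c112 += u1 * u1 * u2;
      c122 += u1 * u2 * u2; c222 += u2 * u2 * u2;
      Qn += u1 * u1; Rn += u2 * u2; Pn += u1 * u2;
    }
    m1 *= dV; m2 *= dV; q11 *= dV; q12 *= dV; q22 *= dV;
    c111 *= dV; c112 *= dV; c122 *= dV; c222 *= dV;
    Qn *= dV; Rn *= dV; Pn *= dV;
    // degenerate (interface-free) field: nothing to constrain
    if (Qn < 1e-8 && Rn < 1e-8) return;

    // linear relaxation of the scalar errors over dt gives the substep's
    // target: u_end = exp(-A dt) u0 (A = overlap matrix of the two forces)
    double A11 = gS * csS * Qn, A12 = gS * cv * Pn;
    double A21 = 0.75 * csS * Pn, A22 = 0.75 * cv * Rn;
    double uS = St - S, uV = Vt - V;
    {
      // closed-form u_end = exp(-A dt) u0; A is congruent to a positive
      // semidefinite Gram matrix, so its eigenvalues are real and >= 0
      double tr = A11 + A22, det = A11 * A22 - A12 * A21;
      double disc = std::sqrt(std::max(tr * tr - 4.0 * det, 0.0));
      double l1 = 0.5 * (tr - disc), l2 = 0.5 * (tr + disc);
      double e1 = std::exp(-std::max(l1, 0.0) * dt);
      double e2 = std::exp(-std::max(l2, 0.0) * dt);
      double E11, E12, E21, E22;
      if (disc > 1e-12 * std::max(1.0, tr)) {
        double w = 1.0 / (l2 - l1);
        E11 = w * (e1 * (l2 - A11) + e2 * (A11 - l1));
        E22 = w * (e1 * (l2 - A22) + e2 * (A22 - l1));
        E12 = w * (e2 - e1) * A12;
        E21 = w * (e2 - e1) * A21;
      } else {
        double lm = 0.5 * tr, em = std::exp(-lm * dt);
        E11 = em * (1.0 - (A11 - lm) * dt);
        E22 = em * (1.0 - (A22 - lm) * dt);
        E12 = em * (-A12 * dt);
        E21 = em * (-A21 * dt);
      }
      double nS = E11 * uS + E12 * uV;
      double nV = E21 * uS + E22 * uV;
      // bound the per-step constraint move so a far-off-target initial
      // state walks to the constraint manifold over many steps instead of
      // demanding one giant (trust-region-violating) shape update; at the
      // stiff reference coefficients near-target states still project in
      // a single step
      double capS = 0.02 * std::max(St, std::abs(S));
      double capV = 0.02 * std::max(Vt, std::abs(V));
      double mS = uS - nS, mV = uV - nV;
      if (mS > capS) mS = capS; else if (mS < -capS) mS = -capS;
      if (mV > capV) mV = capV; else if (mV < -capV) mV = -capV;
      uS -= mS; uV -= mV;
    }
    double S_goal = St - uS, V_goal = Vt - uV;

    // Newton on the exact polynomial responses
    // S(a,b) = S + cSf (2a g_p1 + 2b g_p2 + a^2 g_11 + 2ab g_12 + b^2 g_22)
    // V(a,b) = V + a m1 + b m2 + (a^2 q11 + 2ab q12 + b^2 q22)/2
    //          - (a^3 c111 + 3a^2 b c112 + 3ab^2 c122 + b^3 c222)/4
    double a = 0.0, b = 0.0;
    const double sclS = std::max(1.0, std::abs(S)), sclV = std::max(1.0, std::abs(V));
    bool okN = false;
    for (int it = 0; it < 50; ++it) {
      double Sab = S + cSf * (2 * a * gip[1] + 2 * b * gip[2] + a * a * gip[3] +
                              2 * a * b * gip[4] + b * b * gip[5]);
      double Vab = V + a * m1 + b * m2 +
                   0.5 * (a * a * q11 + 2 * a * b * q12 + b * b * q22) -
                   0.25 * (a * a * a * c111 + 3 * a * a * b * c112 +
                           3 * a * b * b * c122 + b * b * b * c222);
      double rS = Sab - S_goal, rV = Vab - V_goal;
      if (std::abs(rS) < 1e-10 * sclS && std::abs(rV) < 1e-10 * sclV) {
        okN = true;
        break;
      }
      double J11 = cSf * (2 * gip[1] + 2 * a * gip[3] + 2 * b * gip[4]);
      double J12 = cSf * (2 * gip[2] + 2 * a * gip[4] + 2 * b * gip[5]);
      double J21 = m1 + a * q11 + b * q12 -
                   0.25 * (3 * a * a * c111 + 6 * a * b * c112 + 3 * b * b * c122);
      double J22 = m2 + a * q12 + b * q22 -
                   0.25 * (3 * a * a * c112 + 6 * a * b * c122 + 3 * b * b * c222);
      double det = J11 * J22 - J12 * J21;
      if (det == 0.0 || !std::isfinite(det)) break;
      double da = -(rS * J22 - rV * J12) / det;
      double db = -(J11 * rV - J21 * rS) / det;
      // trust region: the polynomial model is only meaningful for small
      // field updates
      double cap = 0.2;
      double amax = std::abs(da) * std::sqrt(Qn / dV / (double)N);
      double bmax = std::abs(db);
      double sc = 1.0;
      if (amax > cap) sc = std::min(sc, cap / amax);
      if (bmax > cap) sc = std::min(sc, cap / bmax);
      a += sc * da;
      b += sc * db;
    }
    if (!okN) {
      // accept a partial correction if it at least halves the residual;
      // otherwise leave the field for the next step to retry
      double Sab = S + cSf * (2 * a * gip[1] + 2 * b * gip[2] + a * a * gip[3] +
                              2 * a * b * gip[4] + b * b * gip[5]);
      double Vab = V + a * m1 + b * m2 +
                   0.5 * (a * a * q11 + 2 * a * b * q12 + b * b * q22) -
                   0.25 * (a * a * a * c111 + 3 * a * a * b * c112 +
                           3 * a * b * b * c122 + b * b * b * c222);
      double r_now = std::abs(Sab - S_goal) / sclS + std::abs(Vab - V_goal) / sclV;
      double r_0 = std::abs(S - S_goal) / sclS + std::abs(V - V_goal) / sclV;
      if (!(std::isfinite(r_now) && r_now < 0.5 * r_0)) return;
    }
    for (R_xlen_t q = 0; q < N; ++q)
      p[q] += a * (-lap[q]) + b * (1.0 - p[q] * p[q]);
  };

  // Each pass applies the constraint projection to the current state and
  // then one semi-implicit update; the extra final pass leaves the returned
  // state on the constraint manifold (that is the state observers see).
  for (int step = 0; step <= nsteps; ++step) {
    // Laplacians of both fields
    for (R_xlen_t q = 0; q < N; ++q) {
      f.buf[q][0] = -k2[q] * zst[q][0];
      f.buf[q][1] = -k2[q] * zst[q][1];
    }
    fftw_execute(f.pb);
    for (R_xlen_t q = 0; q < N; ++q) {
      lap1[q] = f.buf[q][0] * inorm;
      lap2[q] = f.buf[q][1] * inorm;
    }

    // surface (Parseval) and volume of each cell, then the constraint
    // substep; afterwards the spectral state and Laplacians are refreshed
    parseval_S(S1, S2);
    V1 = 0.0; V2 = 0.0;
    for (R_xlen_t q = 0; q < N; ++q) {
      V1 += hfun(p1[q]);
      V2 += hfun(p2[q]);
    }
    V1 *= dV; V2 *= dV;
    if (aS != 0.0 || aV != 0.0) {
      // gradient inner products of {phi, U1=-lap phi, U2=1-phi^2} per cell,
      // via <grad x, grad y> = (dV/N) sum_k k^2 Re(conj(x_hat) y_hat) with
      // U1_hat = k^2 phi_hat; om transforms packed as om1 + i om2
      for (R_xlen_t q = 0; q < N; ++q) {
        f.buf[q][0] = 1.0 - p1[q] * p1[q];
        f.buf[q][1] = 1.0 - p2[q] * p2[q];
      }
      fftw_execute(f.pf);
      double gip1[6] = {0, 0, 0, 0, 0, 0}, gip2[6] = {0, 0, 0, 0, 0, 0};
      for (R_xlen_t q = 0; q < N; ++q) {
        R_xlen_t r = rev[q];
        double ar = zst[q][0], ai = zst[q][1];
        double br = zst[r][0], bi = zst[r][1];
        double f1r = 0.5 * (ar + br), f1i = 0.5 * (ai - bi);
        double f2r = 0.5 * (ai + bi), f2i = -0.5 * (ar - br);
        double cr = f.buf[q][0], ci = f.buf[q][1];
        double dr = f.buf[r][0], di = f.buf[r][1];
        double o1r = 0.5 * (cr + dr), o1i = 0.5 * (ci - di);
        double o2r = 0.5 * (ci + di), o2i = -0.5 * (cr - dr);
        double kk = k2[q], k4 = kk * kk, k6 = k4 * kk;
        double p1sq = f1r * f1r + f1i * f1i;
        double p2sq = f2r * f2r + f2i * f2i;
        gip1[1] += k4 * p1sq;
        gip1[3] += k6 * p1sq;
        gip1[2] += kk * (f1r * o1r + f1i * o1i);
        gip1[4] += k4 * (f1r * o1r + f1i * o1i);
        gip1[5] += kk * (o1r * o1r + o1i * o1i);
        gip2[1] += k4 * p2sq;
        gip2[3] += k6 * p2sq;
        gip2[2] += kk * (f2r * o2r + f2i * o2i);
        gip2[4] += k4 * (f2r * o2r + f2i * o2i);
        gip2[5] += kk * (o2r * o2r + o2i * o2i);
      }
      for (int j = 1; j < 6; ++j) {
        gip1[j] *= dV * inorm;
        gip2[j] *= dV * inorm;
      }
      penalty_substep(p1, lap1, S1, V1, gip1);
      penalty_substep(p2, lap2, S2, V2, gip2);
      for (R_xlen_t q = 0; q < N; ++q) {
        f.buf[q][0] = p1[q];
        f.buf[q][1] = p2[q];
      }
      fftw_execute(f.pf);
      std::memcpy(zst.data(), f.buf, sizeof(fftw_complex) * N);
      for (R_xlen_t q = 0; q < N; ++q) {
        f.buf[q][0] = -k2[q] * zst[q][0];
        f.buf[q][1] = -k2[q] * zst[q][1];
      }
      fftw_execute(f.pb);
      for (R_xlen_t q = 0; q < N; ++q) {
        lap1[q] = f.buf[q][0] * inorm;
        lap2[q] = f.buf[q][1] * inorm;
      }
    }

    if (step == nsteps) break;

    // advection term v . grad(phi), spectral derivatives
    if (need_adv) {
      std::fill(adv1.begin(), adv1.end(), 0.0);
      std::fill(adv2.begin(), adv2.end(), 0.0);
      for (int ax = 0; ax < 3; ++ax) {
        if (v1[ax] == 0.0 && v2[ax] == 0.0) continue;
        R_xlen_t idx = 0;
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i, ++idx) {
              double ka = (ax == 0) ? kx[i] : (ax == 1) ? ky[j] : kz[k];
              // multiply by i*ka
              f.buf[idx][0] = -ka * zst[idx][1];
              f.buf[idx][1] = ka * zst[idx][0];
            }
        fftw_execute(f.pb);
        double w1 = v1[ax], w2 = v2[ax];
        for (R_xlen_t q = 0; q < N; ++q) {
          adv1[q] += w1 * f.buf[q][0] * inorm;
          adv2[q] += w2 * f.buf[q][1] * inorm;
        }
      }
    }

    // h(phi) and lap(-phi+phi^3)
    for (R_xlen_t q = 0; q < N; ++q) {
      h1[q] = hfun(p1[q]);
      h2[q] = hfun(p2[q]);
      f.buf[q][0] = -p1[q] + p1[q] * p1[q] * p1[q];
      f.buf[q][1] = -p2[q] + p2[q] * p2[q] * p2[q];
    }
    fftw_execute(f.pf);
    for (R_xlen_t q = 0; q < N; ++q) {
      f.buf[q][0] *= -k2[q];
      f.buf[q][1] *= -k2[q];
    }
    fftw_execute(f.pb);
    for (R_xlen_t q = 0; q < N; ++q) {
      lg1[q] = f.buf[q][0] * inorm;
      lg2[q] = f.buf[q][1] * inorm;
    }

    if (need_adh) {
      for (R_xlen_t q = 0; q < N; ++q) {
        f.buf[q][0] = h1[q];
        f.buf[q][1] = h2[q];
      }
      fftw_execute(f.pf);
      for (R_xlen_t q = 0; q < N; ++q) {
        f.buf[q][0] *= -k2[q];
        f.buf[q][1] *= -k2[q];
      }
      fftw_execute(f.pb);
      for (R_xlen_t q = 0; q < N; ++q) {
        lh1[q] = f.buf[q][0] * inorm;
        lh2[q] = f.buf[q][1] * inorm;
      }
    }

    // explicit part of the right-hand side for both cells (the constraint
    // terms were applied in the splitting substep above)
    const double cb = 2.0 * M * kB;
    const double cg = 0.75 * M * gam, ce = 0.75 * M * eta;
    for (R_xlen_t q = 0; q < N; ++q) {
      double a = p1[q], b = p2[q];
      double oma = 1.0 - a * a, omb = 1.0 - b * b;
      double mu1 = -a + a * a * a - e2 * lap1[q];
      double mu2 = -b + b * b * b - e2 * lap2[q];
      double n1 = -cb * (3.0 * a * a - 1.0) * mu1 + cb * e2 * lg1[q]
                  - cg * oma * h2[q];
      double n2 = -cb * (3.0 * b * b - 1.0) * mu2 + cb * e2 * lg2[q]
                  - cg * omb * h1[q];
      if (need_adh) {
        n1 += ce * oma * lh2[q];
        n2 += ce * omb * lh1[q];
      }
      if (need_adv) {
        n1 -= adv1[q];
        n2 -= adv2[q];
      }
      f.buf[q][0] = n1;
      f.buf[q][1] = n2;
    }
    fftw_execute(f.pf);

    // semi-implicit update in Fourier space
    if (dealias) {
      for (R_xlen_t q = 0; q < N; ++q)
        if (!keep[q]) { f.buf[q][0] = 0.0; f.buf[q][1] = 0.0; }
    }
    for (R_xlen_t q = 0; q < N; ++q) {
      zst[q][0] = (zst[q][0] + dt * f.buf[q][0]) * invden[q];
      zst[q][1] = (zst[q][1] + dt * f.buf[q][1]) * invden[q];
    }
    std::memcpy(f.buf, zst.data(), sizeof(fftw_complex) * N);
    fftw_execute(f.pb);
    maxabs = 0.0;
    for (R_xlen_t q = 0; q < N; ++q) {
      p1[q] = f.buf[q][0] * inorm;
      p2[q] = f.buf[q][1] * inorm;
      double m = std::max(std::abs(p1[q]), std::abs(p2[q]));
      if (m > maxabs || m != m) maxabs = m; // NaN-propagating max
    }
    done = step + 1;
    if (!std::isfinite(maxabs)) { finite = false; break; }
  }

  // final-state diagnostics
  if (finite) {
    for (R_xlen_t q = 0; q < N; ++q) { f.buf[q][0] = p1[q]; f.buf[q][1] = p2[q]; }
    fftw_execute(f.pf);
    std::memcpy(zst.data(), f.buf, sizeof(fftw_complex) * N);
    parseval_S(S1, S2);
    V1 = 0.0; V2 = 0.0;
    maxabs = 0.0;
    for (R_xlen_t q = 0; q < N; ++q) {
      V1 += hfun(p1[q]);
      V2 += hfun(p2[q]);
      double m = std::max(std::abs(p1[q]), std::abs(p2[q]));
      if (m > maxabs || m != m) maxabs = m;
    }
    V1 *= dV; V2 *= dV;
  }

  NumericVector out1(p1.begin(), p1.end()), out2(p2.begin(), p2.end());
  out1.attr("dim") = dim;
  out2.attr("dim") = dim;
  return List::create(_["phi1"] = out1, _["phi2"] = out2,
                      _["S"] = NumericVector::create(S1, S2),
                      _["V"] = NumericVector::create(V1, V2),
                      _["max_abs"] = maxabs, _["steps_done"] = done,
                      _["finite"] = finite);
}
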