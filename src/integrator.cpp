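#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Logistic gain g(V) = Gamma / (1 + exp(-a (V - h))) and its first two
// V-derivatives, written via the logistic s in (0,1) so all three are
// overflow-safe for any finite V.
static inline void gain3(double V, double Gam, double a, double h,
                         double &g, double &gp, double &gpp) {
  double s = 1.0 / (1.0 + std::exp(-a * (V - h)));
  g   = Gam * s;
  gp  = Gam * a * s * (1.0 - s);
  gpp = Gam * a * a * s * (1.0 - s) * (1.0 - 2.0 * s);
}

struct EiSystem {
  // theta ordering: [beta_e, beta_i, w_e, w_i, w_ee, w_ei, w_ie, w_ii]
  double be, bi, we, wi, wee, wei, wie, wii;
  double Ge, ae, he, Gi, ai, hi;      // fixed gain constants
  vec A, phi, wfreq;                  // Fourier amplitudes, phases, omega_n
  mat W;                              // [[wee,-wei],[wie,-wii]]
  vec Bv, wv;                         // diag(B), input weights
  bool wth, wx, wcross;
  int N;                              // harmonics

  double stim(double t) const {
    double I = 0.0;
    for (int n = 0; n < N; ++n) I += A(n) * std::cos(wfreq(n) * t + phi(n));
    return I;
  }
  // dI/dx, x = [A_1..A_N, phi_1..phi_N]
  rowvec stim_dx(double t) const {
    rowvec d(2 * N);
    for (int n = 0; n < N; ++n) {
      double c = std::cos(wfreq(n) * t + phi(n));
      double s = std::sin(wfreq(n) * t + phi(n));
      d(n)     = c;
      d(N + n) = -A(n) * s;
    }
    return d;
  }

  // Time derivative of the augmented state (state, dv/dtheta, dv/dx, cross).
  // The 8 cross-derivative slices are packed side by side into one
  // 2 x (2N*8) matrix (block k = columns [k*2N, (k+1)*2N)) so the common
  // linear part is applied in a single matrix operation.
  void rhs(double t, const vec &v, const mat &Sth, const mat &Sx,
           const mat &C, vec &dv, mat &dSth, mat &dSx, mat &dC) const {
    double g_e, gp_e, gpp_e, g_i, gp_i, gpp_i;
    gain3(v(0), Ge, ae, he, g_e, gp_e, gpp_e);
    gain3(v(1), Gi, ai, hi, g_i, gp_i, gpp_i);
    vec gv  = {g_e, g_i};
    vec gp  = {gp_e, gp_i};
    vec gpp = {gpp_e, gpp_i};
    double I = stim(t);

    vec brace = -v + W * gv + wv * I;
    dv = Bv % brace;

    if (wth) {
      mat core = -Sth + W * (Sth.each_col() % gp);
      dSth = core.each_col() % Bv;
      // forcing terms z_k, one per network parameter
      dSth(0, 0) += brace(0);
      dSth(1, 1) += brace(1);
      dSth(0, 2) += be * I;
      dSth(1, 3) += bi * I;
      dSth(0, 4) += be * g_e;
      dSth(0, 5) += -be * g_i;
      dSth(1, 6) += bi * g_e;
      dSth(1, 7) += -bi * g_i;
    }

    rowvec dIdx;
    mat GX, braceX;
    if (wx || wcross) {
      dIdx = stim_dx(t);
      GX = Sx.each_col() % gp;                       // G * Sx
      braceX = -Sx + W * GX + wv * dIdx;             // 2 x 2N
    }
    if (wx) dSx = braceX.each_col() % Bv;

    if (wcross) {
      const int nx = Sx.n_cols;
      // W G' diag(s_k) Sx for all k at once: row i of block k is
      // gpp(i) * Sth(i,k) * Sx.row(i)
      mat D(2, nx * 8);
      D.row(0) = vectorise(Sx.row(0).t() * (gpp(0) * Sth.row(0)), 0).t();
      D.row(1) = vectorise(Sx.row(1).t() * (gpp(1) * Sth.row(1)), 0).t();
      mat tmp = -C + W * (C.each_col() % gp) + W * D;
      dC = tmp.each_col() % Bv;
      // forcing terms Z_k
      dC(0, span(0, nx - 1)) += braceX.row(0);
      dC(1, span(nx, 2 * nx - 1)) += braceX.row(1);
      dC(0, span(2 * nx, 3 * nx - 1)) += be * dIdx;
      dC(1, span(3 * nx, 4 * nx - 1)) += bi * dIdx;
      dC(0, span(4 * nx, 5 * nx - 1)) += be * GX.row(0);
      dC(0, span(5 * nx, 6 * nx - 1)) += -be * GX.row(1);
      dC(1, span(6 * nx, 7 * nx - 1)) += bi * GX.row(0);
      dC(1, span(7 * nx, 8 * nx - 1)) += -bi * GX.row(1);
    }
  }
};

// Fixed-step classical RK4 on the augmented system. Sensitivity blocks start
// at zero, except that the dv/dtheta block can be given a nonzero initial
// value Sth0 (2 x 8; e.g. the parameter-sensitivity of the baseline
// equilibrium used as the initial state). The state starts at v0.
// [[Rcpp::export]]
Rcpp::List ei_integrate(Rcpp::NumericVector theta, Rcpp::NumericVector gains,
                        Rcpp::NumericVector A_, Rcpp::NumericVector phi_,
                        double f_base, double T, double dt,
                        Rcpp::NumericVector v0,
                        bool want_dtheta, bool want_dx, bool want_cross,
                        Rcpp::NumericMatrix Sth0) {
  EiSystem sys;
  sys.be = theta[0]; sys.bi = theta[1];
  sys.we = theta[2]; sys.wi = theta[3];
  sys.wee = theta[4]; sys.wei = theta[5];
  sys.wie = theta[6]; sys.wii = theta[7];
  sys.Ge = gains[0]; sys.ae = gains[1]; sys.he = gains[2];
  sys.Gi = gains[3]; sys.ai = gains[4]; sys.hi = gains[5];
  sys.A = vec(A_.begin(), A_.size());
  sys.phi = vec(phi_.begin(), phi_.size());
  sys.N = A_.size();
  sys.wfreq = vec(sys.N);
  for (int n = 0; n < sys.N; ++n)
    sys.wfreq(n) = 2.0 * M_PI * (n + 1) * f_base;
  sys.W = { {sys.wee, -sys.wei}, {sys.wie, -sys.wii} };
  sys.Bv = {sys.be, sys.bi};
  sys.wv = {sys.we, sys.wi};
  if (want_cross && !(want_dtheta && want_dx))
    Rcpp::stop("cross sensitivities require both first-order blocks");
  sys.wth = want_dtheta; sys.wx = want_dx; sys.wcross = want_cross;

  const int nx = 2 * sys.N;
  const int n_steps = (int)std::lround(T / dt);
  if (n_steps < 1) Rcpp::stop("T/dt must be at least 1 step");

  vec v = {v0[0], v0[1]};
  mat Sth(2, 8, fill::zeros), Sx(2, nx, fill::zeros);
  if (want_dtheta && Sth0.nrow() == 2 && Sth0.ncol() == 8)
    Sth = mat(Sth0.begin(), 2, 8);
  mat C(2, nx * 8, fill::zeros);

  mat Vout(n_steps + 1, 2);
  mat SthE, SthI, SxE, SxI, CE, CI;
  if (want_dtheta) { SthE.set_size(n_steps + 1, 8); SthI.set_size(n_steps + 1, 8); }
  if (want_dx)     { SxE.set_size(n_steps + 1, nx); SxI.set_size(n_steps + 1, nx); }
  if (want_cross)  { CE.set_size(n_steps + 1, nx * 8); CI.set_size(n_steps + 1, nx * 8); }

  vec k1v(2), k2v(2), k3v(2), k4v(2);
  mat k1th, k2th, k3th, k4th, k1x, k2x, k3x, k4x;
  mat k1c, k2c, k3c, k4c;
  if (want_dtheta) { k1th.set_size(2, 8); k2th = k1th; k3th = k1th; k4th = k1th; }
  if (want_dx)     { k1x.set_size(2, nx); k2x = k1x; k3x = k1x; k4x = k1x; }
  if (want_cross)  { k1c.set_size(2, nx * 8); k2c = k1c; k3c = k1c; k4c = k1c; }

  auto store = [&](int i) {
    Vout(i, 0) = v(0); Vout(i, 1) = v(1);
    if (sys.wth) { SthE.row(i) = Sth.row(0); SthI.row(i) = Sth.row(1); }
    if (sys.wx)  { SxE.row(i) = Sx.row(0);  SxI.row(i) = Sx.row(1); }
    if (sys.wcross) {
      CE.row(i) = C.row(0);
      CI.row(i) = C.row(1);
    }
  };
  store(0);

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    sys.rhs(t, v, Sth, Sx, C, k1v, k1th, k1x, k1c);
    sys.rhs(t + 0.5 * dt, v + 0.5 * dt * k1v,
            sys.wth ? mat(Sth + 0.5 * dt * k1th) : Sth,
            sys.wx ? mat(Sx + 0.5 * dt * k1x) : Sx,
            sys.wcross ? mat(C + 0.5 * dt * k1c) : C,
            k2v, k2th, k2x, k2c);
    sys.rhs(t + 0.5 * dt, v + 0.5 * dt * k2v,
            sys.wth ? mat(Sth + 0.5 * dt * k2th) : Sth,
            sys.wx ? mat(Sx + 0.5 * dt * k2x) : Sx,
            sys.wcross ? mat(C + 0.5 * dt * k2c) : C,
            k3v, k3th, k3x, k3c);
    sys.rhs(t + dt, v + dt * k3v,
            sys.wth ? mat(Sth + dt * k3th) : Sth,
            sys.wx ? mat(Sx + dt * k3x) : Sx,
            sys.wcross ? mat(C + dt * k3c) : C,
            k4v, k4th, k4x, k4c);

    v += (dt / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    if (sys.wth)   Sth += (dt / 6.0) * (k1th + 2.0 * k2th + 2.0 * k3th + k4th);
    if (sys.wx)    Sx  += (dt / 6.0) * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    if (sys.wcross) C  += (dt / 6.0) * (k1c + 2.0 * k2c + 2.0 * k3c + k4c);

    if (!v.is_finite())
      Rcpp::stop("integration failure: non-finite state at t = %f", (i + 1) * dt);
    if (sys.wth && !Sth.is_finite())
      Rcpp::stop("integration failure: non-finite parameter sensitivity at t = %f",
                 (i + 1) * dt);
    if (sys.wx && !Sx.is_finite())
      Rcpp::stop("integration failure: non-finite stimulus sensitivity at t = %f",
                 (i + 1) * dt);
    if (sys.wcross && !C.is_finite())
      Rcpp::stop("integration failure: non-finite cross sensitivity at t = %f",
                 (i + 1) * dt);
    store(i + 1);
  }

  vec times = regspace(0, n_steps) * dt;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("times") = times,
      Rcpp::Named("V") = Vout);
  if (want_dtheta) { out["dVe_dtheta"] = SthE; out["dVi_dtheta"] = SthI; }
  if (want_dx)     { out["dVe_dx"] = SxE;      out["dVi_dx"] = SxI; }
  if (want_cross)  { out["d2Ve_dxdtheta"] = CE; out["d2Vi_dxdtheta"] = CI; }
  return out;
}

// Whole-dataset spike-train log-likelihood (and analytic gradient) computed
// in one pass: for each stimulus the state (and, for the gradient, the
// dv/dtheta block seeded with Sth0) is integrated by the same RK4 scheme,
// while the trapezoid integral of the rate and the rate at spike times
// (linear interpolation within a step) are accumulated without storing the
// trajectory. All pairs must share f_base, T and dt.
// [[Rcpp::export]]
Rcpp::List ei_dataset_loglik(Rcpp::NumericVector theta, Rcpp::NumericVector gains,
                             Rcpp::NumericMatrix Amat, Rcpp::NumericMatrix Phimat,
                             double f_base, double T, double dt,
                             Rcpp::List spikes, Rcpp::NumericVector v0,
                             Rcpp::NumericMatrix Sth0, bool want_grad) {
  const double floor_rate = 1e-9;
  EiSystem sys;
  sys.be = theta[0]; sys.bi = theta[1];
  sys.we = theta[2]; sys.wi = theta[3];
  sys.wee = theta[4]; sys.wei = theta[5];
  sys.wie = theta[6]; sys.wii = theta[7];
  sys.Ge = gains[0]; sys.ae = gains[1]; sys.he = gains[2];
  sys.Gi = gains[3]; sys.ai = gains[4]; sys.hi = gains[5];
  sys.W = { {sys.wee, -sys.wei}, {sys.wie, -sys.wii} };
  sys.Bv = {sys.be, sys.bi};
  sys.wv = {sys.we, sys.wi};
  sys.wth = want_grad; sys.wx = false; sys.wcross = false;
  sys.N = Amat.ncol();
  sys.wfreq = vec(sys.N);
  for (int n = 0; n < sys.N; ++n)
    sys.wfreq(n) = 2.0 * M_PI * (n + 1) * f_base;

  const int M = Amat.nrow();
  const int n_steps = (int)std::lround(T / dt);
  mat Sth_init(2, 8, fill::zeros);
  if (want_grad && Sth0.nrow() == 2 && Sth0.ncol() == 8)
    Sth_init = mat(Sth0.begin(), 2, 8);

  auto rate_of = [&](const vec &vv) {
    double g, gp, gpp;
    gain3(vv(0), sys.Ge, sys.ae, sys.he, g, gp, gpp);
    return g;
  };
  auto drate_of = [&](const vec &vv, const mat &S) {
    double g, gp, gpp;
    gain3(vv(0), sys.Ge, sys.ae, sys.he, g, gp, gpp);
    return rowvec(gp * S.row(0));
  };

  double ll = 0.0;
  vec grad(8, fill::zeros);
  mat Sx0(2, 0), dS;
  mat C0(2, 0), dC;
  vec k1v(2), k2v(2), k3v(2), k4v(2);
  mat k1th(2, 8), k2th(2, 8), k3th(2, 8), k4th(2, 8);

  for (int m = 0; m < M; ++m) {
    sys.A = vec(sys.N); sys.phi = vec(sys.N);
    for (int n = 0; n < sys.N; ++n) {
      sys.A(n) = Amat(m, n);
      sys.phi(n) = Phimat(m, n);
    }
    Rcpp::NumericVector spk = spikes[m];
    int n_spk = spk.size(), si = 0;

    vec v = {v0[0], v0[1]};
    mat Sth = Sth_init;
    double r_prev = rate_of(v);
    rowvec dr_prev = want_grad ? drate_of(v, Sth) : rowvec();
    double int_r = 0.0;
    rowvec int_dr(8, fill::zeros);

    for (int i = 0; i < n_steps; ++i) {
      double t = i * dt;
      sys.rhs(t, v, Sth, Sx0, C0, k1v, k1th, dS, dC);
      sys.rhs(t + 0.5 * dt, v + 0.5 * dt * k1v,
              want_grad ? mat(Sth + 0.5 * dt * k1th) : Sth, Sx0, C0,
              k2v, k2th, dS, dC);
      sys.rhs(t + 0.5 * dt, v + 0.5 * dt * k2v,
              want_grad ? mat(Sth + 0.5 * dt * k2th) : Sth, Sx0, C0,
              k3v, k3th, dS, dC);
      sys.rhs(t + dt, v + dt * k3v,
              want_grad ? mat(Sth + dt * k3th) : Sth, Sx0, C0,
              k4v, k4th, dS, dC);
      v += (dt / 6.0) * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      if (want_grad) Sth += (dt / 6.0) * (k1th + 2.0 * k2th + 2.0 * k3th + k4th);
      if (!v.is_finite())
        Rcpp::stop("integration failure: non-finite state at t = %f (pair %d)",
                   (i + 1) * dt, m + 1);

      double r_cur = rate_of(v);
      int_r += 0.5 * dt * (r_prev + r_cur);
      rowvec dr_cur;
      if (want_grad) {
        dr_cur = drate_of(v, Sth);
        int_dr += 0.5 * dt * (dr_prev + dr_cur);
      }
      double t1 = (i + 1) * dt;
      if (i == n_steps - 1) t1 = T + 1e-9;   // absorb rounding at the window end
      while (si < n_spk && spk[si] <= t1) {
        double w1 = (spk[si] - t) / dt;
        double rk = (1.0 - w1) * r_prev + w1 * r_cur;
        if (rk < floor_rate) rk = floor_rate;
        ll += std::log(rk);
        if (want_grad) grad += ((1.0 - w1) * dr_prev + w1 * dr_cur).t() / rk;
        ++si;
      }
      r_prev = r_cur;
      if (want_grad) dr_prev = dr_cur;
    }
    ll -= int_r;
    if (want_grad) grad -= int_dr.t();
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("ll") = ll);
  if (want_grad) out["grad"] = Rcpp::NumericVector(grad.begin(), grad.end());
  return out;
}

// RK4 for an arbitrary stimulus given as values on the half-step grid:
// Iv has length 2*n_steps + 1 (values at t_i and t_i + dt/2). Used for
// non-Fourier demo inputs such as the square wave.
// [[Rcpp::export]]
Rcpp::List ei_integrate_tabular(Rcpp::NumericVector theta, Rcpp::NumericVector gains,
                                Rcpp::NumericVector Iv, double T, double dt,
                                Rcpp::NumericVector v0) {
  double be = theta[0], bi = theta[1], we = theta[2], wi = theta[3];
  double wee = theta[4], wei = theta[5], wie = theta[6], wii = theta[7];
  double Ge = gains[0], ae = gains[1], he = gains[2];
  double Gi = gains[3], ai = gains[4], hi = gains[5];
  mat W = { {wee, -wei}, {wie, -wii} };
  vec Bv = {be, bi}, wv = {we, wi};
  const int n_steps = (int)std::lround(T / dt);
  if (Iv.size() != 2 * n_steps + 1)
    Rcpp::stop("stimulus table must have 2*n_steps + 1 values");

  auto f = [&](const vec &v, double I) {
    double g_e, gp_e, gpp_e, g_i, gp_i, gpp_i;
    gain3(v(0), Ge, ae, he, g_e, gp_e, gpp_e);
    gain3(v(1), Gi, ai, hi, g_i, gp_i, gpp_i);
    vec gv = {g_e, g_i};
    return vec(Bv % (-v + W * gv + wv * I));
  };

  vec v = {v0[0], v0[1]};
  mat Vout(n_steps + 1, 2);
  Vout(0, 0) = v(0); Vout(0, 1) = v(1);
  for (int i = 0; i < n_steps; ++i) {
    double I0 = Iv[2 * i], Ih = Iv[2 * i + 1], I1 = Iv[2 * i + 2];
    vec k1 = f(v, I0);
    vec k2 = f(v + 0.5 * dt * k1, Ih);
    vec k3 = f(v + 0.5 * dt * k2, Ih);
    vec k4 = f(v + dt * k3, I1);
    v += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!v.is_finite())
      Rcpp::stop("integration failure: non-finite state at t = %f", (i + 1) * dt);
    Vout(i + 1, 0) = v(0); Vout(i + 1, 1) = v(1);
  }
  vec times = regspace(0, n_steps) * dt;
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("V") = Vout);
}
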