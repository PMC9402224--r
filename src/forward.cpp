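// Bilinear neural state equation and balloon-Windkessel observation model.
// Fixed-step classical RK4 throughout; inputs u are piecewise constant over
// each microtime bin, so the effective coupling matrix is cached per distinct
// input pattern (the task design is a boxcar: only a handful of patterns
// occur). Hot loops use raw arrays: the state dimension is tiny (6 regions),
// so per-step allocation overhead would dominate otherwise.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Pattern id for a binary 2-row input column: 0 rest, 1 low, 2 high, 3 both.
static inline int pattern_id(const mat& u, uword t) {
  return (u(0, t) != 0.0 ? 1 : 0) + (u(1, t) != 0.0 ? 2 : 0);
}

// y = M x + d, column-major M (n x n)
static inline void matvec_add(const double* M, const double* d,
                              const double* x, double* y, int n) {
  for (int i = 0; i < n; ++i) y[i] = d[i];
  for (int j = 0; j < n; ++j) {
    const double xj = x[j];
    const double* mj = M + (size_t)j * n;
    for (int i = 0; i < n; ++i) y[i] += mj[i] * xj;
  }
}

// Integrate dx/dt = (Aeff + u1*Blow + u2*Bhigh) x + C u from x0 with RK4.
// Returns n x T trajectory; column t is the state at time (t-1)*dt (x(0)=x0).
// [[Rcpp::export(name = ".integrate_neural_cpp")]]
arma::mat integrate_neural_cpp(const arma::mat& Aeff, const arma::mat& Blow,
                               const arma::mat& Bhigh, const arma::mat& C,
                               const arma::mat& u, double dt,
                               const arma::vec& x0) {
  const int n = (int)Aeff.n_rows;
  const uword T = u.n_cols;
  // per-pattern effective matrix and constant drive
  std::vector<std::vector<double>> M(4), d(4);
  std::vector<bool> have(4, false);
  mat x(n, T);
  std::vector<double> xc(x0.begin(), x0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int i = 0; i < n; ++i) x(i, 0) = xc[i];
  for (uword t = 0; t + 1 < T; ++t) {
    int p = pattern_id(u, t);
    if (!have[p]) {
      mat Mp = Aeff;
      if (p & 1) Mp += Blow;
      if (p & 2) Mp += Bhigh;
      vec dp = C * u.col(t);
      M[p].assign(Mp.begin(), Mp.end());
      d[p].assign(dp.begin(), dp.end());
      have[p] = true;
    }
    const double* Mp = M[p].data();
    const double* dp = d[p].data();
    matvec_add(Mp, dp, xc.data(), k1.data(), n);
    for (int i = 0; i < n; ++i) tmp[i] = xc[i] + 0.5 * dt * k1[i];
    matvec_add(Mp, dp, tmp.data(), k2.data(), n);
    for (int i = 0; i < n; ++i) tmp[i] = xc[i] + 0.5 * dt * k2[i];
    matvec_add(Mp, dp, tmp.data(), k3.data(), n);
    for (int i = 0; i < n; ++i) tmp[i] = xc[i] + dt * k3[i];
    matvec_add(Mp, dp, tmp.data(), k4.data(), n);
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      xc[i] += (dt / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(xc[i])) ok = false;
      x(i, t + 1) = xc[i];
    }
    if (!ok)
      Rcpp::stop("neural trajectory non-finite at microtime bin %d",
                 (int)(t + 2));
  }
  return x;
}

struct HemoState { double s, f, v, q; };

// Hemodynamic state is carried as (s, log f, v, q). Only inflow f needs the
// log parameterization: the signal equation can drive f through zero for
// sustained negative input, whereas v and q are repelled from zero whenever
// f > 0 (dv ~ f > 0 at v -> 0+, dq ~ f E/e0 > 0 at q -> 0+). tauInv = 1/tau,
// invAlpha = 1/alpha, lome = log(1-e0), e0Inv = 1/e0.
static inline HemoState hemo_deriv(const HemoState& h, double x, double kappa,
                                   double gamma, double tauInv,
                                   double invAlpha, double lome, double e0Inv,
                                   double eps) {
  HemoState d;
  const double f = std::exp(h.f);
  const double vexp = std::exp(invAlpha * std::log(h.v));
  d.s = eps * x - kappa * h.s - gamma * (f - 1.0);
  d.f = h.s / f;
  d.v = tauInv * (f - vexp);
  const double E = 1.0 - std::exp(lome / f);
  d.q = tauInv * (f * E * e0Inv - vexp * h.q / h.v);
  return d;
}

// Balloon-Windkessel stage. neural is n x T; x is interpolated linearly at
// RK4 half-steps. Output is percent signal change about 0 (the resting state
// s=0, f=v=q=1 maps to y=0 exactly).
// [[Rcpp::export(name = ".hemodynamics_cpp")]]
arma::mat hemodynamics_cpp(const arma::mat& neural, double dt,
                           const arma::vec& kappa, const arma::vec& gamma,
                           const arma::vec& tau, const arma::vec& alpha,
                           const arma::vec& e0, const arma::vec& v0,
                           const arma::vec& eps) {
  const uword n = neural.n_rows, T = neural.n_cols;
  mat y(n, T);
  for (uword r = 0; r < n; ++r) {
    const double ka = kappa[r], ga = gamma[r], taInv = 1.0 / tau[r],
                 invAl = 1.0 / alpha[r], E0 = e0[r], V0 = v0[r], ep = eps[r];
    const double lome = std::log(1.0 - E0), e0Inv = 1.0 / E0;
    const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
    HemoState h = {0.0, 0.0, 1.0, 1.0};   // s, log f, v, q at rest
    y(r, 0) = 0.0;
    for (uword t = 0; t + 1 < T; ++t) {
      double xa = neural(r, t), xb = neural(r, t + 1), xm = 0.5 * (xa + xb);
      HemoState d1 = hemo_deriv(h, xa, ka, ga, taInv, invAl, lome, e0Inv, ep);
      HemoState h2 = {h.s + 0.5 * dt * d1.s, h.f + 0.5 * dt * d1.f,
                      h.v + 0.5 * dt * d1.v, h.q + 0.5 * dt * d1.q};
      HemoState d2 = hemo_deriv(h2, xm, ka, ga, taInv, invAl, lome, e0Inv, ep);
      HemoState h3 = {h.s + 0.5 * dt * d2.s, h.f + 0.5 * dt * d2.f,
                      h.v + 0.5 * dt * d2.v, h.q + 0.5 * dt * d2.q};
      HemoState d3 = hemo_deriv(h3, xm, ka, ga, taInv, invAl, lome, e0Inv, ep);
      HemoState h4 = {h.s + dt * d3.s, h.f + dt * d3.f, h.v + dt * d3.v,
                      h.q + dt * d3.q};
      HemoState d4 = hemo_deriv(h4, xb, ka, ga, taInv, invAl, lome, e0Inv, ep);
      h.s += (dt / 6.0) * (d1.s + 2.0 * d2.s + 2.0 * d3.s + d4.s);
      h.f += (dt / 6.0) * (d1.f + 2.0 * d2.f + 2.0 * d3.f + d4.f);
      h.v += (dt / 6.0) * (d1.v + 2.0 * d2.v + 2.0 * d3.v + d4.v);
      h.q += (dt / 6.0) * (d1.q + 2.0 * d2.q + 2.0 * d3.q + d4.q);
      if (!std::isfinite(h.s) || !std::isfinite(h.f) ||
          !(h.v > 0.0) || !(h.q > 0.0))
        Rcpp::stop(
            "hemodynamic state non-positive or non-finite at microtime bin %d",
            (int)(t + 2));
      y(r, t + 1) =
          100.0 * V0 *
          (k1 * (1.0 - h.q) + k2 * (1.0 - h.q / h.v) + k3 * (1.0 - h.v));
    }
  }
  return y;
}

// ---- fast combined path: joint neural + hemodynamic integration ----------

// One classical RK4 pass over the joint state (x, s, log f, log v, log q per
// region): integrating the two stages jointly keeps the scheme 4th order
// (integrating hemodynamics against an interpolated neural trajectory would
// drop it to 2nd order). Samples the volume-onset bin of each TR; returns
// false on instability instead of throwing (the inverter treats that as an
// inadmissible step).
struct JointState {
  std::vector<double> x, s, lf, v, q;
  explicit JointState(int n) : x(n), s(n), lf(n), v(n), q(n) {}
};

static inline void joint_deriv(const JointState& y, const double* M,
                               const double* dconst, int n,
                               const double* kappa, const double* gamma,
                               const double* tauInv, const double* invAl,
                               const double* lome, const double* e0Inv,
                               const double* eps, JointState& d) {
  matvec_add(M, dconst, y.x.data(), d.x.data(), n);
  for (int r = 0; r < n; ++r) {
    const double f = std::exp(y.lf[r]);
    const double vexp = std::exp(invAl[r] * std::log(y.v[r]));
    d.s[r] = eps[r] * y.x[r] - kappa[r] * y.s[r] - gamma[r] * (f - 1.0);
    d.lf[r] = y.s[r] / f;
    d.v[r] = tauInv[r] * (f - vexp);
    const double E = 1.0 - std::exp(lome[r] / f);
    d.q[r] = tauInv[r] * (f * E * e0Inv[r] - vexp * y.q[r] / y.v[r]);
  }
}

static inline void joint_axpy(const JointState& y, double a,
                              const JointState& d, int n, JointState& out) {
  for (int r = 0; r < n; ++r) {
    out.x[r] = y.x[r] + a * d.x[r];
    out.s[r] = y.s[r] + a * d.s[r];
    out.lf[r] = y.lf[r] + a * d.lf[r];
    out.v[r] = y.v[r] + a * d.v[r];
    out.q[r] = y.q[r] + a * d.q[r];
  }
}

static bool forward_sampled(const double* Aeff, const double* Blow,
                            const double* Bhigh, const double* Cmat,
                            const mat& u, double dt, int bins, int n_scans,
                            int n, const double* kappa, const double* gamma,
                            const double* tau, const double* alpha,
                            const double* e0, const double* v0,
                            const double* eps, double* out /* n x n_scans */) {
  const uword T = (uword)bins * n_scans;
  std::vector<double> M[4], d[4];
  bool have[4] = {false, false, false, false};
  std::vector<double> invAl(n), lome(n), tauInv(n), e0Inv(n);
  for (int i = 0; i < n; ++i) {
    invAl[i] = 1.0 / alpha[i];
    lome[i] = std::log(1.0 - e0[i]);
    tauInv[i] = 1.0 / tau[i];
    e0Inv[i] = 1.0 / e0[i];
  }
  JointState y(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int r = 0; r < n; ++r) { y.v[r] = 1.0; y.q[r] = 1.0; }
  // resting initial state: x = s = log f = 0, v = q = 1
  for (uword t = 0; t + 1 <= T - 1; ++t) {
    int p = pattern_id(u, t);
    if (!have[p]) {
      M[p].assign(Aeff, Aeff + (size_t)n * n);
      if (p & 1)
        for (size_t i = 0; i < (size_t)n * n; ++i) M[p][i] += Blow[i];
      if (p & 2)
        for (size_t i = 0; i < (size_t)n * n; ++i) M[p][i] += Bhigh[i];
      d[p].assign(n, 0.0);
      for (int j = 0; j < 2; ++j) {
        double uj = u(j, t);
        if (uj != 0.0)
          for (int i = 0; i < n; ++i) d[p][i] += Cmat[(size_t)j * n + i] * uj;
      }
      have[p] = true;
    }
    const double* Mp = M[p].data();
    const double* dp = d[p].data();
    joint_deriv(y, Mp, dp, n, kappa, gamma, tauInv.data(), invAl.data(),
                lome.data(), e0Inv.data(), eps, k1);
    joint_axpy(y, 0.5 * dt, k1, n, tmp);
    joint_deriv(tmp, Mp, dp, n, kappa, gamma, tauInv.data(), invAl.data(),
                lome.data(), e0Inv.data(), eps, k2);
    joint_axpy(y, 0.5 * dt, k2, n, tmp);
    joint_deriv(tmp, Mp, dp, n, kappa, gamma, tauInv.data(), invAl.data(),
                lome.data(), e0Inv.data(), eps, k3);
    joint_axpy(y, dt, k3, n, tmp);
    joint_deriv(tmp, Mp, dp, n, kappa, gamma, tauInv.data(), invAl.data(),
                lome.data(), e0Inv.data(), eps, k4);
    bool ok = true;
    for (int r = 0; r < n; ++r) {
      y.x[r] += (dt / 6.0) * (k1.x[r] + 2 * k2.x[r] + 2 * k3.x[r] + k4.x[r]);
      y.s[r] += (dt / 6.0) * (k1.s[r] + 2 * k2.s[r] + 2 * k3.s[r] + k4.s[r]);
      y.lf[r] +=
          (dt / 6.0) * (k1.lf[r] + 2 * k2.lf[r] + 2 * k3.lf[r] + k4.lf[r]);
      y.v[r] += (dt / 6.0) * (k1.v[r] + 2 * k2.v[r] + 2 * k3.v[r] + k4.v[r]);
      y.q[r] += (dt / 6.0) * (k1.q[r] + 2 * k2.q[r] + 2 * k3.q[r] + k4.q[r]);
      if (!(std::isfinite(y.x[r]) && std::isfinite(y.s[r]) &&
            std::isfinite(y.lf[r]) && y.v[r] > 0.0 && y.q[r] > 0.0))
        ok = false;
    }
    if (!ok) return false;
    // acquisition at volume onsets (times (s-1)*TR); scan 0 is the initial
    // (zero) state, prefilled by the caller
    if ((t + 1) % (uword)bins == 0) {
      uword scan = (t + 1) / bins;
      if (scan < (uword)n_scans) {
        for (int r = 0; r < n; ++r) {
          double K1 = 7.0 * e0[r], K2 = 2.0, K3 = 2.0 * e0[r] - 0.2;
          out[(size_t)scan * n + r] =
              100.0 * v0[r] * (K1 * (1.0 - y.q[r]) +
                               K2 * (1.0 - y.q[r] / y.v[r]) +
                               K3 * (1.0 - y.v[r]));
        }
      }
    }
  }
  return true;
}

static void scatter_theta(const double* theta, const imat& iA, const imat& iB,
                          const imat& iC, double self_decay, int n,
                          std::vector<double>& A, std::vector<double>& Bl,
                          std::vector<double>& Bh, std::vector<double>& C) {
  A.assign((size_t)n * n, 0.0);
  Bl.assign((size_t)n * n, 0.0);
  Bh.assign((size_t)n * n, 0.0);
  C.assign((size_t)n * 2, 0.0);
  for (int i = 0; i < n; ++i) A[(size_t)i * n + i] = -self_decay;
  size_t k = 0;
  for (uword i = 0; i < iA.n_rows; ++i)
    A[(size_t)iA(i, 1) * n + iA(i, 0)] = theta[k++];
  for (uword i = 0; i < iB.n_rows; ++i)
    Bl[(size_t)iB(i, 1) * n + iB(i, 0)] = theta[k++];
  for (uword i = 0; i < iB.n_rows; ++i)
    Bh[(size_t)iB(i, 1) * n + iB(i, 0)] = theta[k++];
  for (uword i = 0; i < iC.n_rows; ++i)
    C[(size_t)iC(i, 1) * n + iC(i, 0)] = theta[k++];
}

// Predicted BOLD for a parameter vector (columns sampled once per TR).
// [[Rcpp::export(name = ".dcm_predict_cpp")]]
arma::mat dcm_predict_cpp(const arma::vec& theta, const arma::imat& iA,
                          const arma::imat& iB, const arma::imat& iC,
                          double self_decay, const arma::mat& u, double dt,
                          int bins, int n_scans, int n_regions,
                          const arma::vec& kappa, const arma::vec& gamma,
                          const arma::vec& tau, const arma::vec& alpha,
                          const arma::vec& e0, const arma::vec& v0,
                          const arma::vec& eps) {
  std::vector<double> A, Bl, Bh, C;
  scatter_theta(theta.memptr(), iA, iB, iC, self_decay, n_regions, A, Bl, Bh,
                C);
  mat out(n_regions, n_scans, fill::zeros);
  bool ok = forward_sampled(A.data(), Bl.data(), Bh.data(), C.data(), u, dt,
                            bins, n_scans, n_regions, kappa.memptr(),
                            gamma.memptr(), tau.memptr(), alpha.memptr(),
                            e0.memptr(), v0.memptr(), eps.memptr(),
                            out.memptr());
  if (!ok) Rcpp::stop("forward model unstable for the requested parameters");
  return out;
}

// Joint-integration BOLD simulation (same scheme as the inverter's
// prediction path), throwing on instability with the failing bin.
// [[Rcpp::export(name = ".simulate_bold_cpp")]]
arma::mat simulate_bold_cpp(const arma::mat& Aeff, const arma::mat& Blow,
                            const arma::mat& Bhigh, const arma::mat& C,
                            const arma::mat& u, double dt, int bins,
                            int n_scans, const arma::vec& kappa,
                            const arma::vec& gamma, const arma::vec& tau,
                            const arma::vec& alpha, const arma::vec& e0,
                            const arma::vec& v0, const arma::vec& eps) {
  const int n = (int)Aeff.n_rows;
  std::vector<double> A(Aeff.begin(), Aeff.end());
  std::vector<double> Bl(Blow.begin(), Blow.end());
  std::vector<double> Bh(Bhigh.begin(), Bhigh.end());
  std::vector<double> Cm(C.begin(), C.end());
  mat out(n, n_scans, fill::zeros);
  bool ok = forward_sampled(A.data(), Bl.data(), Bh.data(), Cm.data(), u, dt,
                            bins, n_scans, n, kappa.memptr(), gamma.memptr(),
                            tau.memptr(), alpha.memptr(), e0.memptr(),
                            v0.memptr(), eps.memptr(), out.memptr());
  if (!ok)
    Rcpp::stop("forward model unstable: state non-finite before microtime bin %d",
               (int)(bins * n_scans));
  return out;
}

// Prediction plus Jacobian by central finite differences (fixed step h).
// Returns g as vec(y) (region index fastest) and J of size (n*n_scans) x p.
// ok = FALSE flags instability at theta or a perturbation.
// [[Rcpp::export(name = ".dcm_predict_jac_cpp")]]
Rcpp::List dcm_predict_jac_cpp(const arma::vec& theta, const arma::imat& iA,
                               const arma::imat& iB, const arma::imat& iC,
                               double self_decay, const arma::mat& u,
                               double dt, int bins, int n_scans,
                               int n_regions, const arma::vec& kappa,
                               const arma::vec& gamma, const arma::vec& tau,
                               const arma::vec& alpha, const arma::vec& e0,
                               const arma::vec& v0, const arma::vec& eps,
                               double h) {
  const uword p = theta.n_elem;
  const size_t N = (size_t)n_regions * n_scans;
  std::vector<double> A, Bl, Bh, C;
  scatter_theta(theta.memptr(), iA, iB, iC, self_decay, n_regions, A, Bl, Bh,
                C);
  vec g(N, fill::zeros);
  bool ok = forward_sampled(A.data(), Bl.data(), Bh.data(), C.data(), u, dt,
                            bins, n_scans, n_regions, kappa.memptr(),
                            gamma.memptr(), tau.memptr(), alpha.memptr(),
                            e0.memptr(), v0.memptr(), eps.memptr(),
                            g.memptr());
  mat J(N, p, fill::zeros);
  vec gp(N), gm(N);
  if (ok) {
    for (uword j = 0; j < p && ok; ++j) {
      vec tp = theta, tm = theta;
      tp[j] += h;
      tm[j] -= h;
      scatter_theta(tp.memptr(), iA, iB, iC, self_decay, n_regions, A, Bl,
                    Bh, C);
      ok = ok && forward_sampled(A.data(), Bl.data(), Bh.data(), C.data(), u,
                                 dt, bins, n_scans, n_regions, kappa.memptr(),
                                 gamma.memptr(), tau.memptr(), alpha.memptr(),
                                 e0.memptr(), v0.memptr(), eps.memptr(),
                                 gp.memptr());
      scatter_theta(tm.memptr(), iA, iB, iC, self_decay, n_regions, A, Bl,
                    Bh, C);
      ok = ok && forward_sampled(A.data(), Bl.data(), Bh.data(), C.data(), u,
                                 dt, bins, n_scans, n_regions, kappa.memptr(),
                                 gamma.memptr(), tau.memptr(), alpha.memptr(),
                                 e0.memptr(), v0.memptr(), eps.memptr(),
                                 gm.memptr());
      if (ok) J.col(j) = (gp - gm) / (2.0 * h);
    }
  }
  return Rcpp::List::create(Rcpp::Named("g") = g, Rcpp::Named("J") = J,
                            Rcpp::Named("ok") = ok);
}
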