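// Compiled core: predicted cross-spectral features with their analytic
// parameter Jacobian (the inner loop of variational-Laplace inversion), and
// the fixed-step integrator of the neuronal + Balloon system used by the
// cohort simulator. Conventions (state ordering, feature ordering, constants)
// mirror the R-level forward model exactly and are cross-checked in tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct BalloonConst {
  double kappa0 = 0.64, gamma = 0.32, tau0 = 2.0, alpha_g = 0.32;
  double E0 = 0.4, V0 = 4.0, TE = 0.0331, r0 = 25.0, theta0 = 40.3;
  double amp_scale = 1.0 / 65536.0, beta_prior = 1.0;
};

// Build J, B, L and the pieces needed for derivatives.
void build_system(const vec& theta, int n, mat& J, mat& B, mat& L,
                  double& kappa, vec& tau, double& k2eff, double& epsv) {
  BalloonConst c;
  mat a(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) a(i, j) = theta(j * n + i);
  vec transit = theta.subvec(n * n, n * n + n - 1);
  double decay = theta(n * n + n);
  double epsilon = theta(n * n + n + 1);
  kappa = c.kappa0 * std::exp(decay);
  tau = c.tau0 * exp(transit);
  epsv = std::exp(epsilon);
  double k1 = 4.3 * c.theta0 * c.E0 * c.TE;
  double k2 = epsv * c.r0 * c.E0 * c.TE;
  double k3 = 1.0 - epsv;
  k2eff = k2;

  J.zeros(5 * n, 5 * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      J(i, j) = (i == j) ? -0.5 * std::exp(a(i, i)) : a(i, j);
  double dEdf = (1.0 - c.E0) * std::log(1.0 - c.E0);
  for (int r = 0; r < n; ++r) {
    int ix = r, is = n + r, ifl = 2 * n + r, iv = 3 * n + r, iq = 4 * n + r;
    J(is, ix) = 1.0;
    J(is, is) = -kappa;
    J(is, ifl) = -c.gamma;
    J(ifl, is) = 1.0;
    J(iv, ifl) = 1.0 / tau(r);
    J(iv, iv) = -1.0 / (c.alpha_g * tau(r));
    J(iq, ifl) = (c.E0 + dEdf) / (c.E0 * tau(r));
    J(iq, iv) = -(1.0 / c.alpha_g - 1.0) / tau(r);
    J(iq, iq) = -1.0 / tau(r);
  }
  B.zeros(5 * n, n);
  B.rows(0, n - 1) = eye(n, n);
  L.zeros(n, 5 * n);
  for (int r = 0; r < n; ++r) {
    L(r, 4 * n + r) = -c.V0 * (k1 + k2);
    L(r, 3 * n + r) = c.V0 * (k2 - k3);
  }
}

// Feature packing of one complex Hermitian n x n matrix:
// Re upper triangle incl diag (column-major), then Im strict upper.
void pack_features(const cx_mat& S, double* out) {
  int n = S.n_rows, p = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i <= j; ++i) out[p++] = S(i, j).real();
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < j; ++i) out[p++] = S(i, j).imag();
}

} // namespace

// Predicted CSD feature vector and its Jacobian with respect to the packed
// parameter vector (canonical ordering: a column-major, transit, decay,
// epsilon, alpha_v, beta_v, alpha_e, beta_e).
// [[Rcpp::export]]
Rcpp::List csd_features_cpp(const arma::vec& theta, int n,
                            const arma::vec& freq, bool want_jacobian) {
  BalloonConst c;
  int npar = n * n + n + 6;
  if ((int)theta.n_elem != npar) Rcpp::stop("parameter length mismatch");
  int nf = freq.n_elem, per = n * n;
  double alpha_v = theta(npar - 4), beta_v = theta(npar - 3);
  double alpha_e = theta(npar - 2), beta_e = theta(npar - 1);

  mat J, B, L;
  double kappa, k2, epsv;
  vec tau;
  build_system(theta, n, J, B, L, kappa, tau, k2, epsv);

  vec features(nf * per, fill::zeros);
  mat jac;
  if (want_jacobian) jac.zeros(nf * per, npar);

  // dL/depsilon
  mat dL(n, 5 * n, fill::zeros);
  for (int r = 0; r < n; ++r) {
    dL(r, 4 * n + r) = -c.V0 * k2;
    dL(r, 3 * n + r) = c.V0 * (k2 + epsv);
  }

  std::vector<double> buf(per);
  cx_mat Mbase = cx_mat(-J, mat(size(J), fill::zeros));

  for (int kf = 0; kf < nf; ++kf) {
    double f = freq(kf), w = 2.0 * datum::pi * f;
    double gv = std::exp(alpha_v) * c.amp_scale *
                std::pow(f, -c.beta_prior * std::exp(beta_v));
    double ge = std::exp(alpha_e) * c.amp_scale *
                std::pow(f, -c.beta_prior * std::exp(beta_e));
    cx_mat M = Mbase;
    M.diag() += cx_double(0.0, w);
    cx_mat R = inv(M);                         // resolvent (i w I - J)^-1
    cx_mat D = R.cols(0, n - 1);               // R B  (B = [I; 0])
    cx_mat C(n, 5 * n);                        // L R  (L sparse: v, q rows)
    for (int r = 0; r < n; ++r)
      C.row(r) = L(r, 3 * n + r) * R.row(3 * n + r) +
                 L(r, 4 * n + r) * R.row(4 * n + r);
    cx_mat G = C.cols(0, n - 1);               // L R B
    cx_mat GH = G.t();                                            // conj transp
    cx_mat S = gv * (G * GH);
    S.diag() += ge;
    S = (S + S.t()) / 2.0;
    pack_features(S, buf.data());
    for (int p = 0; p < per; ++p) features(kf * per + p) = buf[p];

    if (!want_jacobian) continue;
    auto store = [&](int col, const cx_mat& dS) {
      cx_mat H = (dS + dS.t()) / 2.0;
      pack_features(H, buf.data());
      for (int p = 0; p < per; ++p) jac(kf * per + p, col) = buf[p];
    };
    auto from_dG = [&](int col, const cx_mat& dG) {
      cx_mat dS = gv * (dG * GH + G * dG.t());
      store(col, dS);
    };
    // a-matrix entries
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double scale = (i == j) ? -0.5 * std::exp(theta(j * n + i)) : 1.0;
        cx_mat dG = scale * (C.col(i) * D.row(j));
        from_dG(j * n + i, dG);
      }
    // transit: rows iv, iq of J scale with 1/tau (2-3 nonzeros per row)
    for (int r = 0; r < n; ++r) {
      int ifl = 2 * n + r, iv = 3 * n + r, iq = 4 * n + r;
      cx_rowvec rv = -(J(iv, ifl) * D.row(ifl) + J(iv, iv) * D.row(iv));
      cx_rowvec rq = -(J(iq, ifl) * D.row(ifl) + J(iq, iv) * D.row(iv) +
                       J(iq, iq) * D.row(iq));
      cx_mat dG = C.col(iv) * rv + C.col(iq) * rq;
      from_dG(n * n + r, dG);
    }
    // decay: dJ(is, is) = -kappa
    {
      cx_mat dG(n, n, fill::zeros);
      for (int r = 0; r < n; ++r) {
        int is = n + r;
        dG += C.col(is) * (-kappa * D.row(is));
      }
      from_dG(n * n + n, dG);
    }
    // epsilon: through the observer gradient only (same sparsity as L)
    {
      cx_mat dG(n, n);
      for (int r = 0; r < n; ++r)
        dG.row(r) = dL(r, 3 * n + r) * D.row(3 * n + r) +
                    dL(r, 4 * n + r) * D.row(4 * n + r);
      from_dG(n * n + n + 1, dG);
    }
    // fluctuation and noise spectra
    store(npar - 4, gv * (G * GH));
    store(npar - 3, gv * (-std::log(f)) * std::exp(beta_v) * c.beta_prior *
                    (G * GH));
    {
      cx_mat dS(n, n, fill::zeros);
      dS.diag() += ge;
      store(npar - 2, dS);
      cx_mat dS2(n, n, fill::zeros);
      dS2.diag() += ge * (-std::log(f)) * std::exp(beta_e) * c.beta_prior;
      store(npar - 1, dS2);
    }
  }
  if (want_jacobian)
    return Rcpp::List::create(Rcpp::Named("features") = features,
                              Rcpp::Named("jacobian") = jac);
  return Rcpp::List::create(Rcpp::Named("features") = features);
}

// Fixed-step RK4 integration of the nonlinear neuronal + Balloon system
// driven by a precomputed endogenous input series (substep resolution).
// Returns the BOLD observation at every `subsample`-th substep after
// discarding `burn_steps` substeps.
// [[Rcpp::export]]
arma::mat simulate_balloon_cpp(const arma::mat& A, const arma::vec& tau,
                               double kappa, double epsv,
                               const arma::mat& input, double dt,
                               int subsample, int burn_steps, int n_volumes) {
  BalloonConst c;
  int n = A.n_rows;
  if ((int)input.n_cols != n) Rcpp::stop("input/ROI mismatch");
  int needed = burn_steps + n_volumes * subsample;
  if ((int)input.n_rows < needed) Rcpp::stop("input series too short");
  double k1 = 4.3 * c.theta0 * c.E0 * c.TE;
  double k2 = epsv * c.r0 * c.E0 * c.TE;
  double k3 = 1.0 - epsv;

  // state = (x, s, lf, lv, lq); f, v, q in log space so they stay positive
  vec state(5 * n, fill::zeros);
  auto drift = [&](const vec& st, const rowvec& u) {
    vec x = st.subvec(0, n - 1), s = st.subvec(n, 2 * n - 1);
    vec lf = st.subvec(2 * n, 3 * n - 1), lv = st.subvec(3 * n, 4 * n - 1),
        lq = st.subvec(4 * n, 5 * n - 1);
    vec f = exp(lf), v = exp(lv), q = exp(lq);
    vec E = 1.0 - exp(std::log(1.0 - c.E0) / f);
    vec fout = exp(lv / c.alpha_g);
    vec d(5 * n);
    d.subvec(0, n - 1) = A * x + u.t();
    d.subvec(n, 2 * n - 1) = x - kappa * s - c.gamma * (f - 1.0);
    d.subvec(2 * n, 3 * n - 1) = s / f;
    d.subvec(3 * n, 4 * n - 1) = (f - fout) / (tau % v);
    d.subvec(4 * n, 5 * n - 1) = (f % E / c.E0 - fout % q / v) / (tau % q);
    return d;
  };
  mat out(n_volumes, n);
  int rec = 0;
  for (int t = 0; t < needed; ++t) {
    rowvec u = input.row(t);   // input held constant over the substep
    vec kk1 = drift(state, u);
    vec kk2 = drift(state + 0.5 * dt * kk1, u);
    vec kk3 = drift(state + 0.5 * dt * kk2, u);
    vec kk4 = drift(state + dt * kk3, u);
    state += (dt / 6.0) * (kk1 + 2.0 * kk2 + 2.0 * kk3 + kk4);
    if (!state.is_finite() || abs(state.subvec(2 * n, 4 * n - 1)).max() > 5.0)
      Rcpp::stop("hemodynamic integration became unstable at step %d", t);
    if (t >= burn_steps && ((t - burn_steps + 1) % subsample == 0)) {
      vec vv = exp(state.subvec(3 * n, 4 * n - 1));
      vec qq = exp(state.subvec(4 * n, 5 * n - 1));
      out.row(rec++) = (c.V0 * (k1 * (1.0 - qq) + k2 * (1.0 - qq / vv) +
                                k3 * (1.0 - vv))).t();
      if (rec == n_volumes) break;
    }
  }
  if (rec != n_volumes) Rcpp::stop("integration ended before all volumes");
  return out;
}
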