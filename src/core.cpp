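// Compiled core: moment propagation, Kalman recursions, RTS smoother and
// the Euler-Maruyama simulator. All index vectors arriving from R are
// 1-based and converted here. RNG draws go through R's generator so
// set.seed() governs every stochastic path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// beta(m) = V diag(h) V' with hazards evaluated at the (floored) mean:
// h_k = max(m[src_k], 0) * rate_k. Flooring keeps the diffusion matrix PSD
// when the Gaussian mean goes negative.
static mat beta_at(const vec& m, const mat& V, const vec& rate, const uvec& src) {
  vec h(rate.n_elem);
  for (uword k = 0; k < rate.n_elem; ++k) {
    double x = m(src(k));
    if (x < 0.0) x = 0.0;
    h(k) = x * rate(k);
  }
  return V * diagmat(h) * V.t();
}

// Substep transition cache: expmat is by far the most expensive primitive
// and observation grids typically share a single interval length, so the
// half-substep exponential is computed once per (A, dt) and squared.
struct ExpmCache {
  std::map<double, std::pair<mat, mat>> store; // dt -> (Eh, Eh2)
  const std::pair<mat, mat>& get(const mat& A, double dt, int substeps) {
    auto it = store.find(dt);
    if (it == store.end()) {
      const double h = dt / substeps;
      mat Eh2 = expmat(A * (0.5 * h));
      mat Eh = Eh2 * Eh2;
      it = store.emplace(dt, std::make_pair(std::move(Eh), std::move(Eh2))).first;
    }
    return it->second;
  }
};

// Advance (m, P) over an interval dt.
// Mean: exact linear solution via the substep transition expmat(A h).
// Covariance: classical RK4 on dP/dt = A P + P A' + beta_scale * beta(m*(t)),
// with m*(t) evaluated on the exact mean path (substep and half-substep
// transitions). Symmetrised after every substep.
static void propagate_inplace(vec& m, mat& P, const mat& A, const mat& V,
                              const vec& rate, const uvec& src, double dt,
                              int substeps, double beta_scale, ExpmCache& cache) {
  if (dt <= 0.0) return;
  const double h = dt / substeps;
  const auto& tr = cache.get(A, dt, substeps);
  const mat& Eh  = tr.first;
  const mat& Eh2 = tr.second;
  for (int s = 0; s < substeps; ++s) {
    const vec m0 = m;
    const vec mh = Eh2 * m0;
    const vec m1 = Eh * m0;
    const mat B0 = beta_scale * beta_at(m0, V, rate, src);
    const mat Bh = beta_scale * beta_at(mh, V, rate, src);
    const mat B1 = beta_scale * beta_at(m1, V, rate, src);
    const mat k1 = A * P + P * A.t() + B0;
    mat Pt = P + (0.5 * h) * k1;
    const mat k2 = A * Pt + Pt * A.t() + Bh;
    Pt = P + (0.5 * h) * k2;
    const mat k3 = A * Pt + Pt * A.t() + Bh;
    Pt = P + h * k3;
    const mat k4 = A * Pt + Pt * A.t() + B1;
    P += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    P = 0.5 * (P + P.t());
    m = m1;
  }
  if (!m.is_finite() || !P.is_finite())
    Rcpp::stop("moment integration diverged over an interval of length %g", dt);
}

// Cholesky with escalating diagonal jitter (1e-9 -> 1e-6); hard error
// beyond. Returns the jitter actually applied so callers can keep their
// reported matrices consistent with the factor used.
static double chol_jitter(const mat& S, mat& L, const char* what,
                          int time_index) {
  for (double jit = 1e-9; jit <= 1.1e-6; jit *= 10.0) {
    if (chol(L, S + jit * eye(S.n_rows, S.n_cols), "lower")) return jit;
  }
  Rcpp::stop("%s not positive definite after jitter escalation (time index %d)",
             what, time_index);
  return 0.0; // unreached
}

// Gaussian correction; overwrites (m, P) with filtered moments, returns the
// log-likelihood increment. idx is 0-based. The measurement variance is
// evaluated at the predictive mean, floored at 0.
static double update_inplace(vec& m, mat& P, const uvec& idx, const vec& y,
                             double rho0, double rho1, int time_index,
                             vec* mu_out, mat* S_out) {
  const uword d = idx.n_elem;
  if (d == 0) {
    if (mu_out) mu_out->reset();
    if (S_out) S_out->reset();
    return 0.0;
  }
  const vec mu = m(idx);
  vec rdiag(d);
  for (uword i = 0; i < d; ++i) {
    const double g = mu(i) > 0.0 ? mu(i) : 0.0;
    rdiag(i) = rho0 + rho1 * g;
  }
  mat S = P.submat(idx, idx) + diagmat(rdiag);
  S = 0.5 * (S + S.t());
  mat L;
  const double jit = chol_jitter(S, L, "innovation covariance", time_index);
  S.diag() += jit; // the factorised matrix is the one reported and used
  if (mu_out) *mu_out = mu;
  if (S_out) *S_out = S;
  const vec resid = y - mu;
  const vec alpha = solve(trimatl(L), resid);
  const double ll = -0.5 * d * LOG2PI - accu(log(L.diag())) - 0.5 * dot(alpha, alpha);
  const mat PG = P.cols(idx);                       // n x d
  const mat SinvPGt = solve(trimatu(L.t()), solve(trimatl(L), PG.t()));
  const mat K = SinvPGt.t();                        // Kalman gain, n x d
  m += K * resid;
  P -= K * S * K.t();
  P = 0.5 * (P + P.t());
  return ll;
}

// [[Rcpp::export]]
Rcpp::List cpp_propagate(const arma::vec& m0, const arma::mat& P0,
                         const arma::mat& A, const arma::mat& V,
                         const arma::vec& rate, const arma::uvec& src1,
                         double dt, int substeps, double beta_scale) {
  vec m = m0;
  mat P = P0;
  ExpmCache cache;
  propagate_inplace(m, P, A, V, rate, src1 - 1, dt, substeps, beta_scale, cache);
  return Rcpp::List::create(Rcpp::Named("mean") = m, Rcpp::Named("cov") = P);
}

// [[Rcpp::export]]
Rcpp::List cpp_update(const arma::vec& m0, const arma::mat& P0,
                      const arma::uvec& idx1, const arma::vec& y,
                      double rho0, double rho1) {
  vec m = m0;
  mat P = P0;
  vec mu;
  mat S;
  const double ll = update_inplace(m, P, idx1 - 1, y, rho0, rho1, 1, &mu, &S);
  return Rcpp::List::create(Rcpp::Named("mean") = m, Rcpp::Named("cov") = P,
                            Rcpp::Named("innovation_mean") = mu,
                            Rcpp::Named("innovation_cov") = S,
                            Rcpp::Named("loglik") = ll);
}

// Forward pass over one clone. dts(k) is the interval preceding observation
// k (dts(0) may be 0 when the prior sits at the first observation time).
// obs_idx: list of 1-based integer vectors; ys: list of numeric vectors.
// beta_mode: 0 = unit scaling, 1 = interval (dt) scaling of beta.
// [[Rcpp::export]]
Rcpp::List cpp_filter_clone(const arma::vec& dts, const Rcpp::List& obs_idx,
                            const Rcpp::List& ys, const arma::vec& m0,
                            const arma::mat& P0, const arma::mat& A,
                            const arma::mat& V, const arma::vec& rate,
                            const arma::uvec& src1, double rho0, double rho1,
                            int substeps, int beta_mode, bool store) {
  const uword n = m0.n_elem, tau = dts.n_elem;
  const uvec src = src1 - 1;
  vec m = m0;
  mat P = P0;
  ExpmCache cache;
  double ll = 0.0;
  mat m_pred, m_filt;
  cube P_pred, P_filt;
  Rcpp::List mu_list(tau), S_list(tau);
  if (store) {
    m_pred.set_size(n, tau);
    m_filt.set_size(n, tau);
    P_pred.set_size(n, n, tau);
    P_filt.set_size(n, n, tau);
  }
  for (uword k = 0; k < tau; ++k) {
    const double dt = dts(k);
    propagate_inplace(m, P, A, V, rate, src, dt, substeps,
                      beta_mode == 1 ? dt : 1.0, cache);
    if (store) { m_pred.col(k) = m; P_pred.slice(k) = P; }
    const Rcpp::IntegerVector iv = obs_idx[k];
    uvec idx(iv.size());
    for (int i = 0; i < iv.size(); ++i) idx(i) = (uword)(iv[i] - 1);
    const vec y = Rcpp::as<vec>(ys[k]);
    if (store) {
      vec mu_k;
      mat S_k;
      ll += update_inplace(m, P, idx, y, rho0, rho1, (int)k + 1, &mu_k, &S_k);
      mu_list[k] = mu_k;
      S_list[k] = S_k;
      m_filt.col(k) = m;
      P_filt.slice(k) = P;
    } else {
      ll += update_inplace(m, P, idx, y, rho0, rho1, (int)k + 1, nullptr, nullptr);
    }
  }
  if (!store) return Rcpp::List::create(Rcpp::Named("loglik") = ll);
  return Rcpp::List::create(
      Rcpp::Named("loglik") = ll, Rcpp::Named("m_pred") = m_pred,
      Rcpp::Named("P_pred") = P_pred, Rcpp::Named("m_filt") = m_filt,
      Rcpp::Named("P_filt") = P_filt, Rcpp::Named("innovation_mean") = mu_list,
      Rcpp::Named("innovation_cov") = S_list);
}

// Total marginal log-likelihood over independent clones. clones: list of
// lists with elements dts, obs_idx, ys, m0, P0.
// [[Rcpp::export]]
double cpp_loglik_clones(const Rcpp::List& clones, const arma::mat& A,
                         const arma::mat& V, const arma::vec& rate,
                         const arma::uvec& src1, double rho0, double rho1,
                         int substeps, int beta_mode) {
  const uvec src = src1 - 1;
  ExpmCache cache;
  double ll = 0.0;
  for (int c = 0; c < clones.size(); ++c) {
    const Rcpp::List cl = clones[c];
    const vec dts = Rcpp::as<vec>(cl["dts"]);
    const Rcpp::List obs_idx = cl["obs_idx"];
    const Rcpp::List ys = cl["ys"];
    vec m = Rcpp::as<vec>(cl["m0"]);
    mat P = Rcpp::as<mat>(cl["P0"]);
    for (uword k = 0; k < dts.n_elem; ++k) {
      const double dt = dts(k);
      propagate_inplace(m, P, A, V, rate, src, dt, substeps,
                        beta_mode == 1 ? dt : 1.0, cache);
      const Rcpp::IntegerVector iv = obs_idx[k];
      uvec idx(iv.size());
      for (int i = 0; i < iv.size(); ++i) idx(i) = (uword)(iv[i] - 1);
      const vec y = Rcpp::as<vec>(ys[k]);
      ll += update_inplace(m, P, idx, y, rho0, rho1, (int)k + 1, nullptr, nullptr);
    }
  }
  return ll;
}

// Fixed-interval RTS smoother. Backward gain B_{k+1} = P_k F' (P*_{k+1})^-1
// with F = expmat(A * s), s = dt_{k+1} (interval scaling) or 1 (unit).
// dts(k) is the interval preceding observation k, matching the filter.
// [[Rcpp::export]]
Rcpp::List cpp_smooth_clone(const arma::mat& m_pred, const arma::cube& P_pred,
                            const arma::mat& m_filt, const arma::cube& P_filt,
                            const arma::mat& A, const arma::vec& dts,
                            bool interval_scaling) {
  const uword n = m_filt.n_rows, tau = m_filt.n_cols;
  mat ms(n, tau);
  cube Ps(n, n, tau);
  ms.col(tau - 1) = m_filt.col(tau - 1);
  Ps.slice(tau - 1) = P_filt.slice(tau - 1);
  for (uword k = tau - 1; k-- > 0;) {
    const double s = interval_scaling ? dts(k + 1) : 1.0;
    const mat F = expmat(A * s);
    const mat Pstar = P_pred.slice(k + 1);
    mat L;
    chol_jitter(Pstar, L, "predictive covariance", (int)k + 2);
    // B = P_filt(k) F' Pstar^-1 computed through the Cholesky factor.
    const mat PstarInvT = solve(trimatu(L.t()), solve(trimatl(L), F * P_filt.slice(k)));
    const mat B = PstarInvT.t();
    ms.col(k) = m_filt.col(k) + B * (ms.col(k + 1) - m_pred.col(k + 1));
    mat Pk = P_filt.slice(k) +
             B * (Ps.slice(k + 1) - Pstar) * B.t();
    Ps.slice(k) = 0.5 * (Pk + Pk.t());
  }
  return Rcpp::List::create(Rcpp::Named("mean") = ms, Rcpp::Named("cov") = Ps);
}

// Euler-Maruyama integration of dx = V h(x) dt + (V diag(h) V')^{1/2} dW on
// a fixed grid. The diffusion square root uses a symmetric eigendecomposition
// with negative eigenvalues clipped at 0. Draws come from R's RNG.
// [[Rcpp::export]]
arma::mat cpp_euler_maruyama(const arma::vec& x0, const arma::vec& tgrid,
                             const arma::mat& V, const arma::vec& rate,
                             const arma::uvec& src1, bool floor_states,
                             bool stochastic) {
  const uword n = x0.n_elem, nt = tgrid.n_elem;
  const uvec src = src1 - 1;
  const uword K = rate.n_elem;
  mat out(n, nt);
  vec x = x0;
  out.col(0) = x;
  vec h(K);
  for (uword s = 1; s < nt; ++s) {
    const double dt = tgrid(s) - tgrid(s - 1);
    for (uword k = 0; k < K; ++k) h(k) = x(src(k)) * rate(k);
    x += (V * h) * dt;
    if (stochastic) {
      const mat B = V * diagmat(h) * V.t();
      vec eval;
      mat evec;
      if (!eig_sym(eval, evec, 0.5 * (B + B.t())))
        Rcpp::stop("diffusion eigendecomposition failed at step %u", (unsigned)s);
      eval.transform([](double v) { return v > 0.0 ? std::sqrt(v) : 0.0; });
      vec z(n);
      for (uword j = 0; j < n; ++j) z(j) = R::norm_rand();
      x += std::sqrt(dt) * (evec * (eval % (evec.t() * z)));
    }
    if (floor_states) x.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (!x.is_finite())
      Rcpp::stop("state blew up at step %u (t = %g)", (unsigned)s, tgrid(s));
    out.col(s) = x;
  }
  return out;
}
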