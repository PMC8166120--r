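// Full-information maximum likelihood engine for small structural equation
// models of the latent-growth family.
//
// Model (all matrices small: p observed outcomes, k latent factors,
// q exogenous covariates):
//   eta = B eta + alpha + Gamma x + zeta,   zeta ~ N(0, Psi)
//   y   = Lambda eta + eps,                 eps  ~ N(0, diag(theta))
// Covariates are exogenous and complete; the likelihood computed here is the
// conditional likelihood of the observed outcome subvector given x, grouped
// by missingness pattern so cost is independent of n within a pattern.
//
// Free parameters are mapped into (alpha, Gamma, B, Psi, theta) by integer
// index matrices (0 = fixed at the supplied value, j = j-th free parameter).
// Repeated indices impose equality; symmetric Psi entries share one index.
//
// Variance parameters are deliberately unconstrained: negative estimates
// must be observable so that the boundary (Heywood) rule can act on them.

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

struct SemModel {
  mat Lambda;               // p x k, fixed loadings
  ivec a_idx;  vec a_fix;   // k
  imat G_idx;  mat G_fix;   // k x q
  imat B_idx;  mat B_fix;   // k x k
  imat P_idx;  mat P_fix;   // k x k symmetric
  ivec T_idx;  vec T_fix;   // p (diagonal residual variances)
  int npar;
  bool has_B;
};

struct Pattern {
  uvec obs;   // 0-based indices into 1..p
  mat Y;      // n x |obs|
  mat X;      // n x q (q may be 0)
  unsigned int n;
};

static SemModel as_model(const Rcpp::List& m) {
  SemModel s;
  s.Lambda = Rcpp::as<mat>(m["Lambda"]);
  s.a_idx = Rcpp::as<ivec>(m["a_idx"]);  s.a_fix = Rcpp::as<vec>(m["a_fix"]);
  s.G_idx = Rcpp::as<imat>(m["G_idx"]);  s.G_fix = Rcpp::as<mat>(m["G_fix"]);
  s.B_idx = Rcpp::as<imat>(m["B_idx"]);  s.B_fix = Rcpp::as<mat>(m["B_fix"]);
  s.P_idx = Rcpp::as<imat>(m["P_idx"]);  s.P_fix = Rcpp::as<mat>(m["P_fix"]);
  s.T_idx = Rcpp::as<ivec>(m["T_idx"]);  s.T_fix = Rcpp::as<vec>(m["T_fix"]);
  s.npar  = Rcpp::as<int>(m["npar"]);
  s.has_B = any(vectorise(s.B_idx) > 0) || any(vectorise(abs(s.B_fix)) > 0);
  return s;
}

static std::vector<Pattern> as_patterns(const Rcpp::List& pl) {
  std::vector<Pattern> out;
  out.reserve(pl.size());
  for (int i = 0; i < pl.size(); ++i) {
    Rcpp::List p = pl[i];
    Pattern pa;
    pa.obs = Rcpp::as<uvec>(p["obs"]);       // already 0-based from R side
    pa.Y = Rcpp::as<mat>(p["Y"]);
    pa.X = Rcpp::as<mat>(p["X"]);
    pa.n = pa.Y.n_rows;
    out.push_back(pa);
  }
  return out;
}

static void build_matrices(const SemModel& m, const vec& par,
                           vec& alpha, mat& Gamma, mat& B, mat& Psi, vec& theta) {
  const int k = m.Lambda.n_cols, p = m.Lambda.n_rows, q = m.G_idx.n_cols;
  alpha = m.a_fix;  Gamma = m.G_fix;  B = m.B_fix;  Psi = m.P_fix;  theta = m.T_fix;
  for (int j = 0; j < k; ++j) if (m.a_idx(j) > 0) alpha(j) = par(m.a_idx(j) - 1);
  for (int j = 0; j < k; ++j) for (int l = 0; l < q; ++l)
    if (m.G_idx(j, l) > 0) Gamma(j, l) = par(m.G_idx(j, l) - 1);
  for (int j = 0; j < k; ++j) for (int l = 0; l < k; ++l) {
    if (m.B_idx(j, l) > 0) B(j, l) = par(m.B_idx(j, l) - 1);
    if (m.P_idx(j, l) > 0) Psi(j, l) = par(m.P_idx(j, l) - 1);
  }
  for (int j = 0; j < p; ++j) if (m.T_idx(j) > 0) theta(j) = par(m.T_idx(j) - 1);
}

// conditional log-likelihood of y | x; returns NaN when an observed-block
// covariance submatrix is not positive definite
static double sem_loglik(const SemModel& m, const std::vector<Pattern>& pats,
                         const vec& par) {
  vec alpha, theta; mat Gamma, B, Psi;
  build_matrices(m, par, alpha, Gamma, B, Psi, theta);
  const int k = m.Lambda.n_cols;
  mat LamM;
  if (m.has_B) {
    mat IB = eye(k, k) - B;
    mat Minv;
    if (!inv(Minv, IB)) return datum::nan;
    LamM = m.Lambda * Minv;
  } else {
    LamM = m.Lambda;
  }
  mat Sigma = LamM * Psi * LamM.t();
  Sigma.diag() += theta;

  double ll = 0.0;
  for (const Pattern& pa : pats) {
    if (pa.obs.n_elem == 0) continue;
    mat So = Sigma.submat(pa.obs, pa.obs);
    mat L;
    if (!chol(L, So, "lower")) return datum::nan;
    double logdet = 2.0 * accu(log(L.diag()));
    // means: k x n
    mat C = repmat(alpha, 1, pa.n);
    if (pa.X.n_cols > 0) C += Gamma * pa.X.t();
    mat Mu = LamM.rows(pa.obs) * C;             // |o| x n
    mat R = pa.Y.t() - Mu;                      // |o| x n
    mat Z = solve(trimatl(L), R);               // |o| x n
    double quad = accu(Z % Z);
    ll += -0.5 * (pa.n * (pa.obs.n_elem * LOG2PI + logdet) + quad);
  }
  return ll;
}

// analytic gradient of the conditional log-likelihood
static vec sem_grad(const SemModel& m, const std::vector<Pattern>& pats,
                    const vec& par, bool& ok) {
  vec alpha, theta; mat Gamma, B, Psi;
  build_matrices(m, par, alpha, Gamma, B, Psi, theta);
  const int k = m.Lambda.n_cols, p = m.Lambda.n_rows, q = m.G_idx.n_cols;
  mat Minv = eye(k, k);
  if (m.has_B) {
    mat IB = eye(k, k) - B;
    if (!inv(Minv, IB)) { ok = false; return vec(m.npar, fill::zeros); }
  }
  mat LamM = m.Lambda * Minv;
  mat Sigma = LamM * Psi * LamM.t();
  Sigma.diag() += theta;

  vec g_alpha(k, fill::zeros);
  mat g_Gamma(k, q, fill::zeros);
  mat g_B(k, k, fill::zeros);
  mat Gfull(p, p, fill::zeros);   // dll = tr(Gfull dSigma)
  mat Dsum(k, 1, fill::zeros);    // placeholder, not used

  ok = true;
  for (const Pattern& pa : pats) {
    if (pa.obs.n_elem == 0) continue;
    mat So = Sigma.submat(pa.obs, pa.obs);
    mat A;
    if (!inv_sympd(A, So)) { ok = false; return vec(m.npar, fill::zeros); }
    mat C = repmat(alpha, 1, pa.n);
    if (q > 0) C += Gamma * pa.X.t();
    mat Lo = LamM.rows(pa.obs);                 // |o| x k
    mat Mu = Lo * C;
    mat R = pa.Y.t() - Mu;                      // |o| x n
    mat W = A * R;                              // dll/dMu, |o| x n
    mat D = Lo.t() * W;                         // dll/dC, k x n
    g_alpha += sum(D, 1);
    if (q > 0) g_Gamma += D * pa.X;
    mat S = R * R.t();
    mat Gp = 0.5 * (A * S * A - ((double)pa.n) * A);
    // scatter into full matrix
    for (unsigned int a = 0; a < pa.obs.n_elem; ++a)
      for (unsigned int b = 0; b < pa.obs.n_elem; ++b)
        Gfull(pa.obs(a), pa.obs(b)) += Gp(a, b);
    if (m.has_B) {
      mat Eta = Minv * C;                       // k x n
      g_B += D * Eta.t();                       // mean part (D already has M')
    }
  }

  mat Hpsi = LamM.t() * Gfull * LamM;           // dll = sum Hpsi_jk dPsi_jk
  if (m.has_B) g_B += 2.0 * Hpsi * Psi * Minv.t();

  vec g(m.npar, fill::zeros);
  for (int j = 0; j < k; ++j) if (m.a_idx(j) > 0) g(m.a_idx(j) - 1) += g_alpha(j);
  for (int j = 0; j < k; ++j) for (int l = 0; l < q; ++l)
    if (m.G_idx(j, l) > 0) g(m.G_idx(j, l) - 1) += g_Gamma(j, l);
  for (int j = 0; j < k; ++j) for (int l = 0; l < k; ++l) {
    if (m.B_idx(j, l) > 0) g(m.B_idx(j, l) - 1) += g_B(j, l);
    if (m.P_idx(j, l) > 0) g(m.P_idx(j, l) - 1) += Hpsi(j, l);
  }
  for (int j = 0; j < p; ++j) if (m.T_idx(j) > 0) g(m.T_idx(j) - 1) += Gfull(j, j);
  return g;
}

// [[Rcpp::export]]
double cpp_sem_loglik(const arma::vec& par, const Rcpp::List& model,
                      const Rcpp::List& patterns) {
  SemModel m = as_model(model);
  std::vector<Pattern> pats = as_patterns(patterns);
  return sem_loglik(m, pats, par);
}

// [[Rcpp::export]]
arma::vec cpp_sem_grad(const arma::vec& par, const Rcpp::List& model,
                       const Rcpp::List& patterns) {
  SemModel m = as_model(model);
  std::vector<Pattern> pats = as_patterns(patterns);
  bool ok = true;
  vec g = sem_grad(m, pats, par, ok);
  if (!ok) g.fill(datum::nan);
  return g;
}

static double fit_bfgs(const SemModel& m, const std::vector<Pattern>& pats,
                       vec& x, double tol_g, double tol_step, int maxit,
                       bool& conv, int& iters, double& gnorm);

// BFGS with backtracking line search on the negative log-likelihood.
// Multi-start: each column of `starts` is tried; the best converged optimum
// (falling back to the best point seen) is returned.
// [[Rcpp::export]]
Rcpp::List cpp_sem_fit(const arma::mat& starts, const Rcpp::List& model,
                       const Rcpp::List& patterns,
                       double tol_g = 1e-6, double tol_step = 1e-9,
                       int maxit = 500) {
  SemModel m = as_model(model);
  std::vector<Pattern> pats = as_patterns(patterns);
  const int np = m.npar;

  vec best_x(np, fill::zeros);
  double best_f = datum::inf;
  bool best_conv = false;
  int best_start = -1, best_iter = 0;
  double best_gnorm = datum::inf;

  for (unsigned int s = 0; s < starts.n_cols; ++s) {
    vec x = starts.col(s);
    bool conv; int it; double gn;
    double fx = fit_bfgs(m, pats, x, tol_g, tol_step, maxit, conv, it, gn);
    if (!std::isfinite(fx)) continue;
    bool better = (conv && !best_conv) ||
                  (conv == best_conv && fx < best_f - 1e-10);
    if (better) {
      best_x = x; best_f = fx; best_conv = conv;
      best_start = (int)s; best_iter = it; best_gnorm = gn;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("par") = best_x,
    Rcpp::Named("loglik") = -best_f,
    Rcpp::Named("converged") = best_conv,
    Rcpp::Named("grad_norm") = best_gnorm,
    Rcpp::Named("iterations") = best_iter,
    Rcpp::Named("start_used") = best_start + 1);
}

// observed-information Hessian of the negative log-likelihood,
// central differences of the analytic gradient
// [[Rcpp::export]]
arma::mat cpp_sem_hessian(const arma::vec& par, const Rcpp::List& model,
                          const Rcpp::List& patterns, double h = 1e-5) {
  SemModel m = as_model(model);
  std::vector<Pattern> pats = as_patterns(patterns);
  const int np = m.npar;
  mat H(np, np, fill::zeros);
  for (int j = 0; j < np; ++j) {
    double hj = h * (std::abs(par(j)) + 1.0);
    vec pp = par, pm = par;
    pp(j) += hj; pm(j) -= hj;
    bool ok1 = true, ok2 = true;
    vec gp = -sem_grad(m, pats, pp, ok1);
    vec gm = -sem_grad(m, pats, pm, ok2);
    if (!ok1 || !ok2) { H.fill(datum::nan); return H; }
    H.col(j) = (gp - gm) / (2.0 * hj);
  }
  return 0.5 * (H + H.t());
}

// ---------------------------------------------------------------------------
// Unstructured multivariate-normal FIML: log-likelihood and EM estimation
// over a joint observed vector with arbitrary missingness patterns.
// Patterns here carry Z (n x |obs|) and obs (0-based into 1..d).
// ---------------------------------------------------------------------------

struct ZPattern {
  uvec obs;
  mat Z;
  unsigned int n;
};

static std::vector<ZPattern> as_zpatterns(const Rcpp::List& pl) {
  std::vector<ZPattern> out;
  out.reserve(pl.size());
  for (int i = 0; i < pl.size(); ++i) {
    Rcpp::List p = pl[i];
    ZPattern pa;
    pa.obs = Rcpp::as<uvec>(p["obs"]);
    pa.Z = Rcpp::as<mat>(p["Z"]);
    pa.n = pa.Z.n_rows;
    out.push_back(pa);
  }
  return out;
}

static double mvn_pattern_loglik(const std::vector<ZPattern>& pats,
                                 const vec& mu, const mat& Sigma) {
  double ll = 0.0;
  for (const ZPattern& pa : pats) {
    if (pa.obs.n_elem == 0) continue;
    mat So = Sigma.submat(pa.obs, pa.obs);
    mat L;
    if (!chol(L, So, "lower")) return datum::nan;
    double logdet = 2.0 * accu(log(L.diag()));
    mat R = pa.Z.t();
    R.each_col() -= mu.elem(pa.obs);
    mat Zs = solve(trimatl(L), R);
    ll += -0.5 * (pa.n * (pa.obs.n_elem * LOG2PI + logdet) + accu(Zs % Zs));
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_mvn_loglik(const Rcpp::List& patterns, const arma::vec& mu,
                      const arma::mat& Sigma) {
  std::vector<ZPattern> pats = as_zpatterns(patterns);
  return mvn_pattern_loglik(pats, mu, Sigma);
}

// EM for the saturated (unstructured) mean/covariance MLE under missingness
// [[Rcpp::export]]
Rcpp::List cpp_mvn_em(const Rcpp::List& patterns, const arma::vec& mu0,
                      const arma::mat& Sigma0, double tol = 1e-10,
                      int maxit = 1000) {
  std::vector<ZPattern> pats = as_zpatterns(patterns);
  const int d = mu0.n_elem;
  vec mu = mu0;
  mat Sigma = Sigma0;
  unsigned int N = 0;
  for (const ZPattern& pa : pats) N += pa.n;

  double ll_old = -datum::inf, ll = -datum::inf;
  int it = 0;
  bool conv = false;
  uvec all = regspace<uvec>(0, d - 1);

  for (it = 0; it < maxit; ++it) {
    vec Ez(d, fill::zeros);
    mat Ezz(d, d, fill::zeros);
    ll = 0.0;
    for (const ZPattern& pa : pats) {
      uvec o = pa.obs;
      std::vector<uword> mv;
      uvec is_obs(d, fill::zeros);
      for (uword j = 0; j < o.n_elem; ++j) is_obs(o(j)) = 1;
      for (int j = 0; j < d; ++j) if (!is_obs(j)) mv.push_back(j);
      uvec mm(mv);
      mat So = Sigma.submat(o, o);
      mat L;
      if (!chol(L, So, "lower")) {
        return Rcpp::List::create(Rcpp::Named("converged") = false,
                                  Rcpp::Named("error") = "nonpd");
      }
      double logdet = 2.0 * accu(log(L.diag()));
      mat R = pa.Z.t();                        // |o| x n
      R.each_col() -= mu.elem(o);
      mat Zs = solve(trimatl(L), R);
      ll += -0.5 * (pa.n * (o.n_elem * LOG2PI + logdet) + accu(Zs % Zs));

      mat Zo = pa.Z;                           // n x |o|
      // observed block accumulation
      vec co = sum(Zo, 0).t();
      for (uword a = 0; a < o.n_elem; ++a) Ez(o(a)) += co(a);
      mat ZtZ = Zo.t() * Zo;
      for (uword a = 0; a < o.n_elem; ++a)
        for (uword b = 0; b < o.n_elem; ++b)
          Ezz(o(a), o(b)) += ZtZ(a, b);
      if (mm.n_elem > 0) {
        mat Som_inv_R = solve(trimatl(L).t(), Zs);       // Soo^{-1} (z - mu_o)
        mat Smo = Sigma.submat(mm, o);
        mat Cm = repmat(mu.elem(mm), 1, pa.n) + Smo * Som_inv_R;  // |m| x n
        mat Cmm = Sigma.submat(mm, mm) -
                  Smo * solve(So, Sigma.submat(o, mm));
        vec cm = sum(Cm, 1);
        for (uword a = 0; a < mm.n_elem; ++a) Ez(mm(a)) += cm(a);
        mat Mo = Cm * Zo;                                 // |m| x |o|
        for (uword a = 0; a < mm.n_elem; ++a)
          for (uword b = 0; b < o.n_elem; ++b) {
            Ezz(mm(a), o(b)) += Mo(a, b);
            Ezz(o(b), mm(a)) += Mo(a, b);
          }
        mat Mmm = Cm * Cm.t() + ((double)pa.n) * Cmm;
        for (uword a = 0; a < mm.n_elem; ++a)
          for (uword b = 0; b < mm.n_elem; ++b)
            Ezz(mm(a), mm(b)) += Mmm(a, b);
      }
    }
    vec mu_new = Ez / (double)N;
    mat Sigma_new = Ezz / (double)N - mu_new * mu_new.t();
    Sigma_new = 0.5 * (Sigma_new + Sigma_new.t());
    mu = mu_new; Sigma = Sigma_new;
    if (std::isfinite(ll) && std::abs(ll - ll_old) < tol * (std::abs(ll) + 1.0)) {
      conv = true; ++it; break;
    }
    ll_old = ll;
  }
  double ll_final = mvn_pattern_loglik(pats, mu, Sigma);
  return Rcpp::List::create(
    Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma") = Sigma,
    Rcpp::Named("loglik") = ll_final,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = conv);
}

// ---------------------------------------------------------------------------
// single-voxel pipeline: BFGS fit from supplied starts, observed-information
// standard errors, saturated-model EM (pairwise-moment warm start) and the
// independence-model log-likelihood, in one call. `groups` carries the
// missingness-pattern structure precomputed once per run: per pattern the
// 1-based subject rows and the 0-based observed-outcome indices.
// ---------------------------------------------------------------------------

// expected (Fisher) information of the conditional model at `par`,
// closed form for the multivariate normal: block diagonal in mean and
// covariance parameters, cross-information zero. Only valid with no free
// or nonzero latent regressions (B = 0), which covers the growth models on
// the voxelwise fast path.
static bool expected_information(const SemModel& m,
                                 const std::vector<Pattern>& pats,
                                 const vec& par, mat& I) {
  if (m.has_B) return false;
  const int np = m.npar, k = m.Lambda.n_cols, p = m.Lambda.n_rows,
            q = m.G_idx.n_cols;
  vec alpha, theta; mat Gamma, B, Psi;
  build_matrices(m, par, alpha, Gamma, B, Psi, theta);
  mat Sigma = m.Lambda * Psi * m.Lambda.t();
  Sigma.diag() += theta;

  // per-parameter derivative structures (handles shared/equality indices)
  std::vector<vec> dAlpha(np, vec(k, fill::zeros));
  std::vector<mat> dGamma(np, mat(k, std::max(q, 1), fill::zeros));
  std::vector<mat> dPsi(np, mat(k, k, fill::zeros));
  std::vector<vec> dTheta(np, vec(p, fill::zeros));
  std::vector<bool> is_mean(np, false), is_cov(np, false);
  for (int j = 0; j < k; ++j) {
    if (m.a_idx(j) > 0) { dAlpha[m.a_idx(j) - 1](j) += 1; is_mean[m.a_idx(j) - 1] = true; }
    for (int l = 0; l < q; ++l)
      if (m.G_idx(j, l) > 0) { dGamma[m.G_idx(j, l) - 1](j, l) += 1; is_mean[m.G_idx(j, l) - 1] = true; }
    for (int l = 0; l < k; ++l)
      if (m.P_idx(j, l) > 0) { dPsi[m.P_idx(j, l) - 1](j, l) += 1; is_cov[m.P_idx(j, l) - 1] = true; }
  }
  for (int j = 0; j < p; ++j)
    if (m.T_idx(j) > 0) { dTheta[m.T_idx(j) - 1](j) += 1; is_cov[m.T_idx(j) - 1] = true; }

  I.zeros(np, np);
  for (const Pattern& pa : pats) {
    if (pa.obs.n_elem == 0) continue;
    mat So = Sigma.submat(pa.obs, pa.obs);
    mat A;
    if (!inv_sympd(A, So)) return false;
    mat P = m.Lambda.rows(pa.obs);              // |o| x k
    double n = (double)pa.n;
    vec sx(q, fill::zeros);
    mat Sxx(q, q, fill::zeros);
    if (q > 0) { sx = sum(pa.X, 0).t(); Sxx = pa.X.t() * pa.X; }
    // mean block
    std::vector<vec> aj(np);
    std::vector<mat> Gj(np);
    for (int j = 0; j < np; ++j) {
      if (!is_mean[j]) continue;
      aj[j] = P * dAlpha[j];
      if (q > 0) Gj[j] = P * dGamma[j];
    }
    for (int j = 0; j < np; ++j) {
      if (!is_mean[j]) continue;
      vec Aaj = A * aj[j];
      mat AGj; if (q > 0) AGj = A * Gj[j];
      for (int l = j; l < np; ++l) {
        if (!is_mean[l]) continue;
        double v = n * dot(Aaj, aj[l]);
        if (q > 0) {
          v += dot(Aaj, Gj[l] * sx) + dot(aj[l], AGj * sx) +
               trace(Gj[l].t() * AGj * Sxx);
        }
        I(j, l) += v;
        if (l != j) I(l, j) += v;
      }
    }
    // covariance block
    std::vector<mat> AdS(np);
    for (int j = 0; j < np; ++j) {
      if (!is_cov[j]) continue;
      mat dS = P * dPsi[j] * P.t();
      for (uword a = 0; a < pa.obs.n_elem; ++a)
        dS(a, a) += dTheta[j](pa.obs(a));
      AdS[j] = A * dS;
    }
    for (int j = 0; j < np; ++j) {
      if (!is_cov[j]) continue;
      for (int l = j; l < np; ++l) {
        if (!is_cov[l]) continue;
        double v = 0.5 * n * trace(AdS[j] * AdS[l]);
        I(j, l) += v;
        if (l != j) I(l, j) += v;
      }
    }
  }
  return true;
}

static double fit_bfgs(const SemModel& m, const std::vector<Pattern>& pats,
                       vec& x, double tol_g, double tol_step, int maxit,
                       bool& conv, int& iters, double& gnorm) {
  const int np = m.npar;
  double fx = -sem_loglik(m, pats, x);
  conv = false; iters = 0; gnorm = datum::inf;
  if (!std::isfinite(fx)) return datum::inf;
  bool ok = true;
  vec g = -sem_grad(m, pats, x, ok);
  if (!ok || !g.is_finite()) return fx;
  // initial inverse-Hessian from the expected information at the start:
  // supplies the right scaling for parameters on very different scales
  mat H = eye(np, np);
  {
    mat Iexp;
    if (expected_information(m, pats, x, Iexp)) {
      mat Hi;
      if (inv_sympd(Hi, Iexp)) H = Hi;
    }
  }
  for (int it = 0; it < maxit; ++it) {
    iters = it;
    gnorm = norm(g, "inf");
    if (gnorm < tol_g) { conv = true; break; }
    vec d = -(H * g);
    if (dot(d, g) >= 0) { H = eye(np, np); d = -g; }
    double t = 1.0, fnew = datum::inf;
    vec xnew;
    double slope = dot(g, d);
    int ls;
    for (ls = 0; ls < 60; ++ls) {
      xnew = x + t * d;
      fnew = -sem_loglik(m, pats, xnew);
      if (std::isfinite(fnew) && fnew <= fx + 1e-4 * t * slope) break;
      t *= 0.5;
    }
    if (ls == 60) { conv = (gnorm < 1e-3); break; }
    vec s_step = xnew - x;
    bool ok2 = true;
    vec gnew = -sem_grad(m, pats, xnew, ok2);
    if (!ok2 || !gnew.is_finite()) { x = xnew; fx = fnew; break; }
    vec yv = gnew - g;
    double sy = dot(s_step, yv);
    if (sy > 1e-12) {
      vec Hy = H * yv;
      double yHy = dot(yv, Hy);
      double rho = 1.0 / sy;
      H += (sy + yHy) * rho * rho * (s_step * s_step.t())
           - rho * (Hy * s_step.t() + s_step * Hy.t());
    }
    x = xnew; fx = fnew; g = gnew;
    if (norm(s_step, "inf") < tol_step) { conv = true; break; }
  }
  gnorm = norm(g, "inf");
  return fx;
}

// [[Rcpp::export]]
Rcpp::List cpp_voxel_pipeline(const arma::mat& y, const arma::mat& X,
                              const Rcpp::List& model,
                              const Rcpp::List& groups,
                              const arma::mat& starts,
                              double tol_g = 1e-6, double tol_step = 1e-9,
                              int maxit = 500,
                              double em_tol = 1e-9, int em_maxit = 500,
                              bool do_em = true) {
  SemModel m = as_model(model);
  const int n = y.n_rows, Tn = y.n_cols, q = X.n_cols;
  const int d = Tn + q;

  // build conditional patterns by slicing y
  std::vector<Pattern> pats;
  std::vector<uvec> rows_list;
  for (int i = 0; i < groups.size(); ++i) {
    Rcpp::List g = groups[i];
    uvec rows = Rcpp::as<uvec>(g["rows"]);   // 1-based
    rows -= 1;
    uvec obs = Rcpp::as<uvec>(g["obs0"]);    // 0-based
    Pattern pa;
    pa.obs = obs;
    pa.Y = y.submat(rows, obs);
    pa.X = X.rows(rows);
    pa.n = rows.n_elem;
    pats.push_back(pa);
    rows_list.push_back(rows);
  }

  // multi-start BFGS
  vec best_x(m.npar, fill::zeros);
  double best_f = datum::inf;
  bool best_conv = false;
  int best_iter = 0;
  double best_gn = datum::inf;
  for (unsigned int s = 0; s < starts.n_cols; ++s) {
    vec x = starts.col(s);
    bool conv; int it; double gn;
    double f = fit_bfgs(m, pats, x, tol_g, tol_step, maxit, conv, it, gn);
    bool better = (conv && !best_conv) ||
                  (conv == best_conv && f < best_f - 1e-10);
    if (better) { best_x = x; best_f = f; best_conv = conv;
                  best_iter = it; best_gn = gn; }
  }

  // observed-information standard errors
  vec ses(m.npar, fill::value(datum::nan));
  if (best_conv) {
    mat Hm(m.npar, m.npar, fill::zeros);
    bool okH = true;
    for (int j = 0; j < m.npar && okH; ++j) {
      double hj = 1e-5 * (std::abs(best_x(j)) + 1.0);
      vec pp = best_x, pm = best_x;
      pp(j) += hj; pm(j) -= hj;
      bool o1 = true, o2 = true;
      vec gp = -sem_grad(m, pats, pp, o1);
      vec gm = -sem_grad(m, pats, pm, o2);
      if (!o1 || !o2) { okH = false; break; }
      Hm.col(j) = (gp - gm) / (2.0 * hj);
    }
    if (okH) {
      Hm = 0.5 * (Hm + Hm.t());
      mat Vc;
      if (inv(Vc, Hm)) {
        vec dg = Vc.diag();
        for (int j = 0; j < m.npar; ++j)
          ses(j) = dg(j) > 0 ? std::sqrt(dg(j)) : datum::nan;
      }
    }
  }

  // saturated EM over the joint (y, X) vector, warm-started at the
  // pairwise-complete moments
  double ll_sat = datum::nan;
  mat sat_sigma;
  double ll_base_y = datum::nan;
  if (do_em) {
  vec muz(d, fill::zeros);
  mat Sz(d, d, fill::zeros);
  {
    mat Z(n, d);
    Z.cols(0, Tn - 1) = y;
    if (q > 0) Z.cols(Tn, d - 1) = X;
    umat obsm(n, d);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < d; ++j) obsm(i, j) = std::isfinite(Z(i, j));
    for (int j = 0; j < d; ++j) {
      double s = 0; int c = 0;
      for (int i = 0; i < n; ++i) if (obsm(i, j)) { s += Z(i, j); ++c; }
      muz(j) = s / std::max(c, 1);
    }
    for (int j = 0; j < d; ++j)
      for (int l = j; l < d; ++l) {
        double s = 0; int c = 0;
        for (int i = 0; i < n; ++i)
          if (obsm(i, j) && obsm(i, l)) {
            s += (Z(i, j) - muz(j)) * (Z(i, l) - muz(l)); ++c;
          }
        double v = c > 2 ? s / c : 0.0;
        Sz(j, l) = v; Sz(l, j) = v;
      }
    mat L;
    if (!chol(L, Sz, "lower")) {
      vec dg = Sz.diag();
      Sz = diagmat(clamp(dg, 1e-8, datum::inf));
    }
  }
  // joint patterns: observed outcomes plus all covariates
  std::vector<ZPattern> zpats;
  for (size_t i = 0; i < pats.size(); ++i) {
    ZPattern zp;
    uvec obs_j(pats[i].obs.n_elem + q);
    for (uword a = 0; a < pats[i].obs.n_elem; ++a) obs_j(a) = pats[i].obs(a);
    for (int a = 0; a < q; ++a) obs_j(pats[i].obs.n_elem + a) = Tn + a;
    zp.obs = obs_j;
    zp.Z = join_rows(pats[i].Y, pats[i].X);
    zp.n = pats[i].n;
    zpats.push_back(zp);
  }
  {
    vec mu = muz;
    mat Sg = Sz;
    double ll_old = -datum::inf;
    bool fail = false;
    uvec allv = regspace<uvec>(0, d - 1);
    for (int it = 0; it < em_maxit; ++it) {
      vec Ez(d, fill::zeros);
      mat Ezz(d, d, fill::zeros);
      double ll = 0.0;
      for (const ZPattern& pa : zpats) {
        uvec o = pa.obs;
        std::vector<uword> mv;
        uvec is_obs(d, fill::zeros);
        for (uword j = 0; j < o.n_elem; ++j) is_obs(o(j)) = 1;
        for (int j = 0; j < d; ++j) if (!is_obs(j)) mv.push_back(j);
        uvec mm(mv);
        mat So = Sg.submat(o, o);
        mat L;
        if (!chol(L, So, "lower")) { fail = true; break; }
        double logdet = 2.0 * accu(log(L.diag()));
        mat R = pa.Z.t();
        R.each_col() -= mu.elem(o);
        mat Zs = solve(trimatl(L), R);
        ll += -0.5 * (pa.n * (o.n_elem * LOG2PI + logdet) + accu(Zs % Zs));
        mat Zo = pa.Z;
        vec co = sum(Zo, 0).t();
        for (uword a = 0; a < o.n_elem; ++a) Ez(o(a)) += co(a);
        mat ZtZ = Zo.t() * Zo;
        for (uword a = 0; a < o.n_elem; ++a)
          for (uword b = 0; b < o.n_elem; ++b)
            Ezz(o(a), o(b)) += ZtZ(a, b);
        if (mm.n_elem > 0) {
          mat Som_inv_R = solve(trimatl(L).t(), Zs);
          mat Smo = Sg.submat(mm, o);
          mat Cm = repmat(mu.elem(mm), 1, pa.n) + Smo * Som_inv_R;
          mat Cmm = Sg.submat(mm, mm) - Smo * solve(So, Sg.submat(o, mm));
          vec cm = sum(Cm, 1);
          for (uword a = 0; a < mm.n_elem; ++a) Ez(mm(a)) += cm(a);
          mat Mo = Cm * Zo;
          for (uword a = 0; a < mm.n_elem; ++a)
            for (uword b = 0; b < o.n_elem; ++b) {
              Ezz(mm(a), o(b)) += Mo(a, b);
              Ezz(o(b), mm(a)) += Mo(a, b);
            }
          mat Mmm = Cm * Cm.t() + ((double)pa.n) * Cmm;
          for (uword a = 0; a < mm.n_elem; ++a)
            for (uword b = 0; b < mm.n_elem; ++b)
              Ezz(mm(a), mm(b)) += Mmm(a, b);
        }
      }
      if (fail) break;
      vec mu_new = Ez / (double)n;
      mat S_new = Ezz / (double)n - mu_new * mu_new.t();
      mu = mu_new;
      Sg = 0.5 * (S_new + S_new.t());
      if (std::isfinite(ll) &&
          std::abs(ll - ll_old) < em_tol * (std::abs(ll) + 1.0)) break;
      ll_old = ll;
    }
    if (!fail) {
      ll_sat = mvn_pattern_loglik(zpats, mu, Sg);
      sat_sigma = Sg;
    }
  }

  // independence baseline over the outcomes (covariate part added in R)
  ll_base_y = 0.0;
  for (int t = 0; t < Tn; ++t) {
    double s = 0; int c = 0;
    for (int i = 0; i < n; ++i) if (std::isfinite(y(i, t))) { s += y(i, t); ++c; }
    double mu_t = s / std::max(c, 1);
    double ss = 0;
    for (int i = 0; i < n; ++i)
      if (std::isfinite(y(i, t))) ss += (y(i, t) - mu_t) * (y(i, t) - mu_t);
    double s2 = ss / std::max(c, 1);
    ll_base_y += -0.5 * c * (LOG2PI + std::log(s2) + 1.0);
  }
  } // do_em

  return Rcpp::List::create(
    Rcpp::Named("par") = best_x,
    Rcpp::Named("loglik") = -best_f,
    Rcpp::Named("converged") = best_conv,
    Rcpp::Named("iterations") = best_iter,
    Rcpp::Named("grad_norm") = best_gn,
    Rcpp::Named("ses") = ses,
    Rcpp::Named("ll_sat") = ll_sat,
    Rcpp::Named("sat_sigma") = sat_sigma,
    Rcpp::Named("ll_base_y") = ll_base_y);
}

// model-implied covariance of the joint (outcomes, covariates) vector at
// given parameter values, with the covariate block saturated at x_cov
// [[Rcpp::export]]
arma::mat cpp_implied_cov(const arma::vec& par, const Rcpp::List& model,
                          const arma::mat& x_cov) {
  SemModel m = as_model(model);
  vec alpha, theta; mat Gamma, B, Psi;
  build_matrices(m, par, alpha, Gamma, B, Psi, theta);
  const int k = m.Lambda.n_cols, p = m.Lambda.n_rows, q = x_cov.n_rows;
  mat LamM = m.Lambda;
  if (m.has_B) {
    mat Minv;
    if (!inv(Minv, eye(k, k) - B)) Rcpp::stop("I - B is singular");
    LamM = m.Lambda * Minv;
  }
  mat inner = Psi;
  if (q > 0) inner += Gamma * x_cov * Gamma.t();
  mat Syy = LamM * inner * LamM.t();
  Syy.diag() += theta;
  mat out(p + q, p + q);
  out.submat(0, 0, p - 1, p - 1) = Syy;
  if (q > 0) {
    mat Syx = LamM * Gamma * x_cov;
    out.submat(0, p, p - 1, p + q - 1) = Syx;
    out.submat(p, 0, p + q - 1, p - 1) = Syx.t();
    out.submat(p, p, p + q - 1, p + q - 1) = x_cov;
  }
  return out;
}

// flood-fill style connected-component labelling on a 3D binary array,
// configurable neighbourhood (6, 18 or 26)
// [[Rcpp::export]]
arma::icube cpp_label_components(const arma::icube& maskc, int connectivity) {
  const int nx = maskc.n_rows, ny = maskc.n_cols, nz = maskc.n_slices;
  icube lab(nx, ny, nz, fill::zeros);
  std::vector<std::array<int, 3>> nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<std::array<int, 3>> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (maskc(x, y, z) == 0 || lab(x, y, z) != 0) continue;
        ++next;
        stack.clear();
        stack.push_back({x, y, z});
        lab(x, y, z) = next;
        while (!stack.empty()) {
          auto v = stack.back(); stack.pop_back();
          for (auto& d : nb) {
            int ax = v[0] + d[0], ay = v[1] + d[1], az = v[2] + d[2];
            if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
              continue;
            if (maskc(ax, ay, az) != 0 && lab(ax, ay, az) == 0) {
              lab(ax, ay, az) = next;
              stack.push_back({ax, ay, az});
            }
          }
        }
      }
  return lab;
}
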