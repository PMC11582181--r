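// Particle-filter and MIF2 inner loops.
//
// Conventions shared with the R level:
//  - states are column-major p-vectors; vec() stacking is column-major;
//  - innovation variances come from the unit-marginal-variance
//    identification solve (closed form at p = 2, Armadillo fallback);
//  - measurement kind 0 = graded response, 1 = linear-Gaussian;
//  - all randomness flows from a single integer seed supplied by the R
//    wrappers (which draw it from the session RNG), through a portable
//    xoshiro256++ generator, so runs are reproducible across platforms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG ----
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {  // polar Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// ------------------------------------------------- identification solve ----
// Unit-marginal-variance constraint: given stationary A, find diagonal
// innovation variances sigma (and marginal covariance Gamma with unit
// diagonal) satisfying Gamma = A Gamma A' + Sigma. Returns false when A is
// non-stationary or the implied variances are not strictly positive.
// p = 2 closed form on a raw column-major pointer; writes gamma12 and the
// two innovation variances. Returns false when A is non-stationary or the
// constraint is infeasible.
inline bool identify2(const double* th, double& g, double& s1, double& s2,
                      double tol = 1e-8) {
  const double a = th[0], c = th[1], b = th[2], d = th[3];
  const double tr = a + d, det = a * d - b * c;
  const double disc = tr * tr - 4.0 * det;
  double rho;
  if (disc >= 0.0) {
    const double sq = std::sqrt(disc);
    rho = std::max(std::fabs(0.5 * (tr + sq)), std::fabs(0.5 * (tr - sq)));
  } else {
    rho = std::sqrt(det);
  }
  if (!(rho < 1.0 - 1e-12)) return false;
  const double den = 1.0 - a * d - b * c;
  if (std::fabs(den) < 1e-12) return false;
  g = (a * c + b * d) / den;
  if (!(std::fabs(g) < 1.0 - tol)) return false;
  s1 = 1.0 - a * a - b * b - 2.0 * a * b * g;
  s2 = 1.0 - c * c - d * d - 2.0 * c * d * g;
  return (s1 > tol) && (s2 > tol);
}

bool identify_inno(const arma::mat& A, arma::mat& Gamma, arma::vec& sigma,
                   double tol = 1e-8) {
  const arma::uword p = A.n_rows;
  if (p == 2) {
    double g, s1, s2;
    if (!identify2(A.memptr(), g, s1, s2, tol)) return false;
    Gamma = {{1.0, g}, {g, 1.0}};
    sigma = {s1, s2};
    return true;
  }
  // general small-p path
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, A)) return false;
  if (arma::abs(ev).max() >= 1.0 - 1e-12) return false;
  const arma::uword p2 = p * p;
  arma::mat M = arma::eye(p2, p2) - arma::kron(A, A);
  arma::uvec dpos(p), opos(p2 - p);
  arma::uword k = 0;
  for (arma::uword j = 0; j < p; ++j)
    for (arma::uword i = 0; i < p; ++i) {
      const arma::uword pos = j * p + i;
      if (i == j) dpos(j) = pos; else opos(k++) = pos;
    }
  arma::vec cvec = arma::zeros(p2);
  cvec.elem(dpos).ones();
  arma::mat Mo = M.rows(opos);
  arma::mat lhs = Mo.cols(opos);
  arma::vec rhs = Mo * cvec;
  arma::vec off;
  if (!arma::solve(off, lhs, -rhs)) return false;
  arma::vec vecG = cvec;
  vecG.elem(opos) = off;
  Gamma = arma::reshape(vecG, p, p);
  Gamma = 0.5 * (Gamma + Gamma.t());
  arma::vec vecS = M * arma::vectorise(Gamma);
  sigma = vecS.elem(dpos);
  if (sigma.min() <= tol) return false;
  arma::vec gev;
  if (!arma::eig_sym(gev, Gamma) || gev.min() <= tol) return false;
  return true;
}

// --------------------------------------------------------- measurement ----
struct Measurement {
  int kind;                 // 0 grm, 1 linear
  arma::ivec state_idx;     // 0-based selector per item
  arma::vec alpha;          // grm
  arma::vec beta;           // grm, flattened thresholds
  arma::ivec beta_ptr;      // grm, item i occupies [ptr[i], ptr[i+1])
  arma::vec loading;        // linear
  arma::vec error_var;      // linear
  arma::vec center;         // linear
};

inline double inv_logit(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// log P(y = cat | x) for a graded response item with thresholds b[0..nb-1]
inline double grm_logp(int cat, double x, double a, const double* b, int nb) {
  const double upper =
      (cat >= 2) ? inv_logit(a * (x - b[cat - 2])) : 1.0;
  const double lower =
      (cat <= nb) ? inv_logit(a * (x - b[cat - 1])) : 0.0;
  const double pr = upper - lower;
  return (pr > 0.0) ? std::log(pr) : -INFINITY;
}

// measurement log-likelihood of row t of y given state x (columns of y with
// NaN are treated as missing); beta may point at per-particle thresholds
inline double meas_loglik(const Measurement& m, const double* beta,
                          const arma::vec& loading, const arma::vec& lpsi_sd,
                          const arma::mat& y, arma::uword t, const double* x) {
  double ll = 0.0;
  const arma::uword q = m.state_idx.n_elem;
  if (m.kind == 0) {
    for (arma::uword i = 0; i < q; ++i) {
      const double yi = y(t, i);
      if (std::isnan(yi)) continue;
      const int nb = m.beta_ptr(i + 1) - m.beta_ptr(i);
      ll += grm_logp(static_cast<int>(yi), x[m.state_idx(i)], m.alpha(i),
                     beta + m.beta_ptr(i), nb);
      if (ll == -INFINITY) return ll;
    }
  } else {
    for (arma::uword i = 0; i < q; ++i) {
      const double yi = y(t, i);
      if (std::isnan(yi)) continue;
      const double sd = lpsi_sd(i);
      const double z = (yi - m.center(i) - loading(i) * x[m.state_idx(i)]) / sd;
      ll += -0.5 * z * z - std::log(sd) - 0.918938533204672742;  // log sqrt(2 pi)
    }
  }
  return ll;
}

Measurement make_measurement(int kind, const arma::ivec& state_idx,
                             const arma::vec& alpha, const arma::vec& beta,
                             const arma::ivec& beta_ptr, const arma::vec& loading,
                             const arma::vec& error_var, const arma::vec& center) {
  Measurement m;
  m.kind = kind;
  m.state_idx = state_idx;
  m.alpha = alpha;
  m.beta = beta;
  m.beta_ptr = beta_ptr;
  m.loading = loading;
  m.error_var = error_var;
  m.center = center;
  return m;
}

// ----------------------------------------------------------- resampling ----
// systematic: one uniform per timepoint, stratified positions
inline void systematic_resample(const arma::vec& w, arma::uvec& idx, Xoshiro& rng) {
  const arma::uword K = w.n_elem;
  const double u0 = rng.unif();
  double cum = w(0);
  arma::uword j = 0;
  for (arma::uword i = 0; i < K; ++i) {
    const double target = (i + u0) / K;
    while (cum < target && j + 1 < K) cum += w(++j);
    idx(i) = j;
  }
}

inline void multinomial_resample(const arma::vec& w, arma::uvec& idx, Xoshiro& rng) {
  const arma::uword K = w.n_elem;
  arma::vec cw = arma::cumsum(w);
  for (arma::uword i = 0; i < K; ++i) {
    const double u = rng.unif();
    arma::uword lo = 0, hi = K - 1;
    while (lo < hi) {
      const arma::uword mid = (lo + hi) / 2;
      if (cw(mid) < u) lo = mid + 1; else hi = mid;
    }
    idx(i) = lo;
  }
}

// normalize log-weights in place into w; returns log-mean-weight, or -inf
// when every particle is impossible
inline double normalize_weights(const arma::vec& logw, arma::vec& w) {
  const double mx = logw.max();
  if (mx == -INFINITY) return -INFINITY;
  w = arma::exp(logw - mx);
  const double s = arma::accu(w);
  w /= s;
  return mx + std::log(s / logw.n_elem);
}

}  // namespace

// ----------------------------------------------------------------------
// Fast identification solve (same contract as the R reference
// implementation; used by tests to check the two agree).
// [[Rcpp::export]]
List identify_cpp(const arma::mat& A) {
  arma::mat Gamma;
  arma::vec sigma;
  const bool ok = identify_inno(A, Gamma, sigma);
  if (!ok) return List::create(Named("feasible") = false);
  return List::create(Named("feasible") = true, Named("Gamma") = Gamma,
                      Named("sigma") = sigma);
}

// ----------------------------------------------------------------------
// Bootstrap particle filter at fixed parameters.
// y: T x q with NaN for missing. sigma: innovation variances (length p).
// Returns filtered means (pre-resampling weighted averages), the
// log-likelihood estimate (sum of per-timepoint log-mean-weights) and the
// effective-sample-size trace.
// [[Rcpp::export]]
List pf_cpp(const arma::mat& y, int kind, const arma::ivec& state_idx,
            const arma::vec& alpha, const arma::vec& beta,
            const arma::ivec& beta_ptr, const arma::vec& loading,
            const arma::vec& error_var, const arma::vec& center,
            const arma::mat& A, const arma::vec& sigma, int K, double seed,
            int scheme = 0, bool sigma_zero = false) {
  const arma::uword T = y.n_rows, p = A.n_rows;
  Measurement m = make_measurement(kind, state_idx, alpha, beta, beta_ptr,
                                   loading, error_var, center);
  arma::vec lpsi_sd = (kind == 1) ? arma::sqrt(error_var) : arma::vec();
  Xoshiro rng(static_cast<uint64_t>(seed));
  arma::mat X(p, K);
  for (arma::uword k = 0; k < (arma::uword)K; ++k)
    for (arma::uword d = 0; d < p; ++d) X(d, k) = rng.norm();  // f0 = N(0, I)
  arma::vec sdv = arma::sqrt(sigma);
  if (sigma_zero) sdv.zeros();
  arma::mat fm(T, p, arma::fill::zeros);
  arma::vec ess(T), logw(K), w(K);
  arma::uvec idx(K);
  double loglik = 0.0;
  arma::vec xnew(p);
  for (arma::uword t = 0; t < T; ++t) {
    for (arma::uword k = 0; k < (arma::uword)K; ++k) {
      xnew = A * X.col(k);
      for (arma::uword d = 0; d < p; ++d) xnew(d) += sdv(d) * rng.norm();
      X.col(k) = xnew;
      logw(k) = meas_loglik(m, m.beta.memptr(), m.loading, lpsi_sd, y, t,
                            X.colptr(k));
    }
    const double lmw = normalize_weights(logw, w);
    if (lmw == -INFINITY)
      stop("Particle degeneracy: all particles impossible at timepoint %d.",
           (int)t + 1);
    loglik += lmw;
    fm.row(t) = (X * w).t();
    ess(t) = 1.0 / arma::accu(arma::square(w));
    if (scheme == 0) systematic_resample(w, idx, rng);
    else multinomial_resample(w, idx, rng);
    X = X.cols(idx);
  }
  return List::create(Named("filtered_means") = fm, Named("loglik") = loglik,
                      Named("ess") = ess);
}

// ----------------------------------------------------------------------
// One MIF2 run.
//
// Parameter vector layout (estimation scale), shared with the R encoder:
//   theta[0 .. p*p-1]            vec(A), column-major
//   then, when est_meas is true:
//     grm:    per item: first threshold, then log-intervals (J_i - 1 slots)
//     linear: q loadings, then q log error variances
//
// Each iteration re-initializes states from N(0, I), perturbs every
// particle's parameters with N(0, diag(sd_m^2)) at every timepoint,
// propagates states under the particle's decoded dynamics with the
// identification-implied innovation variances, weights by the measurement
// likelihood, and resamples states and parameters with a common index
// vector. Infeasible decodes (non-stationary A or impossible innovation
// variances) get log-weight -inf. The run estimate is the mean of the
// final iteration's parameter swarm.
// [[Rcpp::export]]
List mif2_cpp(const arma::mat& y, int kind, const arma::ivec& state_idx,
              const arma::vec& alpha, const arma::vec& beta0,
              const arma::ivec& beta_ptr, const arma::vec& loading0,
              const arma::vec& error_var0, const arma::vec& center, int p,
              const arma::vec& theta_init, bool est_meas,
              const arma::vec& perturb_sd, int K, int M,
              double cooling_fraction_50, bool cooling_on_sd, double seed,
              int scheme = 0, int perturb_every = 0) {
  const arma::uword T = y.n_rows, q = y.n_cols;
  const arma::uword np = theta_init.n_elem;
  const arma::uword nA = (arma::uword)p * p;
  Measurement m = make_measurement(kind, state_idx, alpha, beta0, beta_ptr,
                                   loading0, error_var0, center);
  Xoshiro rng(static_cast<uint64_t>(seed));

  arma::mat TH(np, K);
  TH.each_col() = theta_init;
  arma::mat X(p, K);
  arma::mat Xbuf(p, K), THbuf(np, K);
  arma::vec logw(K), w(K);
  arma::uvec idx(K);
  arma::vec trace(M);
  arma::mat swarm_mean(M, np);
  double n_infeasible = 0.0;

  // per-particle decoded workspaces
  arma::mat A(p, p);
  arma::mat Gamma;
  arma::vec sigma, sdv(p);
  arma::vec beta_work = beta0;       // decoded thresholds (grm)
  arma::vec load_work = loading0;    // decoded loadings (linear)
  arma::vec sd_work =
      (kind == 1) ? arma::sqrt(error_var0) : arma::vec();
  arma::vec xnew(p);

  const double expo = cooling_on_sd ? 50.0 : 100.0;

  for (int it = 0; it < M; ++it) {
    const double cool = std::pow(cooling_fraction_50, it / expo);
    arma::vec sd_m = perturb_sd * cool;
    // fresh state swarm from f0 each iteration
    for (arma::uword k = 0; k < (arma::uword)K; ++k)
      for (int d = 0; d < p; ++d) X(d, k) = rng.norm();
    if (perturb_every == 1) {  // once per iteration
      for (arma::uword k = 0; k < (arma::uword)K; ++k) {
        double* th = TH.colptr(k);
        for (arma::uword j = 0; j < np; ++j)
          if (sd_m(j) > 0.0) th[j] += sd_m(j) * rng.norm();
      }
    }
    double ll = 0.0;
    for (arma::uword t = 0; t < T; ++t) {
      for (arma::uword k = 0; k < (arma::uword)K; ++k) {
        double* th = TH.colptr(k);
        if (perturb_every == 0)
          for (arma::uword j = 0; j < np; ++j)
            if (sd_m(j) > 0.0) th[j] += sd_m(j) * rng.norm();
        // decode A, solve the identification constraint, propagate
        double* xk = X.colptr(k);
        bool ok;
        if (p == 2) {
          double g, s1, s2;
          ok = identify2(th, g, s1, s2);
          if (ok) {
            const double x0 = xk[0], x1 = xk[1];
            xk[0] = th[0] * x0 + th[2] * x1 + std::sqrt(s1) * rng.norm();
            xk[1] = th[1] * x0 + th[3] * x1 + std::sqrt(s2) * rng.norm();
          }
        } else {
          A = arma::reshape(arma::vec(th, nA), p, p);
          ok = identify_inno(A, Gamma, sigma);
          if (ok) {
            xnew = A * X.col(k);
            for (int d = 0; d < p; ++d)
              xnew(d) += std::sqrt(sigma(d)) * rng.norm();
            X.col(k) = xnew;
          }
        }
        if (!ok) {
          logw(k) = -INFINITY;
          n_infeasible += 1.0;
          continue;
        }
        // decode measurement parameters
        const double* bptr = m.beta.memptr();
        if (est_meas && kind == 0) {
          arma::uword pos = nA;
          for (arma::uword i = 0; i < q; ++i) {
            const int nb = m.beta_ptr(i + 1) - m.beta_ptr(i);
            double b = th[pos++];
            beta_work(m.beta_ptr(i)) = b;
            for (int j = 1; j < nb; ++j) {
              b += std::exp(th[pos++]);
              beta_work(m.beta_ptr(i) + j) = b;
            }
          }
          bptr = beta_work.memptr();
        } else if (est_meas && kind == 1) {
          for (arma::uword i = 0; i < q; ++i) {
            load_work(i) = th[nA + i];
            sd_work(i) = std::exp(0.5 * th[nA + q + i]);
          }
        }
        logw(k) = meas_loglik(m, bptr, load_work, sd_work, y, t, xk);
      }
      const double lmw = normalize_weights(logw, w);
      if (lmw == -INFINITY)
        stop("MIF2 degeneracy: all particles impossible at iteration %d, timepoint %d.",
             it + 1, (int)t + 1);
      ll += lmw;
      if (scheme == 0) systematic_resample(w, idx, rng);
      else multinomial_resample(w, idx, rng);
      for (arma::uword i = 0; i < (arma::uword)K; ++i) {
        Xbuf.col(i) = X.col(idx(i));
        THbuf.col(i) = TH.col(idx(i));
      }
      X.swap(Xbuf);
      TH.swap(THbuf);
    }
    trace(it) = ll;
    swarm_mean.row(it) = arma::mean(TH, 1).t();
  }
  return List::create(Named("estimate") = arma::vec(arma::mean(TH, 1)),
                      Named("trace") = trace,
                      Named("swarm_mean") = swarm_mean,
                      Named("n_infeasible") = n_infeasible);
}
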