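// Numerical core: matrix exponentials (scaling-and-squaring Pade via
// arma::expmat), the augmented-matrix ENS integral, triad site-pattern
// probabilities, and the negative log-likelihoods used by the optimiser.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".expm_cpp")]]
arma::mat expm_cpp(const arma::mat& M) {
  return expmat(M);
}

// ENS over [0, t] for initial distribution f0 and generator Q, by the
// 5x5 augmented construction C = [Q, -diag(Q); 0, 0]:
// n(t) = f0 . exp(Ct)[1:4, 5].
static double ens_aug(const rowvec& f0, const mat& Q, double t) {
  mat C(5, 5, fill::zeros);
  C.submat(0, 0, 3, 3) = Q;
  C.submat(0, 4, 3, 4) = -Q.diag();
  mat E = expmat(C * t);
  return dot(f0.t(), E.submat(0, 4, 3, 4));
}

// [[Rcpp::export(name = ".ens_aug_cpp")]]
double ens_aug_cpp(const arma::rowvec& f0, const arma::mat& Q, double t) {
  return ens_aug(f0, Q, t);
}

// ENS of the scaled generator s*M over a unit interval, i.e.
// g(s) = -f0 (int_0^s e^{Mv} dv) diag(M), evaluated through the
// eigendecomposition of M when it is well conditioned.  Used by the
// clock constraint, where the duration of one ingroup edge is solved so
// that its ENS matches the other ingroup edge.
struct EnsEig {
  bool ok;
  cx_rowvec w;   // f0 * V
  cx_vec y;      // V^{-1} * diag(M)
  cx_vec lam;
};

static EnsEig ens_eig_setup(const rowvec& f0, const mat& M) {
  EnsEig e;
  e.ok = false;
  cx_vec eigval;
  cx_mat V;
  if (!eig_gen(eigval, V, M)) return e;
  if (rcond(V) < 1e-10) return e;
  cx_mat Vi = inv(V);
  e.w = conv_to<cx_rowvec>::from(f0) * V;
  e.y = Vi * conv_to<cx_vec>::from(M.diag());
  e.lam = eigval;
  e.ok = true;
  return e;
}

static double ens_eig_eval(const EnsEig& e, double s) {
  cx_double acc(0.0, 0.0);
  for (uword i = 0; i < 4; ++i) {
    cx_double lam = e.lam(i);
    cx_double phi = (std::abs(lam) < 1e-12) ? cx_double(s, 0.0)
                                            : (std::exp(lam * s) - 1.0) / lam;
    acc += e.w(i) * phi * e.y(i);
  }
  return -acc.real();
}

// Solve ens(f0, s*M) = target for the scalar s >= 0 (monotone in s).
// [[Rcpp::export(name = ".ens_solve_scale_cpp")]]
double ens_solve_scale_cpp(const arma::rowvec& f0, const arma::mat& M,
                           double target) {
  if (target <= 0.0) return 0.0;
  EnsEig e = ens_eig_setup(f0, M);
  auto g = [&](double s) {
    return e.ok ? ens_eig_eval(e, s) : ens_aug(f0, M, s);
  };
  double hi = 1.0;
  int guard = 0;
  while (g(hi) < target && guard++ < 80) hi *= 2.0;
  double lo = 0.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (g(mid) < target) lo = mid; else hi = mid;
    if (hi - lo < 1e-12 * std::max(1.0, hi)) break;
  }
  return 0.5 * (lo + hi);
}

// Site-pattern probabilities for the rooted 3-edge star: leaves a, b, c
// with transition matrices Pa, Pb, Pc from the root, root distribution f0.
// Pattern index is row-major over (a, b, c) in state order A,C,G,T.
static vec triad_probs(const rowvec& f0, const mat& Pa, const mat& Pb,
                       const mat& Pc) {
  vec p(64, fill::zeros);
  for (int r = 0; r < 4; ++r) {
    double w = f0(r);
    if (w == 0.0) continue;
    int idx = 0;
    for (int i = 0; i < 4; ++i) {
      double wa = w * Pa(r, i);
      for (int j = 0; j < 4; ++j) {
        double wb = wa * Pb(r, j);
        for (int k = 0; k < 4; ++k) p(idx++) += wb * Pc(r, k);
      }
    }
  }
  return p;
}

// [[Rcpp::export(name = ".triad_probs_cpp")]]
arma::vec triad_probs_cpp(const arma::rowvec& f0, const arma::mat& Pa,
                          const arma::mat& Pb, const arma::mat& Pc) {
  return triad_probs(f0, Pa, Pb, Pc);
}

static rowvec softmax4(double b1, double b2, double b3) {
  rowvec z = {0.0, b1, b2, b3};
  z -= z.max();
  rowvec e = exp(z);
  return e / accu(e);
}

// Guarded negative log likelihood accumulation: any non-finite or invalid
// pattern probability (e.g. from an overflowing matrix exponential at an
// extreme parameter point) repels the optimiser instead of poisoning it.
static double negll_from_probs(const vec& probs, const vec& counts) {
  double ll = 0.0;
  for (int i = 0; i < 64; ++i) {
    double p = probs(i);
    if (!std::isfinite(p) || p < -1e-9 || p > 1.0 + 1e-9) return 1e10;
    if (counts(i) > 0.0) {
      if (p <= 0.0) return 1e10;
      ll += counts(i) * std::log(p);
    }
  }
  return -ll;
}

// Equal-probability discrete-gamma bin means (mean-one Gamma(a, rate a)).
static vec gamma_bin_rates(double shape, int nbins) {
  vec r(nbins);
  double prev_q = 0.0, prev_F = 0.0;
  for (int k = 1; k <= nbins; ++k) {
    double q = (k == nbins) ? datum::inf
                            : R::qgamma((double)k / nbins, shape, 1.0 / shape, 1, 0);
    double F = (k == nbins) ? 1.0
                            : R::pgamma(q, shape + 1.0, 1.0 / shape, 1, 0);
    r(k - 1) = nbins * (F - prev_F);
    prev_q = q;
    prev_F = F;
  }
  (void)prev_q;
  return r;
}

// [[Rcpp::export(name = ".gamma_bin_rates_cpp")]]
arma::vec gamma_bin_rates_cpp(double shape, int nbins) {
  return gamma_bin_rates(shape, nbins);
}

// Build the calibrated GTR generator from 5 log exchangeabilities
// (AC, AG, AT, CG, CT; GT fixed at 1) and 3 frequency logits (C, G, T
// against baseline A).
static void gtr_build(const vec& par, mat& Q, rowvec& pi) {
  double rAC = std::exp(par(0)), rAG = std::exp(par(1)), rAT = std::exp(par(2));
  double rCG = std::exp(par(3)), rCT = std::exp(par(4)), rGT = 1.0;
  pi = softmax4(par(5), par(6), par(7));
  mat R(4, 4, fill::zeros);
  R(0, 1) = R(1, 0) = rAC;
  R(0, 2) = R(2, 0) = rAG;
  R(0, 3) = R(3, 0) = rAT;
  R(1, 2) = R(2, 1) = rCG;
  R(1, 3) = R(3, 1) = rCT;
  R(2, 3) = R(3, 2) = rGT;
  Q.zeros(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      if (i != j) Q(i, j) = R(i, j) * pi(j);
  Q.diag() = -sum(Q, 1);
  double rate = -dot(pi.t(), Q.diag());
  Q /= rate;
}

// Negative log-likelihood of the GTR / GTR+Gamma triad model.
// par layout: 5 log rates, 3 freq logits, then edge log-durations
// (t_in shared + t_out when clock, else t_a, t_b, t_c), then log shape
// when gamma.
// [[Rcpp::export(name = ".gtr_negll_cpp")]]
double gtr_negll_cpp(const arma::vec& par, const arma::vec& counts,
                     bool clock, bool gamma, int nbins) {
  mat Q;
  rowvec pi;
  gtr_build(par, Q, pi);
  int ti = 8;
  double ta, tb, tc;
  if (clock) {
    ta = tb = std::exp(par(ti));
    tc = std::exp(par(ti + 1));
    ti += 2;
  } else {
    ta = std::exp(par(ti));
    tb = std::exp(par(ti + 1));
    tc = std::exp(par(ti + 2));
    ti += 3;
  }
  vec rates;
  if (gamma) {
    double shape = std::exp(par(ti));
    rates = gamma_bin_rates(shape, nbins);
  } else {
    rates = vec(1, fill::ones);
  }
  vec probs(64, fill::zeros);
  for (uword b = 0; b < rates.n_elem; ++b) {
    double r = rates(b);
    mat Pa = expmat(Q * (r * ta));
    mat Pb = expmat(Q * (r * tb));
    mat Pc = expmat(Q * (r * tc));
    if (!Pa.is_finite() || !Pb.is_finite() || !Pc.is_finite()) return 1e10;
    probs += triad_probs(pi, Pa, Pb, Pc) / rates.n_elem;
  }
  return negll_from_probs(probs, counts);
}

// Fill the off-diagonals of a generator row-major (A,C,G,T) from 12 log
// parameters; diagonal set so rows sum to zero.
static mat general_edge(const vec& par, int offset) {
  mat M(4, 4, fill::zeros);
  int idx = offset;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      if (i != j) M(i, j) = std::exp(par(idx++));
  M.diag() = -sum(M, 1);
  return M;
}

// Negative log-likelihood of the general nonstationary triad model.
// par layout: 3 root logits, then 12 log off-diagonals of the edge
// product matrix M = Q*t for edges a, b, c.  Under the clock the b-edge
// parameters give only the shape of M_b; its scale is solved so that the
// two ingroup edges have equal ENS.
// [[Rcpp::export(name = ".general_negll_cpp")]]
double general_negll_cpp(const arma::vec& par, const arma::vec& counts,
                         bool clock) {
  rowvec f0 = softmax4(par(0), par(1), par(2));
  mat Ma = general_edge(par, 3);
  mat Mb = general_edge(par, 15);
  mat Mc = general_edge(par, 27);
  if (clock) {
    double target = ens_aug(f0, Ma, 1.0);
    double s = ens_solve_scale_cpp(f0, Mb, target);
    Mb *= s;
  }
  mat Pa = expmat(Ma);
  mat Pb = expmat(Mb);
  mat Pc = expmat(Mc);
  if (!Pa.is_finite() || !Pb.is_finite() || !Pc.is_finite()) return 1e10;
  vec probs = triad_probs(f0, Pa, Pb, Pc);
  return negll_from_probs(probs, counts);
}
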