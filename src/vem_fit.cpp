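// Variational EM outer loop for the bipartite noisy SBM.
//
// Mirrors the reference R implementation in R/vem.R (e_step, m_step, elbo)
// exactly: per-block log mixture densities and edge responsibilities are
// recomputed from the current parameters at the start of every outer
// iteration, the membership fixed points run for a fixed number of inner
// sweeps with log-space row normalization, and the M-step uses the
// responsibilities at the pre-update parameters. Probabilities are clipped
// to [1e-10, 1 - 1e-10] before logs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PROB_EPS = 1e-10;

static inline double clip_prob(double p) {
  if (p < PROB_EPS) return PROB_EPS;
  if (p > 1.0 - PROB_EPS) return 1.0 - PROB_EPS;
  return p;
}

// sum_i sum_q beta[i,q] (log alpha[q] - log beta[i,q]) with 0 log 0 = 0
static double mem_term(const arma::mat& beta, const arma::vec& alpha) {
  double s = 0.0;
  for (arma::uword q = 0; q < beta.n_cols; ++q) {
    double la = std::log(clip_prob(alpha(q)));
    for (arma::uword i = 0; i < beta.n_rows; ++i) {
      double b = beta(i, q);
      if (b > 0.0) s += b * (la - std::log(b));
    }
  }
  return s;
}

static void row_softmax(arma::mat& logb, const char* axis) {
  for (arma::uword i = 0; i < logb.n_rows; ++i) {
    double m = logb.row(i).max();
    if (!std::isfinite(m)) {
      stop("non-finite membership update at %s %d", axis, (int)(i + 1));
    }
    double tot = 0.0;
    for (arma::uword q = 0; q < logb.n_cols; ++q) {
      double e = std::exp(logb(i, q) - m);
      logb(i, q) = e;
      tot += e;
    }
    logb.row(i) /= tot;
  }
}

// [[Rcpp::export(name = ".vem_fit_cpp")]]
List vem_fit_cpp(const arma::mat& xv, arma::vec alpha1, arma::vec alpha2,
                 arma::mat Pi, arma::mat mu, arma::mat sigma2,
                 double s0var, bool fix_null, arma::mat beta1,
                 arma::mat beta2, int max_outer, double rel_tol,
                 int inner_iter) {
  const arma::uword n1 = xv.n_rows, n2 = xv.n_cols;
  const arma::uword B1 = alpha1.n_elem, B2 = alpha2.n_elem;
  const arma::mat xv2 = arma::square(xv);
  arma::mat lg0 = -0.5 * std::log(2.0 * arma::datum::pi * s0var)
    - xv2 / (2.0 * s0var);
  arma::cube D(n1, n2, B1 * B2), R(n1, n2, B1 * B2);
  std::vector<double> trace;
  std::set<std::string> frozen;
  bool converged = false;
  double prev = arma::datum::nan;

  for (int it = 0; it < max_outer; ++it) {
    // log mixture densities and responsibilities at the current theta
    for (arma::uword q = 0; q < B1; ++q) {
      for (arma::uword l = 0; l < B2; ++l) {
        arma::uword k = q * B2 + l;
        double p = clip_prob(Pi(q, l));
        double lp = std::log(p), l1p = std::log1p(-p);
        double m_ql = mu(q, l), v = sigma2(q, l);
        double cst = -0.5 * std::log(2.0 * arma::datum::pi * v);
        double inv2v = 0.5 / v;
        arma::mat& Dk = D.slice(k);
        arma::mat& Rk = R.slice(k);
        for (arma::uword j = 0; j < n2; ++j) {
          for (arma::uword i = 0; i < n1; ++i) {
            double x = xv(i, j);
            double a = lp + cst - (x - m_ql) * (x - m_ql) * inv2v;
            double del = a - (l1p + lg0(i, j));
            // share exp(-|del|) between the sigmoid and the log-sum-exp
            double t = std::exp(-std::fabs(del));
            double denom = 1.0 + t;
            Rk(i, j) = (del >= 0.0) ? 1.0 / denom : t / denom;
            double mx = (del > 0.0) ? a : a - del;
            Dk(i, j) = mx + std::log1p(t);
          }
        }
      }
    }

    // E-step: alternating fixed-point sweeps
    arma::rowvec la1(B1), la2(B2);
    for (arma::uword q = 0; q < B1; ++q) la1(q) = std::log(clip_prob(alpha1(q)));
    for (arma::uword l = 0; l < B2; ++l) la2(l) = std::log(clip_prob(alpha2(l)));
    for (int s = 0; s < inner_iter; ++s) {
      arma::mat logb1 = arma::repmat(la1, n1, 1);
      for (arma::uword q = 0; q < B1; ++q) {
        for (arma::uword l = 0; l < B2; ++l) {
          logb1.col(q) += D.slice(q * B2 + l) * beta2.col(l);
        }
      }
      row_softmax(logb1, "row");
      beta1 = logb1;
      arma::mat logb2 = arma::repmat(la2, n2, 1);
      for (arma::uword q = 0; q < B1; ++q) {
        for (arma::uword l = 0; l < B2; ++l) {
          logb2.col(l) += D.slice(q * B2 + l).t() * beta1.col(q);
        }
      }
      row_softmax(logb2, "column");
      beta2 = logb2;
    }

    // ELBO at (theta, beta) with d-terms at the posterior responsibilities
    double el = mem_term(beta1, alpha1) + mem_term(beta2, alpha2);
    for (arma::uword q = 0; q < B1; ++q) {
      for (arma::uword l = 0; l < B2; ++l) {
        el += arma::as_scalar(beta1.col(q).t() *
                              (D.slice(q * B2 + l) * beta2.col(l)));
      }
    }
    trace.push_back(el);
    if (std::isfinite(prev) &&
        std::fabs(el - prev) <= rel_tol * (std::fabs(prev) + 1e-12)) {
      converged = true;
      break;
    }
    prev = el;

    // M-step with responsibilities at the pre-update theta
    arma::vec cs1 = arma::sum(beta1, 0).t();
    arma::vec cs2 = arma::sum(beta2, 0).t();
    double num0 = 0.0, den0 = 0.0;
    for (arma::uword q = 0; q < B1; ++q) {
      for (arma::uword l = 0; l < B2; ++l) {
        arma::uword k = q * B2 + l;
        double wtot = cs1(q) * cs2(l);
        const arma::mat& Rk = R.slice(k);
        if (wtot < 1e-8) {
          frozen.insert("(" + std::to_string(q + 1) + "," +
                        std::to_string(l + 1) + ")");
          continue;
        }
        arma::vec Rb2 = Rk * beta2.col(l);
        double w_edge = arma::dot(beta1.col(q), Rb2);
        Pi(q, l) = clip_prob(w_edge / wtot);
        if (w_edge < 1e-8) {
          frozen.insert("(" + std::to_string(q + 1) + "," +
                        std::to_string(l + 1) + ")");
        } else {
          double mu_new = arma::dot(beta1.col(q),
                                    (Rk % xv) * beta2.col(l)) / w_edge;
          double s2_new = arma::dot(
              beta1.col(q),
              (Rk % arma::square(xv - mu_new)) * beta2.col(l)) / w_edge;
          mu(q, l) = mu_new;
          sigma2(q, l) = std::max(s2_new, 1e-8);
        }
        if (!fix_null) {
          arma::mat Nb = 1.0 - Rk;
          num0 += arma::dot(beta1.col(q), (Nb % xv2) * beta2.col(l));
          den0 += arma::dot(beta1.col(q), Nb * beta2.col(l));
        }
      }
    }
    alpha1 = cs1 / (double)n1;
    alpha2 = cs2 / (double)n2;
    if (!fix_null) {
      s0var = std::max(num0 / std::max(den0, 1e-12), 1e-8);
      lg0 = -0.5 * std::log(2.0 * arma::datum::pi * s0var)
        - xv2 / (2.0 * s0var);
    }
  }

  return List::create(
      Named("alpha1") = alpha1, Named("alpha2") = alpha2,
      Named("Pi") = Pi, Named("mu") = mu, Named("sigma2") = sigma2,
      Named("s0var") = s0var, Named("beta1") = beta1,
      Named("beta2") = beta2, Named("elbo_trace") = trace,
      Named("converged") = converged,
      Named("frozen") = std::vector<std::string>(frozen.begin(),
                                                 frozen.end()));
}
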