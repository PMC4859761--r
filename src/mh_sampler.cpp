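#include <Rcpp.h>
using namespace Rcpp;

// Componentwise Gaussian random-walk Metropolis-Hastings for the EWOC
// posterior.  Parameters are sampled on logit-transformed coordinates
// mapped to their prior supports:
//   rho0  = theta * s(u0),                 rho0  ~ Unif[0, theta]
//   rho1  = rho0 + (1 - rho0) * s(u1),     rho1 | rho0 ~ Unif[rho0, 1]  (PO only)
//   gamma = s(ug),                         gamma ~ Unif[0, 1]
// where s() is the logistic function.  With uniform priors the transformed
// target is loglik + the log-Jacobians log s'(u); the (1 - rho0) Jacobian
// factor of rho1 cancels against its conditional prior density.

static inline double sigm(double u) { return 1.0 / (1.0 + std::exp(-u)); }

static inline double log_sigm_deriv(double u) {
  // log( s(u) (1 - s(u)) ) computed stably
  double a = -std::fabs(u);
  return a - 2.0 * std::log1p(std::exp(a));
}

// Trinomial / binomial log-likelihood of the logistic working model under
// the (rho0, rho1, gamma) parameterization.  y takes values 0/1/2; for the
// binary variant callers collapse grade-2 outcomes (y = 1) to 0 beforehand.
static double ewoc_loglik(double rho0, double rho1, double gamma, bool po,
                          double theta, const NumericVector& x,
                          const IntegerVector& y) {
  const double l0 = std::log(rho0 / (1.0 - rho0));
  const double lt = std::log(theta / (1.0 - theta));
  const double b  = (lt - l0) / gamma;
  double a1 = 0.0;
  if (po) {
    if (rho1 <= 0.0 || rho1 >= 1.0) return R_NegInf;
    a1 = std::log(rho1 / (1.0 - rho1));
  }
  double ll = 0.0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    const double F2 = sigm(l0 + b * x[i]);
    double p;
    if (!po) {
      p = (y[i] == 2) ? F2 : 1.0 - F2;
    } else {
      const double F1 = sigm(a1 + b * x[i]);
      if (y[i] == 2)      p = F2;
      else if (y[i] == 1) p = F1 - F2;
      else                p = 1.0 - F1;
    }
    if (!(p > 0.0)) return R_NegInf;
    ll += std::log(p);
  }
  return ll;
}

struct State {
  double u0, u1, ug;     // transformed coordinates
  double rho0, rho1, gamma;
  double logpost;
};

static void update_naturals(State& s, bool po, double theta) {
  s.rho0  = theta * sigm(s.u0);
  s.gamma = sigm(s.ug);
  s.rho1  = po ? s.rho0 + (1.0 - s.rho0) * sigm(s.u1) : NA_REAL;
}

static double log_target(const State& s, bool po, double theta,
                         const NumericVector& x, const IntegerVector& y) {
  double lp = ewoc_loglik(s.rho0, s.rho1, s.gamma, po, theta, x, y);
  if (!std::isfinite(lp)) return R_NegInf;
  lp += log_sigm_deriv(s.u0) + log_sigm_deriv(s.ug);
  if (po) lp += log_sigm_deriv(s.u1);
  return lp;
}

// [[Rcpp::export(name = ".ewoc_mh_cpp")]]
List ewoc_mh_cpp(NumericVector x, IntegerVector y, bool po, double theta,
                 int n_burnin, int n_keep, NumericVector scales) {
  if (x.size() != y.size()) stop("dose and outcome lengths differ");
  const int npar = po ? 3 : 2;
  if (scales.size() != npar) stop("need %d proposal scales", npar);

  RNGScope rng;
  State cur;
  cur.u0 = 0.0; cur.u1 = 0.0; cur.ug = 0.0;
  update_naturals(cur, po, theta);
  cur.logpost = log_target(cur, po, theta, x, y);

  NumericMatrix draws(n_keep, npar);
  long n_prop = 0, n_acc = 0;
  const int n_iter = n_burnin + n_keep;

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < npar; ++j) {
      State prop = cur;
      double step = scales[j] * norm_rand();
      if (!po) {
        if (j == 0) prop.u0 += step; else prop.ug += step;
      } else {
        if (j == 0) prop.u0 += step;
        else if (j == 1) prop.u1 += step;
        else prop.ug += step;
      }
      update_naturals(prop, po, theta);
      prop.logpost = log_target(prop, po, theta, x, y);
      ++n_prop;
      if (std::isfinite(prop.logpost) &&
          std::log(unif_rand()) < prop.logpost - cur.logpost) {
        cur = prop;
        ++n_acc;
      }
    }
    if (it >= n_burnin) {
      const int k = it - n_burnin;
      draws(k, 0) = cur.rho0;
      if (po) {
        draws(k, 1) = cur.rho1;
        draws(k, 2) = cur.gamma;
      } else {
        draws(k, 1) = cur.gamma;
      }
    }
  }
  return List::create(_["draws"] = draws,
                      _["acceptance_rate"] = double(n_acc) / double(n_prop));
}
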