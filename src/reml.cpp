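#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Profiled restricted log-likelihood of the transformed mixed model.
//
// After one spectral decomposition A = U diag(d) U', the model
// y = X b + a + e with Var(a) = sigma2a * A, Var(e) = sigma2e * I becomes,
// in rotated coordinates yt = U'y, Xt = U'X, a weighted regression with
// Var(yt) = sigma2e * diag(lambda * d + 1), lambda = sigma2a / sigma2e.
// For fixed lambda the REML residual variance and GLS coefficients are
// closed-form; the restricted log-likelihood (including all constants,
// without the optional log|X'X| term) is
//   -1/2 [ (n-p)(log 2*pi + log s2e + 1) + sum log(lambda d + 1)
//          + log |Xt' W Xt| ].
static double profile_ll(double lambda, const mat& Xt, const vec& yt,
                         const vec& d, double& s2e, vec& beta, mat& XtWXi) {
  const double n = (double)yt.n_elem, p = (double)Xt.n_cols;
  vec h = lambda * d + 1.0;
  vec w = 1.0 / h;
  mat Xw = Xt.each_col() % w;
  mat XtWX = Xt.t() * Xw;
  if (!inv_sympd(XtWXi, XtWX)) return -datum::inf;
  vec XtWy = Xw.t() * yt;
  beta = XtWXi * XtWy;
  double rss = dot(yt % w, yt) - dot(XtWy, beta);
  if (rss <= 0) rss = 1e-300;
  s2e = rss / (n - p);
  double val, sign;
  log_det(val, sign, XtWX);
  if (sign <= 0) return -datum::inf;
  return -0.5 * ((n - p) * (std::log(2.0 * M_PI) + std::log(s2e) + 1.0)
                 + accu(log(h)) + val);
}

// [[Rcpp::export(name = ".reml_profile_cpp")]]
Rcpp::List reml_profile_cpp(const arma::mat& Xt, const arma::vec& yt,
                            const arma::vec& d, double fixLambda,
                            double lower, double upper, double tol) {
  double s2e = 0.0;
  vec beta;
  mat XtWXi;
  double lambda, ll;
  bool flat = false;

  if (fixLambda >= 0.0) {
    lambda = fixLambda;
    ll = profile_ll(lambda, Xt, yt, d, s2e, beta, XtWXi);
  } else {
    // golden-section search on log(lambda); relative tolerance tol on lambda
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double a = std::log(lower), b = std::log(upper);
    double fa = profile_ll(std::exp(a), Xt, yt, d, s2e, beta, XtWXi);
    double fb = profile_ll(std::exp(b), Xt, yt, d, s2e, beta, XtWXi);
    double llmax = std::max(fa, fb), llmin = std::min(fa, fb);
    double c = b - gr * (b - a), dd = a + gr * (b - a);
    double fc = profile_ll(std::exp(c), Xt, yt, d, s2e, beta, XtWXi);
    double fd = profile_ll(std::exp(dd), Xt, yt, d, s2e, beta, XtWXi);
    while (b - a > tol) {
      llmax = std::max(llmax, std::max(fc, fd));
      llmin = std::min(llmin, std::min(fc, fd));
      if (fc > fd) {
        b = dd; dd = c; fd = fc;
        c = b - gr * (b - a);
        fc = profile_ll(std::exp(c), Xt, yt, d, s2e, beta, XtWXi);
      } else {
        a = c; c = dd; fc = fd;
        dd = a + gr * (b - a);
        fd = profile_ll(std::exp(dd), Xt, yt, d, s2e, beta, XtWXi);
      }
    }
    lambda = std::exp((a + b) / 2.0);
    ll = profile_ll(lambda, Xt, yt, d, s2e, beta, XtWXi);
    // include the endpoints in the flatness assessment
    flat = std::isfinite(llmax) && std::isfinite(llmin) &&
           (std::max(llmax, ll) - std::min(llmin, ll)) < 1e-6;
    // shrink an unidentified or boundary-low ratio to the effective zero
    if (fa >= ll - 1e-10 && !flat) { lambda = lower; ll = fa;
      ll = profile_ll(lambda, Xt, yt, d, s2e, beta, XtWXi); }
  }

  return Rcpp::List::create(
      Rcpp::Named("lambda") = lambda,
      Rcpp::Named("sigma2e") = s2e,
      Rcpp::Named("sigma2a") = lambda * s2e,
      Rcpp::Named("beta") = beta,
      Rcpp::Named("vb") = s2e * XtWXi,
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("flat") = flat);
}
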