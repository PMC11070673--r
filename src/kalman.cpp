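// Linear-Gaussian constant-velocity state-space smoother with EM parameter
// estimation, used for two-pass smoothing of tracking coordinates.
// State (position, velocity); observation = position + noise. Missing
// observations (NaN) are handled by prediction-only updates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct SmoothOut {
  arma::vec pos;        // smoothed positions
  arma::mat xs;         // 2 x n smoothed states
  arma::cube Vs;        // 2 x 2 x n smoothed covariances
  arma::cube Vlag;      // 2 x 2 x n lag-one covariances (t, t-1)
  double loglik;
};

static SmoothOut rts_smooth(const arma::vec& y, const arma::mat& F,
                            const arma::mat& Q, double R,
                            const arma::vec& x0, const arma::mat& P0) {
  const arma::uword n = y.n_elem;
  arma::rowvec H = {1.0, 0.0};
  arma::mat xp(2, n), xf(2, n);
  arma::cube Pp(2, 2, n), Pf(2, 2, n);
  arma::vec xprev = x0;
  arma::mat Pprev = P0;
  double loglik = 0.0;
  arma::cube K_store(2, 1, n, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t) {
    arma::vec xpred = (t == 0) ? x0 : F * xprev;
    arma::mat Ppred = (t == 0) ? P0 : F * Pprev * F.t() + Q;
    xp.col(t) = xpred; Pp.slice(t) = Ppred;
    if (std::isfinite(y(t))) {
      double S = arma::as_scalar(H * Ppred * H.t()) + R;
      arma::vec K = Ppred * H.t() / S;
      double innov = y(t) - arma::as_scalar(H * xpred);
      xprev = xpred + K * innov;
      Pprev = Ppred - K * H * Ppred;
      loglik += -0.5 * (std::log(2 * M_PI * S) + innov * innov / S);
      K_store.slice(t) = K;
    } else {
      xprev = xpred;
      Pprev = Ppred;
    }
    xf.col(t) = xprev; Pf.slice(t) = Pprev;
  }
  // RTS backward pass
  SmoothOut out;
  out.xs.set_size(2, n);
  out.Vs.set_size(2, 2, n);
  out.Vlag.set_size(2, 2, n);
  out.Vlag.zeros();
  out.loglik = loglik;
  out.xs.col(n - 1) = xf.col(n - 1);
  out.Vs.slice(n - 1) = Pf.slice(n - 1);
  arma::mat J_next;
  for (arma::uword t = n - 1; t-- > 0;) {
    arma::mat Pp1 = arma::symmatu(Pp.slice(t + 1));
    Pp1.diag() += 1e-10 * (1.0 + Pp1.diag().max());
    arma::mat Pinv;
    if (!arma::inv_sympd(Pinv, Pp1)) Pinv = arma::pinv(Pp1);
    arma::mat J = Pf.slice(t) * F.t() * Pinv;
    out.xs.col(t) = xf.col(t) + J * (out.xs.col(t + 1) - xp.col(t + 1));
    out.Vs.slice(t) = Pf.slice(t) +
      J * (out.Vs.slice(t + 1) - Pp.slice(t + 1)) * J.t();
    out.Vlag.slice(t + 1) = out.Vs.slice(t + 1) * J.t();
    J_next = J;
  }
  out.pos = out.xs.row(0).t();
  return out;
}

// [[Rcpp::export]]
List cpp_kalman_two_pass(const arma::vec& y, double dt, int em_iter,
                         double tol, double obs_scale) {
  const arma::uword n = y.n_elem;
  arma::mat F = {{1.0, dt}, {0.0, 1.0}};
  arma::uvec obs_idx = arma::find_finite(y);
  if (obs_idx.n_elem < 10) stop("too few valid observations");
  double vy = arma::var(y.elem(obs_idx));
  if (vy < 1e-12) vy = 1e-12;
  // initial guesses
  double R = 0.25 * vy;
  arma::mat Q = {{1e-3 * vy, 0.0}, {0.0, 1e-2 * vy}};
  arma::vec x0 = {y(obs_idx(0)), 0.0};
  arma::mat P0 = {{vy, 0.0}, {0.0, vy}};
  arma::rowvec H = {1.0, 0.0};

  double ll_old = -arma::datum::inf;
  bool converged = false;
  SmoothOut sm;
  for (int it = 0; it < em_iter; ++it) {
    sm = rts_smooth(y, F, Q, R, x0, P0);
    if (std::abs(sm.loglik - ll_old) < tol * (std::abs(ll_old) + 1.0)) {
      converged = true;
      break;
    }
    ll_old = sm.loglik;
    // M-step sufficient statistics
    arma::mat S11(2, 2, arma::fill::zeros), S10(2, 2, arma::fill::zeros),
      S00(2, 2, arma::fill::zeros);
    for (arma::uword t = 1; t < n; ++t) {
      arma::mat Ptt = sm.Vs.slice(t) + sm.xs.col(t) * sm.xs.col(t).t();
      arma::mat Pt1 = sm.Vs.slice(t - 1) +
        sm.xs.col(t - 1) * sm.xs.col(t - 1).t();
      arma::mat Pcross = sm.Vlag.slice(t) + sm.xs.col(t) * sm.xs.col(t - 1).t();
      S11 += Ptt; S00 += Pt1; S10 += Pcross;
    }
    Q = (S11 - S10 * F.t() - F * S10.t() + F * S00 * F.t()) / (double)(n - 1);
    Q = arma::symmatu(Q);
    Q.diag() += 1e-12;
    double racc = 0.0;
    for (arma::uword k = 0; k < obs_idx.n_elem; ++k) {
      arma::uword t = obs_idx(k);
      double hx = sm.xs(0, t);
      racc += (y(t) - hx) * (y(t) - hx) + sm.Vs(0, 0, t);
    }
    R = std::max(racc / obs_idx.n_elem, 1e-10);
    x0 = sm.xs.col(0);
    P0 = arma::symmatu(sm.Vs.slice(0));
    P0.diag() += 1e-12;
  }
  SmoothOut pass1 = rts_smooth(y, F, Q, R, x0, P0);
  SmoothOut pass2 = rts_smooth(y, F, Q, R * obs_scale, x0, P0);
  return List::create(
    _["pass1"] = pass1.pos, _["pass2"] = pass2.pos,
    _["converged"] = converged, _["R"] = R, _["Q"] = Q,
    _["loglik"] = pass1.loglik);
}
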