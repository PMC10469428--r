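#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
// velocity) Kalman filter / RTS smoother.  State per axis is (position,
// velocity); the two axes share (beta, sigma) but are coupled through the
// observation error ellipse, so a joint 4-state filter is used with state
// ordering (x, vx, y, vy).

static void iou_mats(double dt, double beta, double sigma, mat &T, mat &Q) {
  double e = std::exp(-beta * dt);
  double e2 = std::exp(-2.0 * beta * dt);
  double u = beta * dt;
  double s2 = sigma * sigma;
  double phi, q11, q12, q22;
  if (u < 1e-4) {
    // series expansions: the closed forms cancel catastrophically as
    // beta*dt -> 0 and can produce an indefinite Q
    phi = dt * (1.0 - u / 2.0 + u * u / 6.0);
    q11 = s2 * dt * dt * dt * (1.0 / 3.0 - u / 4.0);
    q12 = s2 * dt * dt * (0.5 - u / 2.0);
    q22 = s2 * dt * (1.0 - u);
  } else {
    phi = (1.0 - e) / beta;
    q11 = (s2 / (beta * beta)) *
          (dt - 2.0 * (1.0 - e) / beta + (1.0 - e2) / (2.0 * beta));
    q12 = s2 * (1.0 - e) * (1.0 - e) / (2.0 * beta * beta);
    q22 = s2 * (1.0 - e2) / (2.0 * beta);
  }
  T.zeros(4, 4); Q.zeros(4, 4);
  for (int ax = 0; ax < 2; ++ax) {
    int i = 2 * ax;
    T(i, i) = 1.0; T(i, i + 1) = phi; T(i + 1, i + 1) = e;
    Q(i, i) = q11; Q(i, i + 1) = Q(i + 1, i) = q12; Q(i + 1, i + 1) = q22;
  }
}

// t_all: sorted times (hours); has_obs: 1 where a fix exists; obs: n x 2
// (ignored where has_obs == 0); R: n x 3 columns (var_x, var_y, cov_xy) in
// km^2; p0_pos, p0_vel: diagonal initial variances.  Returns the marginal
// log-likelihood and, if smooth, RTS-smoothed position means and variances.
// [[Rcpp::export(name = ".ctcrw_kalman")]]
Rcpp::List ctcrw_kalman(const arma::vec &t_all, const arma::ivec &has_obs,
                        const arma::mat &obs, const arma::mat &R,
                        double beta, double sigma,
                        double p0_pos, double p0_vel, bool smooth) {
  const int n = t_all.n_elem;
  mat H(2, 4, fill::zeros);
  H(0, 0) = 1.0; H(1, 2) = 1.0;

  // initial prior at t_all[0]: centred on the first observation
  int first = 0;
  while (first < n && has_obs(first) == 0) ++first;
  if (first != 0) Rcpp::stop("first time point must carry an observation");
  vec m(4, fill::zeros);
  m(0) = obs(0, 0); m(2) = obs(0, 1);
  mat P(4, 4, fill::zeros);
  P(0, 0) = p0_pos; P(2, 2) = p0_pos;
  P(1, 1) = p0_vel; P(3, 3) = p0_vel;

  double ll = 0.0;
  const double log2pi = std::log(2.0 * M_PI);

  cube Pp(4, 4, n), Pf(4, 4, n);
  mat mp(4, n), mf(4, n);

  mat T(4, 4), Q(4, 4);
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = t_all(i) - t_all(i - 1);
      iou_mats(dt, beta, sigma, T, Q);
      m = T * m;
      P = T * P * T.t() + Q;
    }
    if (smooth) { mp.col(i) = m; Pp.slice(i) = P; }
    if (has_obs(i)) {
      mat Ri = {{R(i, 0), R(i, 2)}, {R(i, 2), R(i, 1)}};
      vec y = {obs(i, 0), obs(i, 1)};
      vec v = y - H * m;
      mat S = H * P * H.t() + Ri;
      double det_S = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
      if (det_S <= 0.0 || !std::isfinite(det_S))
        Rcpp::stop("singular innovation covariance in CTCRW filter");
      mat Sinv = {{S(1, 1), -S(0, 1)}, {-S(1, 0), S(0, 0)}};
      Sinv /= det_S;
      ll += -log2pi - 0.5 * std::log(det_S) - 0.5 * as_scalar(v.t() * Sinv * v);
      mat K = P * H.t() * Sinv;
      m = m + K * v;
      P = P - K * H * P;
      P = 0.5 * (P + P.t());
    }
    if (smooth) { mf.col(i) = m; Pf.slice(i) = P; }
  }

  if (!smooth)
    return Rcpp::List::create(Rcpp::Named("loglik") = ll);

  // RTS backward pass
  mat ms(4, n); cube Ps(4, 4, n);
  ms.col(n - 1) = mf.col(n - 1); Ps.slice(n - 1) = Pf.slice(n - 1);
  for (int i = n - 2; i >= 0; --i) {
    double dt = t_all(i + 1) - t_all(i);
    iou_mats(dt, beta, sigma, T, Q);
    mat Ppi = Pp.slice(i + 1);
    mat J = Pf.slice(i) * T.t() * pinv(Ppi);
    ms.col(i) = mf.col(i) + J * (ms.col(i + 1) - mp.col(i + 1));
    Ps.slice(i) = Pf.slice(i) + J * (Ps.slice(i + 1) - Ppi) * J.t();
  }
  vec sx(n), sy(n), vx(n), vy(n);
  for (int i = 0; i < n; ++i) {
    sx(i) = ms(0, i); sy(i) = ms(2, i);
    vx(i) = Ps.slice(i)(0, 0); vy(i) = Ps.slice(i)(2, 2);
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("x") = sx, Rcpp::Named("y") = sy,
                            Rcpp::Named("var_x") = vx, Rcpp::Named("var_y") = vy);
}
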