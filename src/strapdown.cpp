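#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Strapdown inertial navigation and the zero-velocity-update error-state
// Kalman filter.  Sequential per-sample recurrences, hence compiled.
// Inputs are specific force (m/s^2) and angular rate (rad/s) in the sensor
// frame; gravity is a navigation-frame vector (ENU: (0, 0, -9.81)).

static mat skew(const vec& v) {
  mat S(3, 3, fill::zeros);
  S(0, 1) = -v(2); S(0, 2) =  v(1);
  S(1, 0) =  v(2); S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) =  v(0);
  return S;
}

// Rodrigues formula, exact for any rotation vector.
static mat exp_so3(const vec& w) {
  double th = norm(w);
  mat I = eye(3, 3);
  if (th < 1e-12) return I + skew(w);
  mat S = skew(w / th);
  return I + std::sin(th) * S + (1.0 - std::cos(th)) * (S * S);
}

// One symmetric-Newton re-orthonormalization step; keeps ||C'C - I||
// at machine level when C is already near-orthogonal.
static mat renorm(const mat& C) {
  return 1.5 * C - 0.5 * C * C.t() * C;
}

// First-order strapdown integration:
//   C_k = C_{k-1} * Exp(w_{k-1} dt);  v_k = v_{k-1} + (C_{k-1} f_{k-1} + g) dt;
//   p_k = p_{k-1} + v_k dt.
// [[Rcpp::export]]
Rcpp::List cpp_strapdown(const arma::mat& f, const arma::mat& w, double dt,
                         const arma::mat& C0, const arma::vec& g) {
  const uword n = f.n_rows;
  mat p(n, 3, fill::zeros), v(n, 3, fill::zeros);
  cube C(3, 3, n);
  mat Ck = C0;
  C.slice(0) = Ck;
  for (uword k = 1; k < n; ++k) {
    vec a = Ck * f.row(k - 1).t() + g;
    Ck = renorm(Ck * exp_so3(w.row(k - 1).t() * dt));
    v.row(k) = v.row(k - 1) + a.t() * dt;
    p.row(k) = p.row(k - 1) + v.row(k) * dt;
    C.slice(k) = Ck;
  }
  return Rcpp::List::create(Rcpp::_["p"] = p, Rcpp::_["v"] = v,
                            Rcpp::_["C"] = C);
}

// Error-state (complementary) Kalman filter over the strapdown solution.
// 9-dim error state [attitude error (nav frame); velocity error; position
// error] with C_true ~ (I - skew(eps)) C_est.  Propagation couples attitude
// error into velocity error through the skew of the navigation-frame
// specific force; process noise from sigma_a, sigma_w.  At every zv-true
// sample the estimated velocity is measured against zero (H selects the
// velocity error, R = sigma_v^2 I); the posterior error is fed back and
// reset.  Joseph-form covariance update keeps P symmetric PSD.
// [[Rcpp::export]]
Rcpp::List cpp_zupt_kalman(const arma::mat& f, const arma::mat& w,
                           const Rcpp::IntegerVector& zv, double dt,
                           const arma::mat& C0, const arma::vec& g,
                           double sigma_a, double sigma_w, double sigma_v) {
  const uword n = f.n_rows;
  mat p(n, 3, fill::zeros), v(n, 3, fill::zeros);
  cube C(3, 3, n);
  mat Ck = C0;
  C.slice(0) = Ck;

  mat P(9, 9, fill::zeros);
  mat Q(9, 9, fill::zeros);
  for (int i = 0; i < 3; ++i) {
    Q(i, i) = std::pow(sigma_w * dt, 2);
    Q(3 + i, 3 + i) = std::pow(sigma_a * dt, 2);
  }
  mat I9 = eye(9, 9), I3 = eye(3, 3);
  mat R = sigma_v * sigma_v * I3;
  std::vector<double> tr_pre, tr_post;

  for (uword k = 1; k < n; ++k) {
    vec a_sf = Ck * f.row(k - 1).t();          // specific force, nav frame
    vec a = a_sf + g;
    Ck = renorm(Ck * exp_so3(w.row(k - 1).t() * dt));
    v.row(k) = v.row(k - 1) + a.t() * dt;
    p.row(k) = p.row(k - 1) + v.row(k) * dt;

    mat F = I9;
    F.submat(3, 0, 5, 2) = -dt * skew(a_sf);
    F.submat(6, 3, 8, 5) = dt * I3;
    P = F * P * F.t() + Q;

    if (zv[k]) {
      tr_pre.push_back(trace(P));
      mat S = P.submat(3, 3, 5, 5) + R;
      mat K = P.cols(3, 5) * inv_sympd(symmatu(S));   // H = [0 I 0]
      vec z = v.row(k).t();                            // innovation: v - 0
      vec dx = K * z;
      mat IKH = I9;
      IKH.cols(3, 5) -= K;
      P = IKH * P * IKH.t() + K * R * K.t();
      P = symmatu(P);
      tr_post.push_back(trace(P));

      Ck = renorm((I3 - skew(dx.subvec(0, 2))) * Ck);
      v.row(k) -= dx.subvec(3, 5).t();
      p.row(k) -= dx.subvec(6, 8).t();
    }
    C.slice(k) = Ck;
  }
  return Rcpp::List::create(
      Rcpp::_["p"] = p, Rcpp::_["v"] = v, Rcpp::_["C"] = C,
      Rcpp::_["tr_pre"] = tr_pre, Rcpp::_["tr_post"] = tr_post);
}

// Matrix logarithm on SO(3): rotation vector of R.  Used by the synthetic
// generator to turn an attitude sequence into exact body angular rates.
// [[Rcpp::export]]
arma::vec cpp_log_so3(const arma::mat& R) {
  double c = (trace(R) - 1.0) / 2.0;
  c = std::max(-1.0, std::min(1.0, c));
  double th = std::acos(c);
  vec w = { R(2, 1) - R(1, 2), R(0, 2) - R(2, 0), R(1, 0) - R(0, 1) };
  if (th < 1e-9) return 0.5 * w;
  return th / (2.0 * std::sin(th)) * w;
}
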