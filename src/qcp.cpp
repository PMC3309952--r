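#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Largest root of the characteristic quartic of the (traceless, symmetric)
// 4x4 key matrix by Newton iteration, seeded at lambda0 = (E_X + E_Y)/2.
// Coefficients come from the principal minors of K.
static double quartic_newton(const arma::mat& K, double lambda0,
                             double tol, int maxit, bool& converged,
                             int& iters, double& dp_final) {
  double c2 = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j)
      c2 += K(i, i) * K(j, j) - K(i, j) * K(i, j);
  double c1 = 0.0;
  for (int i = 0; i < 4; ++i) {
    arma::uvec idx(3);
    int t = 0;
    for (int j = 0; j < 4; ++j) if (j != i) idx(t++) = j;
    c1 -= arma::det(K.submat(idx, idx));
  }
  double c0 = arma::det(K);

  double l = lambda0;
  converged = false;
  iters = 0;
  dp_final = 0.0;
  for (int it = 0; it < maxit; ++it) {
    ++iters;
    double l2 = l * l;
    double p  = l2 * l2 + c2 * l2 + c1 * l + c0;
    double dp = 4.0 * l2 * l + 2.0 * c2 * l + c1;
    dp_final = dp;
    if (dp == 0.0) break;
    double lnew = l - p / dp;
    if (std::abs(lnew - l) < tol * (std::abs(lnew) + 1.0)) {
      l = lnew;
      converged = true;
      break;
    }
    l = lnew;
  }
  return l;
}

static arma::mat quat_to_rot(const arma::vec& q) {
  double w = q(0), x = q(1), y = q(2), z = q(3);
  arma::mat R(3, 3);
  R(0, 0) = w * w + x * x - y * y - z * z;
  R(0, 1) = 2.0 * (x * y - w * z);
  R(0, 2) = 2.0 * (x * z + w * y);
  R(1, 0) = 2.0 * (x * y + w * z);
  R(1, 1) = w * w - x * x + y * y - z * z;
  R(1, 2) = 2.0 * (y * z - w * x);
  R(2, 0) = 2.0 * (x * z - w * y);
  R(2, 1) = 2.0 * (y * z + w * x);
  R(2, 2) = w * w - x * x - y * y + z * z;
  return R;
}

// Minimal-RMSD rigid superposition of X onto Y (paired rows) via the
// quaternion characteristic polynomial.  Returns the RMSD, and when
// want_rotation is true also the proper rotation + translation achieving it.
// [[Rcpp::export]]
List qcp_core(const arma::mat& X, const arma::mat& Y, bool want_rotation) {
  const int n = X.n_rows;
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx;
  arma::mat Yc = Y.each_row() - cy;
  double E = arma::accu(Xc % Xc) + arma::accu(Yc % Yc);
  arma::mat M = Xc.t() * Yc;  // 3x3 inner-product matrix

  double Sxx = M(0, 0), Sxy = M(0, 1), Sxz = M(0, 2);
  double Syx = M(1, 0), Syy = M(1, 1), Syz = M(1, 2);
  double Szx = M(2, 0), Szy = M(2, 1), Szz = M(2, 2);

  arma::mat K(4, 4);
  K(0, 0) = Sxx + Syy + Szz;
  K(0, 1) = Syz - Szy;  K(0, 2) = Szx - Sxz;  K(0, 3) = Sxy - Syx;
  K(1, 1) = Sxx - Syy - Szz;
  K(1, 2) = Sxy + Syx;  K(1, 3) = Szx + Sxz;
  K(2, 2) = -Sxx + Syy - Szz;
  K(2, 3) = Syz + Szy;
  K(3, 3) = -Sxx - Syy + Szz;
  K(1, 0) = K(0, 1); K(2, 0) = K(0, 2); K(3, 0) = K(0, 3);
  K(2, 1) = K(1, 2); K(3, 1) = K(1, 3); K(3, 2) = K(2, 3);

  bool converged = false;
  int iters = 0;
  double dp_final = 0.0;
  double lmax = quartic_newton(K, E / 2.0, 1e-13, 60, converged, iters,
                               dp_final);
  bool fallback = false;
  arma::vec q(4, arma::fill::zeros);

  // A near-multiple largest root (degenerate spectrum: collinear or
  // planar point sets) leaves the quartic ill-conditioned: Newton either
  // converges slowly or stalls with a vanishing derivative.  Both cases
  // are routed to the exact symmetric eigen-decomposition.
  double scale3 = std::pow(std::abs(lmax) + 1.0, 3);
  if (converged && (iters > 20 || std::abs(dp_final) < 1e-6 * scale3)) {
    converged = false;
  }

  if (!converged) {
    arma::vec ev;
    arma::mat V;
    arma::eig_sym(ev, V, K);
    lmax = ev(3);
    q = V.col(3);
    fallback = true;
  } else if (want_rotation) {
    // eigenvector of K for lmax = null space of (K - lmax I), via SVD
    arma::mat U, V;
    arma::vec s;
    arma::svd(U, s, V, K - lmax * arma::eye(4, 4));
    q = V.col(3);
    if (s(2) < 1e-8 * std::max(1.0, std::abs(lmax))) {
      // near-degenerate spectrum: take the safer symmetric eigen route
      arma::vec ev;
      arma::mat W;
      arma::eig_sym(ev, W, K);
      lmax = ev(3);
      q = W.col(3);
      fallback = true;
    }
  }

  double rmsd = std::sqrt(std::max(0.0, E - 2.0 * lmax) / n);

  // Near rmsd = 0 the difference E - 2 lambda cancels catastrophically
  // (its noise floor grows with the structure's radius of gyration), so
  // the residual is re-evaluated directly from the superimposed
  // coordinates; at the optimum this is second-order exact.
  bool need_rot = want_rotation || rmsd < 1e-3;

  List out = List::create(_["rmsd"] = rmsd,
                          _["lambda_max"] = lmax,
                          _["fallback"] = fallback);
  if (need_rot) {
    if (!fallback && arma::norm(q) == 0.0) {
      arma::mat U, V;
      arma::vec s;
      arma::svd(U, s, V, K - lmax * arma::eye(4, 4));
      q = V.col(3);
    }
    arma::mat R = quat_to_rot(q / arma::norm(q));
    // guard: quaternion rotations are proper by construction, but a
    // numerically null quaternion would not be
    if (arma::det(R) < 0.0 || !R.is_finite()) {
      arma::vec ev;
      arma::mat W;
      arma::eig_sym(ev, W, K);
      R = quat_to_rot(arma::vec(W.col(3) / arma::norm(W.col(3))));
    }
    if (rmsd < 1e-3) {
      arma::mat res = Xc * R.t() - Yc;
      out["rmsd"] = std::sqrt(arma::accu(res % res) / n);
    }
    if (want_rotation) {
      arma::vec t = cy.t() - R * cx.t();
      out["rotation"] = R;
      out["translation"] = t;
    }
  }
  return out;
}
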