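// Dense forward/backward kernels for the contact-map interaction model.
//
// Blocks (all separately exported for unit testing):
//   projection   Z = relu(E * Wp + bp)                      (L x d)
//   pair feats   F[(i,j),] = [ |z1_i - z2_j| , z1_i * z2_j ] (n*m x 2d)
//   hidden       H = relu(F * Wq + bq)                       (n*m x h)
//   contact      C = sigmoid(conv2_same(H, K) + bk)          (n x m)
//   pooling      P = maxpool(C, l)  (stride l, no padding)
//   head         Q = relu(P - mean(P) - gammah * var(P));
//                phat = sum(Q) / (#active + 1);
//                yhat = sigmoid(kact * (phat - 0.5))
//                (thresholded sparsification + sharp trainable logistic)
//
// Row index convention: pair (i, j) -> row i + j*n (column-major).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static mat relu_affine(const mat& E, const mat& W, const rowvec& b) {
  mat Z = E * W;
  Z.each_row() += b;
  Z.transform([](double x) { return x > 0.0 ? x : 0.0; });
  return Z;
}

// [[Rcpp::export]]
arma::mat cpp_pair_features(const arma::mat& Z1, const arma::mat& Z2) {
  const uword n = Z1.n_rows, m = Z2.n_rows, d = Z1.n_cols;
  mat F(n * m, 2 * d);
  for (uword j = 0; j < m; ++j) {
    for (uword i = 0; i < n; ++i) {
      const uword r = i + j * n;
      for (uword c = 0; c < d; ++c) {
        const double a = Z1(i, c), b = Z2(j, c);
        F(r, c) = std::abs(a - b);
        F(r, d + c) = a * b;
      }
    }
  }
  return F;
}

// Same-size zero-padded 2D convolution of an (n*m x h) channel matrix with
// a (k x k x h) kernel summed over channels, plus bias.
// [[Rcpp::export]]
arma::mat cpp_conv2_same(const arma::mat& Hmat, const arma::cube& K,
                         double bk, int n, int m) {
  const int k = K.n_rows, h = K.n_slices, w = (k - 1) / 2;
  mat C(n, m, fill::value(bk));
  for (int c = 0; c < h; ++c) {
    const mat Hc = reshape(Hmat.col(c), n, m);
    for (int a = 0; a < k; ++a) {
      const int di = a - w;
      const int i0 = std::max(0, -di), i1 = std::min(n - 1, n - 1 - di);
      if (i0 > i1) continue;
      for (int b = 0; b < k; ++b) {
        const int dj = b - w;
        const int j0 = std::max(0, -dj), j1 = std::min(m - 1, m - 1 - dj);
        if (j0 > j1) continue;
        C.submat(i0, j0, i1, j1) +=
          K(a, b, c) * Hc.submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
      }
    }
  }
  return C;
}

// Max pooling with window l, stride l, no padding (partial edge blocks).
// Returns P plus 0-based argmax coordinates for gradient routing.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool(const arma::mat& C, int pool) {
  const int n = C.n_rows, m = C.n_cols;
  const int np = (n + pool - 1) / pool, mp = (m + pool - 1) / pool;
  mat P(np, mp);
  imat AI(np, mp), AJ(np, mp);
  for (int u = 0; u < np; ++u) {
    const int i0 = u * pool, i1 = std::min(n - 1, i0 + pool - 1);
    for (int v = 0; v < mp; ++v) {
      const int j0 = v * pool, j1 = std::min(m - 1, j0 + pool - 1);
      double best = C(i0, j0);
      int bi = i0, bj = j0;
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          if (C(i, j) > best) { best = C(i, j); bi = i; bj = j; }
      P(u, v) = best; AI(u, v) = bi; AJ(u, v) = bj;
    }
  }
  return Rcpp::List::create(Rcpp::Named("P") = P,
                            Rcpp::Named("AI") = AI,
                            Rcpp::Named("AJ") = AJ);
}

// [[Rcpp::export]]
Rcpp::List cpp_model_forward(const arma::mat& E1, const arma::mat& E2,
                             const arma::mat& Wp, const arma::rowvec& bp,
                             const arma::mat& Wq, const arma::rowvec& bq,
                             const arma::cube& K, double bk,
                             double gammah, double kact,
                             int pool) {
  const int n = E1.n_rows, m = E2.n_rows;
  mat Z1 = relu_affine(E1, Wp, bp);
  mat Z2 = relu_affine(E2, Wp, bp);
  mat F = cpp_pair_features(Z1, Z2);
  mat Hmat = F * Wq;
  Hmat.each_row() += bq;
  Hmat.transform([](double x) { return x > 0.0 ? x : 0.0; });
  mat Cpre = cpp_conv2_same(Hmat, K, bk, n, m);
  mat C = Cpre;
  C.transform([](double x) { return sigmoid(x); });
  Rcpp::List pl = cpp_maxpool(C, pool);
  mat P = pl["P"];
  const double NP = P.n_elem;
  const double mu = accu(P) / NP;
  const double va = accu(square(P - mu)) / NP;
  mat Q = P - mu - gammah * va;
  Q.transform([](double x) { return x > 0.0 ? x : 0.0; });
  const double nact = accu(conv_to<mat>::from(Q > 0.0));
  const double phat = accu(Q) / (nact + 1.0);
  const double s = kact * (phat - 0.5);
  const double yhat = sigmoid(s);
  return Rcpp::List::create(
    Rcpp::Named("yhat") = yhat, Rcpp::Named("s") = s,
    Rcpp::Named("C") = C, Rcpp::Named("P") = P,
    Rcpp::Named("mu") = mu, Rcpp::Named("va") = va,
    Rcpp::Named("Q") = Q, Rcpp::Named("nact") = nact,
    Rcpp::Named("phat") = phat,
    Rcpp::Named("AI") = pl["AI"], Rcpp::Named("AJ") = pl["AJ"],
    Rcpp::Named("Z1") = Z1, Rcpp::Named("Z2") = Z2,
    Rcpp::Named("F") = F, Rcpp::Named("H") = Hmat);
}

// Backward pass: dyhat is dL/dyhat; dC_extra is an additional dL/dC term
// (the contact-magnitude regulariser). Returns gradients for every
// parameter plus (unused by training, useful for checks) dE1/dE2.
// [[Rcpp::export]]
Rcpp::List cpp_model_backward(const Rcpp::List& fwd,
                              const arma::mat& E1, const arma::mat& E2,
                              const arma::mat& Wp, const arma::mat& Wq,
                              const arma::cube& K,
                              double gammah, double kact,
                              double dyhat, const arma::mat& dC_extra,
                              int pool) {
  const int n = E1.n_rows, m = E2.n_rows;
  const int k = K.n_rows, h = K.n_slices, w = (k - 1) / 2;
  const double yhat = fwd["yhat"];
  const mat C = fwd["C"];
  const mat P = fwd["P"];
  const imat AI = fwd["AI"], AJ = fwd["AJ"];
  const mat Z1 = fwd["Z1"], Z2 = fwd["Z2"];
  const mat F = fwd["F"], Hmat = fwd["H"];
  const mat Q = fwd["Q"];
  const double mu = fwd["mu"], va = fwd["va"];
  const double nact = fwd["nact"], phat = fwd["phat"];
  const int np = P.n_rows, mp = P.n_cols;
  const double NP = np * mp;

  const double ds = dyhat * yhat * (1.0 - yhat);
  const double dkact = ds * (phat - 0.5);
  const double dphat = ds * kact;
  // phat = sum(Q) / (nact + 1); the active-cell count is treated as
  // locally constant (its derivative is zero almost everywhere)
  const mat act = conv_to<mat>::from(Q > 0.0);
  const double dQsum = dphat / (nact + 1.0);
  const double sum_act = accu(act);
  // Q = relu(P - mu - gammah * va)
  const double dgammah = -va * dQsum * sum_act;
  const double dva = -gammah * dQsum * sum_act;
  const double dmu_direct = -dQsum * sum_act;
  // mu and va both depend on P
  mat dP = dQsum * act;
  dP += (dmu_direct / NP);
  dP += dva * 2.0 * (P - mu) / NP;

  mat dC = dC_extra;
  if (dC.n_rows != (uword)n || dC.n_cols != (uword)m) dC.zeros(n, m);
  for (int u = 0; u < np; ++u)
    for (int v = 0; v < mp; ++v)
      dC(AI(u, v), AJ(u, v)) += dP(u, v);

  mat dCpre = dC % (C % (1.0 - C));
  const double dbk = accu(dCpre);

  cube dK(k, k, h, fill::zeros);
  mat dHmat(n * m, h, fill::zeros);
  for (int c = 0; c < h; ++c) {
    const mat Hc = reshape(Hmat.col(c), n, m);
    mat dHc(n, m, fill::zeros);
    for (int a = 0; a < k; ++a) {
      const int di = a - w;
      const int i0 = std::max(0, -di), i1 = std::min(n - 1, n - 1 - di);
      if (i0 > i1) continue;
      for (int b = 0; b < k; ++b) {
        const int dj = b - w;
        const int j0 = std::max(0, -dj), j1 = std::min(m - 1, m - 1 - dj);
        if (j0 > j1) continue;
        dK(a, b, c) = accu(dCpre.submat(i0, j0, i1, j1) %
                           Hc.submat(i0 + di, j0 + dj, i1 + di, j1 + dj));
        dHc.submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
          K(a, b, c) * dCpre.submat(i0, j0, i1, j1);
      }
    }
    dHmat.col(c) = vectorise(dHc);
  }
  // relu mask on hidden activations
  dHmat %= conv_to<mat>::from(Hmat > 0.0);

  mat dWq = F.t() * dHmat;
  rowvec dbq = sum(dHmat, 0);
  mat dF = dHmat * Wq.t();

  const uword d = Z1.n_cols;
  mat dZ1(Z1.n_rows, d, fill::zeros), dZ2(Z2.n_rows, d, fill::zeros);
  for (uword j = 0; j < (uword)m; ++j) {
    for (uword i = 0; i < (uword)n; ++i) {
      const uword r = i + j * n;
      for (uword c = 0; c < d; ++c) {
        const double a = Z1(i, c), b = Z2(j, c);
        const double sgn = (a > b) ? 1.0 : ((a < b) ? -1.0 : 0.0);
        const double du = dF(r, c), dv = dF(r, d + c);
        dZ1(i, c) += du * sgn + dv * b;
        dZ2(j, c) += -du * sgn + dv * a;
      }
    }
  }
  dZ1 %= conv_to<mat>::from(Z1 > 0.0);
  dZ2 %= conv_to<mat>::from(Z2 > 0.0);

  mat dWp = E1.t() * dZ1 + E2.t() * dZ2;
  rowvec dbp = sum(dZ1, 0) + sum(dZ2, 0);

  return Rcpp::List::create(
    Rcpp::Named("Wp") = dWp, Rcpp::Named("bp") = dbp,
    Rcpp::Named("Wq") = dWq, Rcpp::Named("bq") = dbq,
    Rcpp::Named("K") = dK, Rcpp::Named("bk") = dbk,
    Rcpp::Named("gammah") = dgammah, Rcpp::Named("kact") = dkact);
}
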