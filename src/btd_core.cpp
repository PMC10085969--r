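// Residual, cost and raw gradients of the structured block-term fit
//
//   J = sum_k || T_k - sum_r H_r C_{r,k} H_r^T ||_F^2,
//   C_{r,k}(i,j) = z_r(|k + i - j|)   (0-based lags, symmetric extension).
//
// Gradients are returned with respect to the unstructured block columns H_r
// and the generating vectors z_r; chain rules onto HRF parameters and
// artifact gains are applied on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat toeplitz_slice(const vec& z, int k, int P) {
  mat C(P, P);
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < P; ++i)
      C(i, j) = z(std::abs(k + i - j));
  return C;
}

// [[Rcpp::export]]
Rcpp::List btd_cost_grad(const arma::cube& T, const arma::mat& H,
                         const arma::mat& Z, bool want_grad) {
  const int K = T.n_slices;
  const int P = Z.n_rows - K + 1;   // Z has P + K - 1 lags per source
  const int R = Z.n_cols;
  if ((int) H.n_cols != R * P)
    Rcpp::stop("H has %d columns, expected R*P = %d", H.n_cols, R * P);

  cube E(T);  // residual slices
  std::vector<mat> HC(R * K);  // cache H_r C_{r,k}
  for (int r = 0; r < R; ++r) {
    const mat Hr = H.cols(r * P, (r + 1) * P - 1);
    for (int k = 0; k < K; ++k) {
      const mat C = toeplitz_slice(Z.col(r), k, P);
      HC[r * K + k] = Hr * C;
      E.slice(k) -= HC[r * K + k] * Hr.t();
    }
  }
  double cost = accu(square(E));
  if (!want_grad)
    return Rcpp::List::create(Rcpp::Named("cost") = cost);

  mat dH(H.n_rows, H.n_cols, fill::zeros);
  mat dZ(Z.n_rows, Z.n_cols, fill::zeros);
  for (int r = 0; r < R; ++r) {
    const mat Hr = H.cols(r * P, (r + 1) * P - 1);
    mat dHr(H.n_rows, P, fill::zeros);
    for (int k = 0; k < K; ++k) {
      const mat& Ek = E.slice(k);
      const mat C = toeplitz_slice(Z.col(r), k, P);
      // dJ/dHr = -2 sum_k (E_k Hr C^T + E_k^T Hr C)
      dHr -= 2.0 * (Ek * (Hr * C.t()) + Ek.t() * HC[r * K + k]);
      // dJ/dC = -2 Hr^T E_k Hr; accumulate onto z along diagonals j - i = d
      const mat G = Hr.t() * Ek * Hr;
      for (int d = -(P - 1); d <= P - 1; ++d)
        dZ(std::abs(k - d), r) += -2.0 * accu(G.diag(d));
    }
    dH.cols(r * P, (r + 1) * P - 1) = dHr;
  }
  return Rcpp::List::create(Rcpp::Named("cost") = cost,
                            Rcpp::Named("dH") = dH,
                            Rcpp::Named("dZ") = dZ);
}

// Least-squares core generators given fixed block columns H:
// the model is linear in each z_r, so  min_z ||T - sum_r lambda(z_r) x1 H_r
// x2 H_r||_F^2  is a linear system. Used to initialize the joint descent.
// [[Rcpp::export]]
arma::mat solve_z_ls(const arma::cube& T, const arma::mat& H, int P,
                     double ridge) {
  const int K = T.n_slices;
  const int R = H.n_cols / P;
  const int nlag = P + K - 1;
  const int n = R * nlag;

  // W_{r,k} = H_r^T T_k H_r ; rhs(r,l) = sum_k sum_{a in A(k,l)} diagsum_a
  vec b(n, fill::zeros);
  for (int r = 0; r < R; ++r) {
    const mat Hr = H.cols(r * P, (r + 1) * P - 1);
    for (int k = 0; k < K; ++k) {
      const mat W = Hr.t() * T.slice(k) * Hr;
      for (int l = 0; l < nlag; ++l) {
        const int as[2] = {k - l, k + l};
        const int na = (l == 0) ? 1 : 2;
        for (int t = 0; t < na; ++t) {
          const int a = as[t];
          if (a >= -(P - 1) && a <= P - 1)
            b(r * nlag + l) += accu(W.diag(a));
        }
      }
    }
  }

  // Q_{rr'}(a,b) = sum_{ij} G(i-a, j-b) G(i,j), G = H_r^T H_r'
  mat N(n, n, fill::zeros);
  for (int r = 0; r < R; ++r) {
    for (int rp = r; rp < R; ++rp) {
      const mat G = H.cols(r * P, (r + 1) * P - 1).t() *
                    H.cols(rp * P, (rp + 1) * P - 1);
      mat Q(2 * P - 1, 2 * P - 1, fill::zeros);
      for (int a = -(P - 1); a <= P - 1; ++a) {
        const int i0 = std::max(0, a), i1 = std::min(P - 1, P - 1 + a);
        for (int bsh = -(P - 1); bsh <= P - 1; ++bsh) {
          const int j0 = std::max(0, bsh), j1 = std::min(P - 1, P - 1 + bsh);
          double s = 0.0;
          for (int j = j0; j <= j1; ++j)
            s += dot(G(span(i0 - a, i1 - a), j - bsh),
                     G(span(i0, i1), j));
          Q(a + P - 1, bsh + P - 1) = s;
        }
      }
      for (int l = 0; l < nlag; ++l) {
        for (int lp = 0; lp < nlag; ++lp) {
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            const int as[2] = {k - l, k + l};
            const int bs[2] = {k - lp, k + lp};
            const int na = (l == 0) ? 1 : 2, nb = (lp == 0) ? 1 : 2;
            for (int t = 0; t < na; ++t) {
              if (as[t] < -(P - 1) || as[t] > P - 1) continue;
              for (int u = 0; u < nb; ++u) {
                if (bs[u] < -(P - 1) || bs[u] > P - 1) continue;
                s += Q(as[t] + P - 1, bs[u] + P - 1);
              }
            }
          }
          N(r * nlag + l, rp * nlag + lp) = s;
          N(rp * nlag + lp, r * nlag + l) = s;
        }
      }
    }
  }
  N.diag() += ridge * (trace(N) / n + 1e-12);
  vec z = solve(N, b, solve_opts::likely_sympd + solve_opts::allow_ugly);
  return reshape(z, nlag, R);
}
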