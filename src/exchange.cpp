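// Exchange-algorithm core for r-score training-set optimization.
//
// All quantities are expressed over the candidate pool: K = Xc Xc' and
// R = Xc Theta Xc' (Theta = centered reference Gram), both n_c x n_c. For a
// subset S, with G = K[S,S] + lambda I and B = R[S,S]:
//   q12 = Tr[B G^-1],  q2 = q12 + (1 - lambda) Tr[B G^-2],
//   r   = q12 / sqrt(q1 q2).
// Candidate swaps inside a sweep are screened with rank-2 Woodbury updates
// of P = G^-1 (and Q = P^2); every accepted move is re-scored exactly from a
// fresh factorization, so reported scores never depend on the update algebra.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct SubsetState {
  mat P;        // G^-1
  mat Q;        // G^-2
  mat B;        // R[S,S]
  double q12;
  double t2;    // Tr[B G^-2]
  double q2;
  double value; // r-score, -inf if degenerate
};

bool score_subset(const mat& K, const mat& R, double q1, double lambda,
                  const uvec& S, SubsetState& st) {
  mat G = K.submat(S, S);
  G.diag() += lambda;
  st.B = R.submat(S, S);
  mat P;
  if (!inv_sympd(P, G)) return false;
  st.P = P;
  st.Q = P * P;
  st.q12 = accu(st.B % st.P);
  st.t2 = accu(st.B % st.Q);
  st.q2 = st.q12 + (1.0 - lambda) * st.t2;
  if (!std::isfinite(st.q2) || st.q2 <= 1e-14 * q1) {
    st.value = -datum::inf;
    return false;
  }
  st.value = st.q12 / std::sqrt(q1 * st.q2);
  return true;
}

inline double trD(const mat22& A) { return A(0, 1) + A(1, 0); }

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_subset_score(const arma::mat& K, const arma::mat& R, double q1,
                            double lambda, const arma::uvec& idx0) {
  SubsetState st;
  bool ok = score_subset(K, R, q1, lambda, idx0, st);
  if (!ok && !st.P.n_elem)
    Rcpp::stop("training Gram matrix is not positive definite");
  if (!ok)
    Rcpp::stop("degenerate r-score criterion: q2 is numerically zero");
  return Rcpp::List::create(Rcpp::Named("q12") = st.q12,
                            Rcpp::Named("q2") = st.q2,
                            Rcpp::Named("value") = st.value);
}

// One full exchange search from a given start. cluster is an integer label
// per pool member (empty = unconstrained); swaps are restricted to the
// cluster of the outgoing member, which preserves any initial quota.
// [[Rcpp::export]]
Rcpp::List cpp_exchange(const arma::mat& K, const arma::mat& R, double q1,
                        double lambda, const arma::uvec& init0,
                        const arma::ivec& cluster, int maxSweeps, double tol) {
  const uword nc = K.n_rows;
  const uword nt = init0.n_elem;
  const bool useCluster = cluster.n_elem == nc;

  uvec S = init0;
  std::vector<bool> inS(nc, false);
  for (uword i = 0; i < nt; ++i) inS[S[i]] = true;

  SubsetState st;
  if (!score_subset(K, R, q1, lambda, S, st))
    Rcpp::stop("degenerate or singular criterion at the initial training set");

  std::vector<double> traceVals;
  traceVals.push_back(st.value);
  double nEval = 1.0;
  bool converged = false;
  int sweeps = 0;

  for (; sweeps < maxSweeps; ++sweeps) {
    bool improvedThisSweep = false;
    for (uword k = 0; k < nt; ++k) {
      const uword a = S[k];
      // pool of admissible incoming candidates, ascending index order
      std::vector<uword> poolv;
      poolv.reserve(nc - nt);
      for (uword b = 0; b < nc; ++b)
        if (!inS[b] && (!useCluster || cluster[b] == cluster[a]))
          poolv.push_back(b);
      if (poolv.empty()) continue;
      const uvec pool(poolv);
      const uword np = pool.n_elem;

      // batched rank-2 update screening
      mat U = K.submat(S, pool);
      U.each_col() -= K.submat(S, uvec{a});
      mat V = R.submat(S, pool);
      V.each_col() -= R.submat(S, uvec{a});
      for (uword j = 0; j < np; ++j) {
        U(k, j) = 0.5 * (K(pool[j], pool[j]) - K(a, a));
        V(k, j) = 0.5 * (R(pool[j], pool[j]) - R(a, a));
      }
      const vec y1 = st.P.col(k);
      const vec z1 = st.Q.col(k);
      const vec By1 = st.B * y1;
      const vec Bz1 = st.B * z1;
      const mat PU = st.P * U;
      const mat QU = st.Q * U;
      const mat BPU = st.B * PU;
      const mat BQU = st.B * QU;
      nEval += static_cast<double>(np);

      double bestVal = st.value + tol;
      sword bestJ = -1;
      for (uword j = 0; j < np; ++j) {
        const vec u = U.col(j), v = V.col(j);
        const vec y2 = PU.col(j), z2 = QU.col(j);
        const vec By2 = BPU.col(j), Bz2 = BQU.col(j);

        mat22 M;
        M(0, 0) = st.P(k, k);
        M(0, 1) = M(1, 0) = 1.0 + y2[k];
        M(1, 1) = dot(u, y2);
        const double det = M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0);
        if (std::abs(det) < 1e-12 * (1.0 + std::abs(M(0, 1)))) continue;
        mat22 Minv;
        Minv(0, 0) = M(1, 1) / det;  Minv(1, 1) = M(0, 0) / det;
        Minv(0, 1) = Minv(1, 0) = -M(0, 1) / det;

        mat22 YBY;
        YBY(0, 0) = dot(y1, By1); YBY(0, 1) = YBY(1, 0) = dot(y1, By2);
        YBY(1, 1) = dot(y2, By2);
        mat22 VtY;  // rows: e_k, v; cols: y1, y2
        VtY(0, 0) = y1[k];       VtY(0, 1) = y2[k];
        VtY(1, 0) = dot(v, y1);  VtY(1, 1) = dot(v, y2);

        const double q12n = st.q12 + 2.0 * dot(v, y1)
          - trace(Minv * YBY) - trD(VtY * Minv * VtY.t());

        mat22 YBPY;  // Y' B (PY), PY = [z1, z2]
        YBPY(0, 0) = dot(y1, Bz1); YBPY(0, 1) = dot(y1, Bz2);
        YBPY(1, 0) = dot(y2, Bz1); YBPY(1, 1) = dot(y2, Bz2);
        mat22 W1;    // (PY)' V: rows z1, z2; cols e_k, v
        W1(0, 0) = z1[k];      W1(0, 1) = dot(z1, v);
        W1(1, 0) = z2[k];      W1(1, 1) = dot(z2, v);
        mat22 YtY;
        YtY(0, 0) = dot(y1, y1); YtY(0, 1) = YtY(1, 0) = dot(y1, y2);
        YtY(1, 1) = dot(y2, y2);

        const double t2n = st.t2 + 2.0 * dot(v, z1)
          - 2.0 * trace(Minv * YBPY)
          - 2.0 * trD(VtY * Minv * W1)
          + trace(Minv * YtY * Minv * YBY)
          + trD(VtY * Minv * YtY * Minv * VtY.t());

        const double q2n = q12n + (1.0 - lambda) * t2n;
        if (!(q2n > 0.0)) continue;
        const double val = q12n / std::sqrt(q1 * q2n);
        if (val > bestVal) { bestVal = val; bestJ = static_cast<sword>(j); }
      }

      if (bestJ >= 0) {
        // exact re-score before accepting
        const uword b = pool[static_cast<uword>(bestJ)];
        uvec Snew = S;
        Snew[k] = b;
        SubsetState stNew;
        nEval += 1.0;
        if (score_subset(K, R, q1, lambda, Snew, stNew) &&
            stNew.value > st.value + tol) {
          inS[a] = false;
          inS[b] = true;
          S = Snew;
          st = stNew;
          traceVals.push_back(st.value);
          improvedThisSweep = true;
        }
      }
      Rcpp::checkUserInterrupt();
    }
    if (!improvedThisSweep) { converged = true; break; }
  }

  return Rcpp::List::create(
      Rcpp::Named("idx") = S, Rcpp::Named("value") = st.value,
      Rcpp::Named("q12") = st.q12, Rcpp::Named("q2") = st.q2,
      Rcpp::Named("trace") = traceVals, Rcpp::Named("n_eval") = nEval,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("sweeps") = sweeps + (converged ? 1 : 0));
}
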