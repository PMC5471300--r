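#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequence reweighting: w_s = 1 / #{t : identity(s,t) >= thr}, self included.
// Identity counts equal codes over all L columns (gap = ordinary symbol).
// [[Rcpp::export]]
NumericVector cpp_identity_weights(IntegerMatrix X, double thr) {
  const int M = X.nrow(), L = X.ncol();
  std::vector<int> nb(M, 1); // self
  // column-major access is cache-unfriendly for row pairs; copy rows out
  std::vector<int> rows((size_t)M * L);
  for (int s = 0; s < M; ++s)
    for (int c = 0; c < L; ++c) rows[(size_t)s * L + c] = X(s, c);
  const double cut = thr * L;
  for (int s = 0; s < M; ++s) {
    const int* rs = &rows[(size_t)s * L];
    for (int t = s + 1; t < M; ++t) {
      const int* rt = &rows[(size_t)t * L];
      int same = 0;
      for (int c = 0; c < L; ++c) same += (rs[c] == rt[c]);
      if ((double)same >= cut) { ++nb[s]; ++nb[t]; }
    }
  }
  NumericVector w(M);
  for (int s = 0; s < M; ++s) w[s] = 1.0 / nb[s];
  return w;
}

// Asymmetric pseudo-likelihood, one site. theta = [h (q) | J_blocks], one
// q x q block (column-major, row = state at `site`, col = state at j) for
// each j != site in increasing j. Objective:
//   (1/neff) * sum_s w_s * (-log P(x_si | x_s,-i)) + lh*||h||^2 + lJ*sum||J||^2
// [[Rcpp::export]]
List cpp_plm_obj_grad(NumericVector theta, IntegerMatrix X, NumericVector w,
                      int site, int q, double lambda_h, double lambda_J,
                      double neff) {
  const int M = X.nrow(), L = X.ncol();
  const int i0 = site - 1; // 0-based site
  const int nblk = L - 1;
  if (theta.size() != q + (R_xlen_t)nblk * q * q)
    stop("theta has wrong length");
  const double* h = theta.begin();
  const double* J = theta.begin() + q;
  NumericVector grad(theta.size());
  double* gh = grad.begin();
  double* gJ = grad.begin() + q;

  // map column j -> block index (skip site)
  std::vector<int> blk(L, -1);
  {
    int b = 0;
    for (int j = 0; j < L; ++j) if (j != i0) blk[j] = b++;
  }

  std::vector<double> E(q), p(q);
  double nll = 0.0;
  for (int s = 0; s < M; ++s) {
    for (int a = 0; a < q; ++a) E[a] = h[a];
    for (int j = 0; j < L; ++j) {
      if (j == i0) continue;
      const int xj = X(s, j) - 1;
      const double* Jb = J + ((size_t)blk[j] * q * q + (size_t)xj * q);
      for (int a = 0; a < q; ++a) E[a] += Jb[a];
    }
    double emax = E[0];
    for (int a = 1; a < q; ++a) if (E[a] > emax) emax = E[a];
    double z = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(E[a] - emax); z += p[a]; }
    const double ws = w[s] / neff;
    const int xi = X(s, i0) - 1;
    nll += ws * (std::log(z) + emax - E[xi]);
    const double inv_z = 1.0 / z;
    for (int a = 0; a < q; ++a) p[a] *= inv_z;
    // d nll / d E[a] = ws * (p[a] - 1{a == xi})
    for (int a = 0; a < q; ++a) {
      const double g = ws * (p[a] - (a == xi ? 1.0 : 0.0));
      gh[a] += g;
      p[a] = g; // reuse buffer as gradient wrt E
    }
    for (int j = 0; j < L; ++j) {
      if (j == i0) continue;
      const int xj = X(s, j) - 1;
      double* Gb = gJ + ((size_t)blk[j] * q * q + (size_t)xj * q);
      for (int a = 0; a < q; ++a) Gb[a] += p[a];
    }
  }
  // L2 terms
  double reg = 0.0;
  for (int a = 0; a < q; ++a) {
    reg += lambda_h * h[a] * h[a];
    gh[a] += 2.0 * lambda_h * h[a];
  }
  const size_t nJ = (size_t)nblk * q * q;
  for (size_t k = 0; k < nJ; ++k) {
    reg += lambda_J * J[k] * J[k];
    gJ[k] += 2.0 * lambda_J * J[k];
  }
  return List::create(_["value"] = nll + reg, _["grad"] = grad);
}

// Single-chain single-site Gibbs sampler for the Potts distribution
//   P(x) ~ exp( sum_i h_i(x_i) + sum_{i<j} J_ij(x_i, x_j) ).
// h: L x q; Jvec: array [q, q, L, L] with J[a,b,i,j] symmetric
// (J[a,b,i,j] = J[b,a,j,i]); uses R's RNG so set.seed() governs output.
// Returns n x L integer matrix of codes 1..q.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_sample(NumericMatrix h, NumericVector Jvec,
                               int n, int burn_in, int thinning) {
  const int L = h.nrow(), q = h.ncol();
  if (Jvec.size() != (R_xlen_t)q * q * L * L) stop("J has wrong length");
  const double* J = Jvec.begin();
  const size_t qq = (size_t)q * q;
  IntegerMatrix out(n, L);
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i)
    x[i] = (int)std::floor(unif_rand() * q); // 0-based states
  std::vector<double> E(q), p(q);
  const int total_sweeps = burn_in + n * thinning;
  int taken = 0;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int i = 0; i < L; ++i) {
      for (int a = 0; a < q; ++a) E[a] = h(i, a);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        // J[a, x_j, i, j]
        const double* Jb = J + ((size_t)x[j] * q + qq * ((size_t)i + (size_t)L * j));
        for (int a = 0; a < q; ++a) E[a] += Jb[a];
      }
      double emax = E[0];
      for (int a = 1; a < q; ++a) if (E[a] > emax) emax = E[a];
      double z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(E[a] - emax); z += p[a]; }
      double u = unif_rand() * z, acc = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { acc += p[a]; if (u <= acc) { pick = a; break; } }
      x[i] = pick;
    }
    if (sweep >= burn_in && (sweep - burn_in + 1) % thinning == 0 && taken < n) {
      for (int i = 0; i < L; ++i) out(taken, i) = x[i] + 1;
      ++taken;
    }
  }
  return out;
}
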