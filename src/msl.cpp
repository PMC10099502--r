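// Simulated-likelihood kernel for the mixed (random-coefficient) logit.
//
// Rows of Z are sorted by chooser; gstart holds 0-based row offsets per
// chooser (length n+1); chosen holds the 0-based row index of each
// chooser's chosen alternative.  Edraws is a list of n x R standard-normal
// draw matrices, one per random coefficient; ridx maps them to columns of
// Z (0-based).  theta = (beta, s).  With no random coefficients the kernel
// evaluates the plain conditional logit (R = 1, no draws).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List msl_eval_cpp(NumericVector theta, NumericMatrix Z, IntegerVector gstart,
                  IntegerVector chosen, NumericVector w, List Edraws,
                  IntegerVector ridx, bool grad, bool scores, bool probs) {
  const int K = Z.ncol();
  const int Kr = ridx.size();
  const int n = gstart.size() - 1;
  const int nr = Z.nrow();
  std::vector<NumericMatrix> E;
  for (int q = 0; q < Kr; q++) E.push_back(as<NumericMatrix>(Edraws[q]));
  const int R = Kr ? E[0].ncol() : 1;

  // row-major copy of Z for cache-friendly access in the inner loops
  std::vector<double> Zt((size_t)nr * K);
  for (int k = 0; k < K; k++)
    for (int j = 0; j < nr; j++) Zt[(size_t)j * K + k] = Z(j, k);

  // fixed-utility part
  std::vector<double> eta(nr);
  for (int j = 0; j < nr; j++) {
    double s = 0;
    const double *zr = &Zt[(size_t)j * K];
    for (int k = 0; k < K; k++) s += zr[k] * theta[k];
    eta[j] = s;
  }

  double ll = 0;
  NumericVector g(K + Kr);
  NumericVector L(n);
  NumericMatrix SC = scores ? NumericMatrix(n, K + Kr) : NumericMatrix(0, 0);
  NumericVector Prow = probs ? NumericVector(nr) : NumericVector(0);
  std::vector<double> u, p, accB(K), accS(Kr), zb(K);
  bool ok = true;

  for (int i = 0; i < n && ok; i++) {
    const int a = gstart[i], b = gstart[i + 1];
    const int M = b - a;
    if ((int)u.size() < M) { u.resize(M); p.resize(M); }
    const int c = chosen[i];
    double Li = 0;
    std::fill(accB.begin(), accB.end(), 0.0);
    std::fill(accS.begin(), accS.end(), 0.0);
    for (int r = 0; r < R; r++) {
      double mx = -1e300;
      for (int m = 0; m < M; m++) {
        double um = eta[a + m];
        const double *zr = &Zt[(size_t)(a + m) * K];
        for (int q = 0; q < Kr; q++)
          um += theta[K + q] * zr[ridx[q]] * E[q](i, r);
        if (um > 700) um = 700;
        u[m] = um;
        if (um > mx) mx = um;
      }
      double den = 0;
      for (int m = 0; m < M; m++) { p[m] = std::exp(u[m] - mx); den += p[m]; }
      const double pc = p[c - a] / den;
      Li += pc;
      if (probs)
        for (int m = 0; m < M; m++) Prow[a + m] += p[m] / den;
      if (grad || scores) {
        const double *zc = &Zt[(size_t)c * K];
        std::fill(zb.begin(), zb.end(), 0.0);
        for (int m = 0; m < M; m++) {
          const double pm = p[m];
          const double *zr = &Zt[(size_t)(a + m) * K];
          for (int k = 0; k < K; k++) zb[k] += pm * zr[k];
        }
        for (int k = 0; k < K; k++)
          accB[k] += (zc[k] - zb[k] / den) * pc;
        for (int q = 0; q < Kr; q++) {
          const int k = ridx[q];
          accS[q] += (zc[k] - zb[k] / den) * pc * E[q](i, r);
        }
      }
    }
    Li /= R;
    if (!(Li > 0) || !std::isfinite(Li)) { ok = false; break; }
    L[i] = Li;
    ll += w[i] * std::log(Li);
    const double inv = w[i] / (R * Li);
    if (grad || scores) {
      for (int k = 0; k < K; k++) {
        g[k] += inv * accB[k];
        if (scores) SC(i, k) = inv * accB[k];
      }
      for (int q = 0; q < Kr; q++) {
        g[K + q] += inv * accS[q];
        if (scores) SC(i, K + q) = inv * accS[q];
      }
    }
  }
  if (probs) for (int j = 0; j < nr; j++) Prow[j] /= R;
  List out = List::create(_["ll"] = ok ? ll : R_NegInf, _["L"] = L,
                          _["grad"] = g);
  if (scores) out["scores"] = SC;
  if (probs) out["probs"] = Prow;
  return out;
}
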