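#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment of two ordered label lists (restriction
// maps). A candidate alignment is a monotone set of matched label pairs
// (i_1<...<i_k on the query, j_1<...<j_k on the reference), k >= 2 (a
// single matched pair defines no interval). Each consecutive matched
// transition contributes
//   match_bonus - (residual / tol)^2
//     - miss_pen  * (skipped internal reference labels)
//     - extra_pen * (skipped internal query labels)
// where residual = (q[i_t]-q[i_{t-1}]) - (r[j_t]-r[j_{t-1}]) and
// tol = max(tol_bp, tol_rel * reference interval). Unmatched query labels
// at either end cost end_pen each beyond the first (molecule ends are
// noisy); unmatched reference labels outside the aligned span are free
// (local placement on the reference). Returns the best-scoring alignment.
// [[Rcpp::export]]
List align_dp_cpp(NumericVector q, NumericVector r,
                  double tol_bp, double tol_rel,
                  double match_bonus, double miss_pen, double extra_pen,
                  double end_pen, int max_skip) {
  const int nq = q.size(), nr = r.size();
  const double NEG = -1e18;
  if (nq < 2 || nr < 2)
    return List::create(_["score"] = NEG);

  // M: best prefix value ending matched at (i, j), allowing a fresh start
  // (k = 1) there; M2: best value whose last step is a transition (k >= 2).
  NumericMatrix M(nq, nr), M2(nq, nr);
  IntegerMatrix Pi(nq, nr), Pj(nq, nr), Fr(nq, nr);

  for (int i = 0; i < nq; ++i) {
    double fresh = -end_pen * std::max(0, i - 1); // labels before i, 1 free
    for (int j = 0; j < nr; ++j) {
      double bestT = NEG;
      int bi = -1, bj = -1;
      int i0 = std::max(0, i - max_skip), j0 = std::max(0, j - max_skip);
      for (int ip = i0; ip < i; ++ip) {
        double dq = q[i] - q[ip];
        for (int jp = j0; jp < j; ++jp) {
          double dr = r[j] - r[jp];
          double tol = std::max(tol_bp, tol_rel * dr);
          double res = dq - dr;
          double gain = match_bonus - (res / tol) * (res / tol)
            - miss_pen * (j - jp - 1) - extra_pen * (i - ip - 1);
          double cand = M(ip, jp) + gain;
          if (cand > bestT + 1e-12) { bestT = cand; bi = ip; bj = jp; }
        }
      }
      M2(i, j) = bestT;
      Pi(i, j) = bi;
      Pj(i, j) = bj;
      if (bestT > fresh + 1e-12) {
        M(i, j) = bestT; Fr(i, j) = 1;
      } else {
        M(i, j) = fresh; Fr(i, j) = 0;
      }
    }
  }

  double best = NEG;
  int ei = -1, ej = -1;
  for (int i = 0; i < nq; ++i) {
    double tail_pen = end_pen * std::max(0, nq - i - 2);
    for (int j = 0; j < nr; ++j) {
      if (Pi(i, j) < 0) continue;
      double s = M2(i, j) - tail_pen;
      if (s > best + 1e-12) { best = s; ei = i; ej = j; }
    }
  }
  if (ei < 0)
    return List::create(_["score"] = NEG);

  std::vector<int> qi, rj;
  qi.push_back(ei + 1); rj.push_back(ej + 1);
  int ci = Pi(ei, ej), cj = Pj(ei, ej);
  while (true) {
    qi.push_back(ci + 1); rj.push_back(cj + 1);
    if (!Fr(ci, cj)) break;
    int ni = Pi(ci, cj), nj = Pj(ci, cj);
    ci = ni; cj = nj;
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(rj.begin(), rj.end());

  int k = qi.size();
  NumericVector residuals(k - 1);
  int missing = 0, extra = 0;
  for (int t = 1; t < k; ++t) {
    residuals[t - 1] = (q[qi[t] - 1] - q[qi[t - 1] - 1]) -
                       (r[rj[t] - 1] - r[rj[t - 1] - 1]);
    missing += rj[t] - rj[t - 1] - 1;
    extra += qi[t] - qi[t - 1] - 1;
  }

  return List::create(_["score"] = best,
                      _["qi"] = wrap(qi), _["rj"] = wrap(rj),
                      _["residuals"] = residuals,
                      _["missing"] = missing, _["extra"] = extra);
}
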