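#include <Rcpp.h>
using namespace Rcpp;

// Banded dynamic time warping between a reference x and a query y.
// The Sakoe-Chiba band is expressed in samples around the length-scaled
// diagonal; only band cells are stored. Local cost is the absolute
// amplitude difference; ties between moves prefer the diagonal so identical
// inputs align identically. Non-diagonal moves carry an additive
// gap_penalty, which suppresses the flat-region pile-ups ("singularities")
// that plain DTW produces when quiet samples value-match onto wave slopes.
// Returns the alignment cost and, optionally, the warping path.
// [[Rcpp::export(name = ".dtw_align")]]
List dtw_align(NumericVector x, NumericVector y, int band, bool need_path,
               double gap_penalty = 0.0) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty input to DTW");
  const double slope = (double)m / (double)n;
  const int minband = (int)std::ceil(std::fabs(slope - 1.0) * n) + 2;
  if (band < minband) band = minband;  // keep (n, m) reachable
  const int W = 2 * band + 1;
  const double INF = R_PosInf;

  // row i (0..n) covers query columns jlo(i) .. jlo(i)+W-1
  std::vector<int> jlo(n + 1);
  for (int i = 0; i <= n; ++i) {
    int jc = (int)std::lround(i * slope);
    int lo = jc - band;
    if (lo < 0) lo = 0;
    if (lo > m - W + 1) lo = std::max(0, m - W + 1);
    jlo[i] = lo;
  }
  std::vector<double> prev(W, INF), cur(W, INF);
  std::vector<signed char> move;
  if (need_path) move.assign((size_t)(n + 1) * W, 0);

  // virtual cell (0, 0)
  prev.assign(W, INF);
  if (jlo[0] == 0) prev[0] = 0.0;  // D(0,0)

  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    const int lo = jlo[i], loprev = jlo[i - 1];
    const int jhi = std::min(m, lo + W - 1);
    const double xi = x[i - 1];
    for (int j = std::max(1, lo); j <= jhi; ++j) {
      const int k = j - lo;
      const int kp = j - loprev;       // column j in row i-1
      const int kpd = j - 1 - loprev;  // column j-1 in row i-1
      double dd = (kpd >= 0 && kpd < W) ? prev[kpd] : INF;
      double du = (kp >= 0 && kp < W) ? prev[kp] + gap_penalty : INF;
      double dl = (k - 1 >= 0) ? cur[k - 1] + gap_penalty : INF;
      double best = dd; signed char mv = 1;
      if (du < best) { best = du; mv = 2; }
      if (dl < best) { best = dl; mv = 3; }
      if (best == INF) continue;
      cur[k] = std::fabs(xi - y[j - 1]) + best;
      if (need_path) move[(size_t)i * W + k] = mv;
    }
    prev.swap(cur);
  }
  const int kend = m - jlo[n];
  double dist = (kend >= 0 && kend < W) ? prev[kend] : INF;
  if (!R_finite(dist)) stop("DTW band too narrow for these lengths");
  if (!need_path)
    return List::create(_["dist"] = dist);

  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    pi.push_back(i); pj.push_back(j);
    signed char mv = move[(size_t)i * W + (j - jlo[i])];
    if (mv == 1) { --i; --j; }
    else if (mv == 2) { --i; }
    else if (mv == 3) { --j; }
    else break;  // reached the virtual origin
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["dist"] = dist,
                      _["index_ref"] = wrap(pi),
                      _["index_query"] = wrap(pj));
}
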