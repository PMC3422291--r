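#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Synchronization likelihood for all channel pairs of one band-filtered
// epoch, evaluated at a set of anchor (reference) vectors.
//
// x: samples x channels matrix, already band-pass filtered.
// L, m: embedding lag and dimension for this band.
// p_ref: reference recurrence probability.
// candidate_shift: spacing (samples) between successive candidate vectors.
// anchors0: 0-based start samples of the anchor vectors.
// theiler: half-width (samples) of the temporal exclusion zone around each
//   anchor; candidates with |start - anchor| <= theiler never count as
//   recurrences.
//
// Per channel and anchor the critical distance is the ceil(p_ref * N)-th
// order statistic of the (squared) distances to the N non-excluded
// candidates, so each channel's recurrence fraction is fixed at p_ref up to
// ties. The pair value is the mean of the two directed conditional
// recurrence fractions |Rx n Ry| / |Rx| and |Rx n Ry| / |Ry|.
//
// Squared distances accumulate in long double over ascending embedding
// dimension, matching R's colSums() accumulation so the R reference
// implementation reproduces this path bit for bit.
// [[Rcpp::export]]
NumericMatrix sl_pairwise_core(NumericMatrix x, int L, int m, double p_ref,
                               int candidate_shift, IntegerVector anchors0,
                               int theiler) {
  const int ns = x.nrow(), nc = x.ncol();
  const int span = (m - 1) * L;
  const int nvec = ns - span;
  if (nvec < 1)
    stop("epoch too short for embedding: need at least %d samples, got %d",
         span + 1, ns);
  if (p_ref <= 0.0 || p_ref >= 1.0) stop("p_ref must lie in (0, 1)");
  if (candidate_shift < 1) stop("candidate_shift must be >= 1");

  std::vector<int> cand;
  for (int t = 0; t < nvec; t += candidate_shift) cand.push_back(t);
  const int ncand = (int)cand.size();
  const int na = anchors0.size();
  const int min_cand = (int)std::ceil(1.0 / p_ref);

  std::vector<std::vector<std::vector<int> > > R(
      nc, std::vector<std::vector<int> >(na));
  std::vector<double> d2(ncand);
  std::vector<double> keep;
  keep.reserve(ncand);

  for (int c = 0; c < nc; ++c) {
    const double* xc = &x(0, c);
    for (int a = 0; a < na; ++a) {
      const int ap = anchors0[a];
      if (ap < 0 || ap >= nvec)
        stop("anchor at sample %d outside the embeddable range 0..%d", ap,
             nvec - 1);
      keep.clear();
      for (int j = 0; j < ncand; ++j) {
        const int cp = cand[j];
        if (std::abs(cp - ap) <= theiler) {
          d2[j] = -1.0;  // excluded marker; true distances are >= 0
          continue;
        }
        long double acc = 0.0L;
        for (int d = 0; d < m; ++d) {
          const double diff = xc[ap + d * L] - xc[cp + d * L];
          const double sq = diff * diff;
          acc += (long double)sq;
        }
        d2[j] = (double)acc;
        keep.push_back(d2[j]);
      }
      const int N = (int)keep.size();
      if (N < min_cand)
        stop("only %d non-excluded candidates at anchor %d; need >= %d for p_ref = %g",
             N, ap, min_cand, p_ref);
      const int k = (int)std::ceil(p_ref * (double)N);
      std::nth_element(keep.begin(), keep.begin() + (k - 1), keep.end());
      const double eps2 = keep[k - 1];
      std::vector<int>& set = R[c][a];
      for (int j = 0; j < ncand; ++j)
        if (d2[j] >= 0.0 && d2[j] <= eps2) set.push_back(j);
    }
  }

  const int npair = nc * (nc - 1) / 2;
  NumericMatrix out(npair, na);
  int pr = 0;
  for (int i = 0; i < nc - 1; ++i) {
    for (int j = i + 1; j < nc; ++j, ++pr) {
      for (int a = 0; a < na; ++a) {
        const std::vector<int>& A = R[i][a];
        const std::vector<int>& B = R[j][a];
        int cnt = 0;
        size_t u = 0, v = 0;
        while (u < A.size() && v < B.size()) {
          if (A[u] < B[v])
            ++u;
          else if (B[v] < A[u])
            ++v;
          else {
            ++cnt;
            ++u;
            ++v;
          }
        }
        out(pr, a) =
            (cnt / (double)A.size() + cnt / (double)B.size()) / 2.0;
      }
    }
  }
  return out;
}
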