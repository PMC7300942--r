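#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Delay vector variance curve for a single series.
//
// Delay vectors are x(k) = [x_{k-m}, ..., x_{k-1}] with target x_k, giving
// N - m (vector, target) pairs. For each span threshold tau the set
// Omega_k collects all delay vectors within Euclidean distance tau of
// x(k) (including x(k) itself); the sample variance of their targets,
// normalised by the sample variance of the whole series, is averaged over
// all sets retaining at least t0 members. Spans are uniformly spaced over
// [max(0, mu_d - n_d * sd_d), mu_d + n_d * sd_d], where mu_d and sd_d are
// the mean and population standard deviation of all pairwise distances.
//
// Per reference vector, distances are sorted once and neighbourhood target
// variances for every span come from prefix sums over the sorted order, so
// the whole curve costs O(N^2 (m + log N)) rather than O(spans * N^2 m).
// [[Rcpp::export]]
List dvv_curve_cpp(NumericVector x, int m, double n_d, int n_spans, int t0) {
  const int n = x.size();
  const int ndv = n - m;
  const double* xp = REAL(x);

  // pairwise-distance mean and population sd (two passes, single storage)
  std::vector<double> dists((size_t)ndv * (ndv - 1) / 2);
  size_t q = 0;
  for (int i = 0; i < ndv; ++i) {
    for (int j = i + 1; j < ndv; ++j) {
      double d2 = 0.0;
      for (int t = 0; t < m; ++t) {
        const double df = xp[i + t] - xp[j + t];
        d2 += df * df;
      }
      dists[q++] = std::sqrt(d2);
    }
  }
  const double npairs = (double)dists.size();
  double dsum = 0.0;
  for (size_t a = 0; a < dists.size(); ++a) dsum += dists[a];
  const double mu = dsum / npairs;
  double vsum = 0.0;
  for (size_t a = 0; a < dists.size(); ++a) {
    const double c = dists[a] - mu;
    vsum += c * c;
  }
  const double sdv = std::sqrt(vsum / npairs);

  double xm = 0.0;
  for (int i = 0; i < n; ++i) xm += xp[i];
  xm /= n;
  double xv = 0.0;
  for (int i = 0; i < n; ++i) xv += (xp[i] - xm) * (xp[i] - xm);
  xv /= (n - 1);

  const double lo = std::max(0.0, mu - n_d * sdv);
  const double hi = mu + n_d * sdv;
  const double by = (hi - lo) / (n_spans - 1);
  NumericVector spans(n_spans);
  for (int s = 0; s < n_spans; ++s) spans[s] = lo + s * by;

  std::vector<double> acc(n_spans, 0.0);
  std::vector<int> nret(n_spans, 0);
  std::vector<std::pair<double, double> > dy(ndv);  // (distance, target)
  std::vector<double> s1(ndv + 1), s2(ndv + 1), dsorted(ndv);
  for (int k = 0; k < ndv; ++k) {
    for (int i = 0; i < ndv; ++i) {
      double d2 = 0.0;
      for (int t = 0; t < m; ++t) {
        const double df = xp[k + t] - xp[i + t];
        d2 += df * df;
      }
      dy[i] = std::make_pair(std::sqrt(d2), xp[i + m]);
    }
    std::sort(dy.begin(), dy.end());
    s1[0] = s2[0] = 0.0;
    for (int i = 0; i < ndv; ++i) {
      dsorted[i] = dy[i].first;
      const double y = dy[i].second;
      s1[i + 1] = s1[i] + y;
      s2[i + 1] = s2[i] + y * y;
    }
    for (int s = 0; s < n_spans; ++s) {
      const int cnt = (int)(std::upper_bound(dsorted.begin(), dsorted.end(),
                                             spans[s]) - dsorted.begin());
      if (cnt >= t0 && cnt >= 2) {
        acc[s] += (s2[cnt] - s1[cnt] * s1[cnt] / cnt) / (cnt - 1);
        ++nret[s];
      }
    }
  }
  NumericVector sstar(n_spans);
  LogicalVector valid(n_spans);
  for (int s = 0; s < n_spans; ++s) {
    if (nret[s] > 0) {
      sstar[s] = acc[s] / nret[s] / xv;
      valid[s] = true;
    } else {
      sstar[s] = NA_REAL;
      valid[s] = false;
    }
  }
  return List::create(_["spans"] = spans, _["sigma_star"] = sstar,
                      _["valid"] = valid, _["mu_d"] = mu, _["sd_d"] = sdv,
                      _["sigma_x2"] = xv);
}
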