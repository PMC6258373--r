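#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Recurrent connectivity sampler. One independent Bernoulli draw per ordered
// pair (i -> j), with probability p_dist(d) * p_ori(dori). Distances are in
// the x-y plane. Candidate pairs are enumerated with a uniform grid whose bin
// size equals the largest cutoff, so only the 3x3 bin neighborhood of each
// source needs to be scanned.
//
// ei: 0 = excitatory source/target, 1 = inhibitory.
// theta: assigned preferred direction in degrees (used for E->E only).
// ori_dep_prob: TRUE for the "L" connection-probability rules (LL, LR).
// [[Rcpp::export]]
List build_recurrent_cpp(NumericVector x, NumericVector y,
                         IntegerVector ei, NumericVector theta,
                         double pmax_ee, double pmax_ei,
                         double cutoff_e, double cutoff_i,
                         bool ori_dep_prob) {
  const int n = x.size();
  const double cutoff_max = std::max(cutoff_e, cutoff_i);

  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double bin = cutoff_max;
  const int nbx = std::max(1, (int)std::floor((xmax - xmin) / bin) + 1);
  const int nby = std::max(1, (int)std::floor((ymax - ymin) / bin) + 1);

  // bucket cells by grid bin (counting sort)
  std::vector<int> bin_of(n), count(nbx * nby + 1, 0);
  for (int i = 0; i < n; ++i) {
    int bx = std::min(nbx - 1, (int)std::floor((x[i] - xmin) / bin));
    int by = std::min(nby - 1, (int)std::floor((y[i] - ymin) / bin));
    bin_of[i] = bx + nbx * by;
    count[bin_of[i] + 1]++;
  }
  for (int b = 0; b < nbx * nby; ++b) count[b + 1] += count[b];
  std::vector<int> order(n), fill(count.begin(), count.end() - 1);
  for (int i = 0; i < n; ++i) order[fill[bin_of[i]]++] = i;

  std::vector<int> src, tgt, nsyn;
  src.reserve(1 << 20); tgt.reserve(1 << 20); nsyn.reserve(1 << 20);

  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const bool src_e = ei[i] == 0;
    const double cutoff = src_e ? cutoff_e : cutoff_i;
    const double inv_cut = 1.0 / cutoff;
    const double cut2 = cutoff * cutoff;
    const int bx = std::min(nbx - 1, (int)std::floor((x[i] - xmin) / bin));
    const int by = std::min(nby - 1, (int)std::floor((y[i] - ymin) / bin));
    for (int dby = -1; dby <= 1; ++dby) {
      const int jy = by + dby;
      if (jy < 0 || jy >= nby) continue;
      for (int dbx = -1; dbx <= 1; ++dbx) {
        const int jx = bx + dbx;
        if (jx < 0 || jx >= nbx) continue;
        const int b = jx + nbx * jy;
        for (int q = count[b]; q < count[b + 1]; ++q) {
          const int j = order[q];
          if (j == i) continue;
          const double dx = x[i] - x[j], dy = y[i] - y[j];
          const double d2 = dx * dx + dy * dy;
          if (d2 >= cut2) continue;
          double p;
          if (src_e) {
            p = (ei[j] == 0 ? pmax_ee : pmax_ei);
          } else {
            p = 1.0;
          }
          p *= 1.0 - std::sqrt(d2) * inv_cut;
          if (ori_dep_prob && src_e && ei[j] == 0) {
            double d = std::fabs(theta[i] - theta[j]);   // thetas in [0, 360)
            if (d > 180.0) d = 360.0 - d;
            if (d > 90.0) d = 180.0 - d;
            p *= 1.0 - 0.5 * d / 90.0;
          }
          if (unif_rand() < p) {
            src.push_back(i);
            tgt.push_back(j);
            nsyn.push_back(3 + (int)std::floor(unif_rand() * 5.0));
          }
        }
      }
    }
  }

  return List::create(_["src"] = IntegerVector(src.begin(), src.end()),
                      _["tgt"] = IntegerVector(tgt.begin(), tgt.end()),
                      _["n_syn"] = IntegerVector(nsyn.begin(), nsyn.end()));
}
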