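#include <Rcpp.h>
using namespace Rcpp;

// Spatial projection of a movie onto a set of receptive-subfield kernels.
// movie is an (nx, ny, nt) array (column-major); each subfield s has a dense
// kernel patch of size wx[s] x wy[s] whose lower-left pixel is (x0[s], y0[s])
// (0-based) and whose values are stored flattened (column-major) in kern
// starting at koff[s]. Returns an nt x nsub matrix of per-frame dot products.
// [[Rcpp::export]]
NumericMatrix lgn_spatial_project_cpp(NumericVector movie, IntegerVector mdim,
                                      IntegerVector x0, IntegerVector y0,
                                      IntegerVector wx, IntegerVector wy,
                                      NumericVector kern, IntegerVector koff) {
  const int nx = mdim[0], ny = mdim[1], nt = mdim[2];
  const int nsub = x0.size();
  NumericMatrix out(nt, nsub);
  const double *mv = movie.begin();
  const double *kv = kern.begin();

  for (int s = 0; s < nsub; ++s) {
    if (x0[s] < 0 || y0[s] < 0 || x0[s] + wx[s] > nx || y0[s] + wy[s] > ny)
      stop("subfield window falls outside the movie frame");
  }
  // block over frames so that each block's movie data stays cached while all
  // subfield kernels stream over it
  const int BT = 16;
  for (int t0 = 0; t0 < nt; t0 += BT) {
    const int t1 = std::min(nt, t0 + BT);
    for (int s = 0; s < nsub; ++s) {
      const int sx = x0[s], sy = y0[s], w = wx[s], h = wy[s];
      const double *kp = kv + koff[s];
      double *op = &out(0, s);
      for (int t = t0; t < t1; ++t) {
        const double *frame = mv + (R_xlen_t)t * nx * ny;
        double acc = 0.0;
        for (int j = 0; j < h; ++j) {
          const double *row = frame + sx + (R_xlen_t)(sy + j) * nx;
          const double *kr = kp + (R_xlen_t)j * w;
          for (int i = 0; i < w; ++i) acc += kr[i] * row[i];
        }
        op[t] = acc;
      }
    }
  }
  return out;
}
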