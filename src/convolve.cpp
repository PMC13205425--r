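#include <Rcpp.h>
using namespace Rcpp;

// Same-size true 2-D convolution (kernel flipped relative to correlation)
// with replicate (edge-clamp) border padding.
//
// Anchor convention: the kernel origin sits at row/col floor(m/2) (0-based),
// the exact centre for odd sizes. With top/left padding chosen to match, the
// inner sum reduces to R[i,j] = sum_{u,v} K[u,v] * P[i+mr-1-u, j+mc-1-v],
// which is the convolution sum over the padded image P.
// [[Rcpp::export]]
NumericMatrix conv2_replicate(NumericMatrix img, NumericMatrix ker) {
  const int M = img.nrow(), N = img.ncol();
  const int mr = ker.nrow(), mc = ker.ncol();
  if (M < 1 || N < 1) stop("empty image");
  if (mr < 1 || mc < 1) stop("empty kernel");
  const int ar = mr / 2, ac = mc / 2;          // anchor, 0-based
  const int pt = mr - 1 - ar, pl = mc - 1 - ac; // top/left pad
  const int PM = M + mr - 1, PN = N + mc - 1;

  // replicate-padded copy (clamp indices to the valid range)
  std::vector<double> P((size_t)PM * PN);
  for (int j = 0; j < PN; ++j) {
    int sj = j - pl;
    if (sj < 0) sj = 0; else if (sj >= N) sj = N - 1;
    double* col = &P[(size_t)j * PM];
    for (int i = 0; i < PM; ++i) {
      int si = i - pt;
      if (si < 0) si = 0; else if (si >= M) si = M - 1;
      col[i] = img(si, sj);
    }
  }

  NumericMatrix out(M, N);
  for (int j = 0; j < N; ++j) {
    double* ocol = &out(0, j);
    for (int v = 0; v < mc; ++v) {
      const double* pcol = &P[(size_t)(j + mc - 1 - v) * PM];
      for (int u = 0; u < mr; ++u) {
        const double k = ker(u, v);
        if (k == 0.0) continue;
        const double* prow = pcol + (mr - 1 - u);
        for (int i = 0; i < M; ++i) ocol[i] += k * prow[i];
      }
    }
  }
  return out;
}
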