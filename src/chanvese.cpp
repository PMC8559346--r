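#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Morphological Chan-Vese (active contour without edges) on a binary level
// set. Each iteration: recompute the two region means, reassign boundary
// pixels (3x3 min != max) to the region with the closer mean, then apply
// one 3x3 binary median pass as the curvature/smoothing term.
// Unconditionally stable; the update is a deterministic map of the mask, so
// once an iteration leaves the mask unchanged every further iteration
// would too and the loop exits at that exact fixed point.

static inline int med9(const int* u, int i, int j, int H, int W) {
  int cnt = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    int jj = j + dj; if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
    const int* col = u + (size_t)jj * H;
    for (int di = -1; di <= 1; ++di) {
      int ii = i + di; if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
      cnt += col[ii];
    }
  }
  return cnt >= 5 ? 1 : 0;
}

static inline void minmax9(const int* u, int i, int j, int H, int W,
                           int& mn, int& mx) {
  mn = 1; mx = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    int jj = j + dj; if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
    const int* col = u + (size_t)jj * H;
    for (int di = -1; di <= 1; ++di) {
      int ii = i + di; if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
      const int val = col[ii];
      if (val < mn) mn = val;
      if (val > mx) mx = val;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix acwe_evolve(NumericMatrix img, IntegerMatrix init,
                          int iterations, int smoothing = 1) {
  const int H = img.nrow(), W = img.ncol();
  if (init.nrow() != H || init.ncol() != W)
    stop("mask and image extents differ");
  const size_t n = (size_t)H * W;
  std::vector<int> u(init.begin(), init.end());
  std::vector<int> v(n);
  std::vector<int> prev1(n), prev2(n);
  const double* I = img.begin();

  for (int it = 0; it < iterations; ++it) {
    prev2 = prev1;
    prev1 = u;
    double s1 = 0.0, s2 = 0.0;
    size_t n1 = 0;
    for (size_t x = 0; x < n; ++x) {
      if (u[x]) { s1 += I[x]; ++n1; }
      else      { s2 += I[x]; }
    }
    if (n1 == 0 || n1 == n) break;  // one region vanished: converged
    const double c1 = s1 / n1, c2 = s2 / (n - n1);

    bool changed = false;
    // reassign pixels on the current boundary
    for (int j = 0; j < W; ++j) {
      const size_t off = (size_t)j * H;
      for (int i = 0; i < H; ++i) {
        int mn, mx;
        minmax9(u.data(), i, j, H, W, mn, mx);
        int out = u[off + i];
        if (mn != mx) {
          const double d1 = I[off + i] - c1, d2 = I[off + i] - c2;
          out = (d1 * d1 < d2 * d2) ? 1 : 0;
        }
        if (out != (int)u[off + i]) changed = true;
        v[off + i] = out;
      }
    }
    u.swap(v);

    // binary median smoothing
    for (int s = 0; s < smoothing; ++s) {
      for (int j = 0; j < W; ++j) {
        const size_t off = (size_t)j * H;
        for (int i = 0; i < H; ++i) {
          const int out = med9(u.data(), i, j, H, W);
          if (out != u[off + i]) changed = true;
          v[off + i] = out;
        }
      }
      u.swap(v);
    }
    if (!changed) break;  // exact fixed point reached
    // period-2 cycle: the remaining iterations alternate between the two
    // states, so the final state is determined by the parity of the count
    if (it >= 1 && u == prev2) {
      const int remaining = iterations - it - 1;
      if (remaining % 2 == 1) u.swap(prev1);
      break;
    }
  }

  IntegerMatrix res(H, W);
  std::copy(u.begin(), u.end(), res.begin());
  return res;
}
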