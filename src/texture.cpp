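#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component counting on a binary mask via iterative flood fill.
// conn is 4 or 8. Border-touching components count as components.
static int count_components(const std::vector<char>& mask, int nr, int nc,
                            int conn) {
  std::vector<char> seen(mask.size(), 0);
  std::vector<int> stack;
  stack.reserve(256);
  int ncomp = 0;
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (conn == 8) ? dr8 : dr4;
  const int* dc = (conn == 8) ? dc8 : dc4;
  int nn = (conn == 8) ? 8 : 4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (!mask[idx] || seen[idx]) continue;
      ++ncomp;
      seen[idx] = 1;
      stack.clear();
      stack.push_back(idx);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cr = cur % nr, cc = cur / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = c2 * nr + r2;
          if (mask[i2] && !seen[i2]) {
            seen[i2] = 1;
            stack.push_back(i2);
          }
        }
      }
    }
  }
  return ncomp;
}

// [[Rcpp::export]]
int cpp_count_components(const LogicalMatrix& img, int conn) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<char> mask((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      mask[(size_t)c * nr + r] = img(r, c) == TRUE ? 1 : 0;
  return count_components(mask, nr, nc, conn);
}

// Threshold sweep for 2D Minkowski functionals. White = height >= z.
// Returns a matrix with one row per threshold:
//   n_white, n_boundary_pairs (4-neighbour white/black), c_white (8-conn),
//   c_black (4-conn).
// [[Rcpp::export]]
IntegerMatrix cpp_minkowski_sweep(const NumericMatrix& z,
                                  const NumericVector& thresholds) {
  int nr = z.nrow(), nc = z.ncol(), nt = thresholds.size();
  IntegerMatrix out(nt, 4);
  std::vector<char> mask((size_t)nr * nc), inv((size_t)nr * nc);
  for (int t = 0; t < nt; ++t) {
    double th = thresholds[t];
    long nwhite = 0;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        char w = z(r, c) >= th ? 1 : 0;
        mask[(size_t)c * nr + r] = w;
        inv[(size_t)c * nr + r] = 1 - w;
        nwhite += w;
      }
    }
    long pairs = 0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r + 1 < nr; ++r)
        pairs += mask[(size_t)c * nr + r] != mask[(size_t)c * nr + r + 1];
    for (int c = 0; c + 1 < nc; ++c)
      for (int r = 0; r < nr; ++r)
        pairs += mask[(size_t)c * nr + r] != mask[(size_t)(c + 1) * nr + r];
    out(t, 0) = (int)nwhite;
    out(t, 1) = (int)pairs;
    out(t, 2) = count_components(mask, nr, nc, 8);
    out(t, 3) = count_components(inv, nr, nc, 4);
  }
  return out;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Grayscale dilation by a (non-flat) tip: out(x) = max_u [ z(x-u) + tip(u) ].
// Tip grid has odd sides with the apex (value 0) at the centre; borders are
// edge-replicated.
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& z,
                              const NumericMatrix& tip) {
  int nr = z.nrow(), nc = z.ncol();
  int tr = tip.nrow(), tc = tip.ncol();
  int cr = tr / 2, cc = tc / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = R_NegInf;
      for (int j = 0; j < tc; ++j) {
        for (int i = 0; i < tr; ++i) {
          int rs = clampi(r - (i - cr), 0, nr - 1);
          int cs = clampi(c - (j - cc), 0, nc - 1);
          double v = z(rs, cs) + tip(i, j);
          if (v > best) best = v;
        }
      }
      out(r, c) = best;
    }
  }
  return out;
}

// Grayscale erosion by the reflected tip with a certainty map:
// rec(x) = min_u [ img(x+u) - tip(u) ].
// A reconstructed pixel is certain when it is the unique touching point for
// at least one image pixel: dilate(rec)(y) == img(y) attained at a single
// surface position x.
// [[Rcpp::export]]
List cpp_gray_erode_certainty(const NumericMatrix& img,
                              const NumericMatrix& tip) {
  int nr = img.nrow(), nc = img.ncol();
  int tr = tip.nrow(), tc = tip.ncol();
  int cr = tr / 2, cc = tc / 2;
  NumericMatrix rec(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = R_PosInf;
      for (int j = 0; j < tc; ++j) {
        for (int i = 0; i < tr; ++i) {
          int rs = clampi(r + (i - cr), 0, nr - 1);
          int cs = clampi(c + (j - cc), 0, nc - 1);
          double v = img(rs, cs) - tip(i, j);
          if (v < best) best = v;
        }
      }
      rec(r, c) = best;
    }
  }
  // scale-aware tolerance for float comparisons along the dilate/erode chain
  double scale = 1.0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (std::abs(img(r, c)) > scale) scale = std::abs(img(r, c));
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i)
      if (std::abs(tip(i, j)) > scale) scale = std::abs(tip(i, j));
  double tol = 1e-9 * scale;

  LogicalMatrix certain(nr, nc);
  std::fill(certain.begin(), certain.end(), FALSE);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      // dilate(rec) at image pixel (r, c); track attaining surface pixel
      double best = R_NegInf;
      for (int j = 0; j < tc; ++j) {
        for (int i = 0; i < tr; ++i) {
          int rs = clampi(r - (i - cr), 0, nr - 1);
          int cs = clampi(c - (j - cc), 0, nc - 1);
          double v = rec(rs, cs) + tip(i, j);
          if (v > best) best = v;
        }
      }
      if (best < img(r, c) - tol) continue;  // tip never touches here
      int hit_r = -1, hit_c = -1;
      bool unique = true;
      for (int j = 0; j < tc && unique; ++j) {
        for (int i = 0; i < tr; ++i) {
          int rs = clampi(r - (i - cr), 0, nr - 1);
          int cs = clampi(c - (j - cc), 0, nc - 1);
          double v = rec(rs, cs) + tip(i, j);
          if (v >= best - tol) {
            if (hit_r < 0) {
              hit_r = rs;
              hit_c = cs;
            } else if (rs != hit_r || cs != hit_c) {
              unique = false;
              break;
            }
          }
        }
      }
      if (unique && hit_r >= 0) certain(hit_r, hit_c) = TRUE;
    }
  }
  return List::create(_["reconstruction"] = rec, _["certainty"] = certain);
}
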