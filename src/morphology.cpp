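#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pixel grids are R matrices (column-major); a pixel (r, c) has up to 8
// neighbours. All kernels treat nonzero as foreground.

static inline int at(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// Zhang-Suen thinning: iterative two-subpass deletion of simple border
// pixels, preserving 8-connectivity of foreground and 4-connectivity of
// background. Converges to a 1-px-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) img(r, c) = img(r, c) != 0 ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours clockwise from north (p2..p9)
          int p2 = at(img, r - 1, c),     p3 = at(img, r - 1, c + 1);
          int p4 = at(img, r, c + 1),     p5 = at(img, r + 1, c + 1);
          int p6 = at(img, r + 1, c),     p7 = at(img, r + 1, c - 1);
          int p8 = at(img, r, c - 1),     p9 = at(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = 0;
    }
  }

  // staircase cleanup: Zhang-Suen leaves corner pixels on diagonal steps
  // whose removal keeps the skeleton connected but whose presence creates
  // spurious >=3-neighbor junctions. Remove (sequentially, until stable)
  // every non-endpoint pixel whose foreground neighbors form a single
  // 8-connected cluster without it.
  bool again = true;
  while (again) {
    again = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!img(r, c)) continue;
        int nbr[8][2]; int k = 0;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (at(img, r + dr, c + dc)) { nbr[k][0] = r + dr; nbr[k][1] = c + dc; ++k; }
          }
        if (k < 2) continue;           // endpoints and isolated pixels stay
        // connectivity of the neighbor set among themselves
        int comp[8]; for (int i = 0; i < k; ++i) comp[i] = i;
        for (int i = 0; i < k; ++i)
          for (int j = i + 1; j < k; ++j) {
            if (std::abs(nbr[i][0] - nbr[j][0]) <= 1 &&
                std::abs(nbr[i][1] - nbr[j][1]) <= 1) {
              int a = comp[i], b = comp[j];
              if (a != b)
                for (int t = 0; t < k; ++t) if (comp[t] == b) comp[t] = a;
            }
          }
        bool one = true;
        for (int i = 1; i < k; ++i) if (comp[i] != comp[0]) one = false;
        if (one) { img(r, c) = 0; again = true; }
      }
    }
  }
  return img;
}

// Connected-component labelling by flood fill, connectivity 4 or 8.
// Labels are 1..k in scan order (column-major first-pixel order), so the
// labelling is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_cc_cpp(IntegerMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr8[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dc8[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  const int dr4[4] = { -1, 0, 0, 1 };
  const int dc4[4] = { 0, -1, 1, 0 };
  int nnb = connectivity == 8 ? 8 : 4;
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + nr * c2);
          }
        }
      }
    }
  }
  return lab;
}

// Count of foreground neighbours (8-connectivity) for every pixel.
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int s = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          s += at(mask, r + dr, c + dc);
        }
      out(r, c) = s;
    }
  return out;
}

// Separable Gaussian blur, kernel truncated at 3 sigma, replicated edges.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = std::min(std::max(r + i, 0), nr - 1);
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = std::min(std::max(c + i, 0), nc - 1);
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// Synchronous label growth: `steps` rounds of 8-neighbor dilation of an
// integer label image into the background; each background pixel takes the
// minimum positive neighboring label (tie -> lower id).
// [[Rcpp::export]]
IntegerMatrix grow_labels_cpp(IntegerMatrix labels, int steps) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix cur(clone(labels));
  for (int s = 0; s < steps; ++s) {
    IntegerMatrix nxt(clone(cur));
    bool any = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        if (cur(r, c) != 0) continue;
        int best = 0;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            int v = cur(rr, cc);
            if (v > 0 && (best == 0 || v < best)) best = v;
          }
        if (best > 0) { nxt(r, c) = best; any = true; }
      }
    cur = nxt;
    if (!any) break;
  }
  return cur;
}

// Otsu threshold on a histogram with `levels` bins over [lo, hi]; returns
// the lower edge of the first bin of the upper class (maximizing
// between-class variance; ties -> lowest cut).
// [[Rcpp::export]]
double otsu_cpp(NumericVector values, double lo, double hi,
                int levels = 256) {
  int n = values.size();
  std::vector<double> hist(levels, 0.0);
  double w = (hi - lo) / levels;
  if (w <= 0) return lo;
  for (int i = 0; i < n; ++i) {
    int b = (int)((values[i] - lo) / w);
    if (b < 0) b = 0;
    if (b >= levels) b = levels - 1;
    hist[b] += 1.0;
  }
  double total = n, sum = 0.0;
  for (int b = 0; b < levels; ++b) sum += b * hist[b];
  double sumB = 0.0, wB = 0.0, best = -1.0;
  int cut = 0;
  for (int b = 0; b < levels - 1; ++b) {
    wB += hist[b];
    if (wB == 0) continue;
    double wF = total - wB;
    if (wF == 0) break;
    sumB += b * hist[b];
    double mB = sumB / wB, mF = (sum - sumB) / wF;
    double between = wB * wF * (mB - mF) * (mB - mF);
    if (between > best) { best = between; cut = b + 1; }
  }
  return lo + cut * w;
}

// Box median filter with window (2*radius+1)^2; borders use the clamped
// (replicated-edge) window.
// [[Rcpp::export]]
NumericMatrix median_box_cpp(NumericMatrix img, int radius = 1) {
  if (radius < 1) stop("radius must be >= 1");
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int w = 2 * radius + 1;
  std::vector<double> win;
  win.reserve(w * w);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      win.clear();
      for (int dc = -radius; dc <= radius; ++dc)
        for (int dr = -radius; dr <= radius; ++dr) {
          int rr = std::min(std::max(r + dr, 0), nr - 1);
          int cc = std::min(std::max(c + dc, 0), nc - 1);
          win.push_back(img(rr, cc));
        }
      size_t mid = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      double hi = win[mid];
      // even count cannot occur (odd window), median is the middle element
      out(r, c) = hi;
    }
  }
  return out;
}
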