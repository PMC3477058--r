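#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Out-of-bounds neighbours are ignored (window restricted to the image), so a
// flat field is an exact fixed point of erosion, dilation and the median.

// [[Rcpp::export]]
NumericMatrix cpp_minmax_filter(const NumericMatrix& img,
                                const IntegerVector& dr,
                                const IntegerVector& dc,
                                bool dilate) {
  const int H = img.nrow(), W = img.ncol(), K = dr.size();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (int k = 0; k < K; ++k) {
        const int r = i + dr[k], c = j + dc[k];
        if (r < 0 || r >= H || c < 0 || c >= W) continue;
        const double x = img(r, c);
        if (dilate) { if (x > v) v = x; } else { if (x < v) v = x; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      buf.clear();
      for (int dc = -radius; dc <= radius; ++dc) {
        const int c = j + dc;
        if (c < 0 || c >= W) continue;
        for (int dr = -radius; dr <= radius; ++dr) {
          const int r = i + dr;
          if (r < 0 || r >= H) continue;
          buf.push_back(img(r, c));
        }
      }
      const size_t n = buf.size();
      std::sort(buf.begin(), buf.end());
      out(i, j) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return out;
}

// Two-pass connected-component labelling with union-find.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  // scan order is column-major (R storage); prior neighbours for 8-connectivity
  const int ndr4[] = {-1, 0}, ndc4[] = {0, -1};
  const int ndr8[] = {-1, 0, -1, 1}, ndc8[] = {0, -1, -1, -1};
  const int nn = (connectivity == 8) ? 4 : 2;
  const int* ndr = (connectivity == 8) ? ndr8 : ndr4;
  const int* ndc = (connectivity == 8) ? ndc8 : ndc4;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int assigned = 0;
      for (int k = 0; k < nn; ++k) {
        const int r = i + ndr[k], c = j + ndc[k];
        if (r < 0 || r >= H || c < 0 || c >= W) continue;
        const int l = lab(r, c);
        if (l > 0) {
          if (assigned == 0) assigned = l; else unite(assigned, l);
        }
      }
      if (assigned == 0) {
        assigned = ++next;
        parent.push_back(assigned);
      }
      lab(i, j) = assigned;
    }
  }
  // relabel to consecutive 1..n
  std::vector<int> remap(next + 1, 0);
  int n_final = 0;
  for (int x = 1; x <= next; ++x) {
    const int r = find(x);
    if (remap[r] == 0) remap[r] = ++n_final;
    remap[x] = remap[r];
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) lab(i, j) = remap[lab(i, j)];
  return lab;
}

// Grayscale reconstruction by erosion of `marker` constrained from below by
// `mask` (marker >= mask pointwise); sequential raster scans until stable.
// Used for morphological hole filling: fill(I) = rec_erode(border(I), I).
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_erode(const NumericMatrix& marker,
                                    const NumericMatrix& mask) {
  const int H = marker.nrow(), W = marker.ncol();
  NumericMatrix J = clone(marker);
  bool changed = true;
  while (changed) {
    changed = false;
    // forward pass: causal neighbours (N, W, NW, SW in column-major order)
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double v = J(i, j);
        if (i > 0 && J(i - 1, j) < v) v = J(i - 1, j);
        if (j > 0) {
          if (J(i, j - 1) < v) v = J(i, j - 1);
          if (i > 0 && J(i - 1, j - 1) < v) v = J(i - 1, j - 1);
          if (i < H - 1 && J(i + 1, j - 1) < v) v = J(i + 1, j - 1);
        }
        if (v < mask(i, j)) v = mask(i, j);
        if (v < J(i, j)) { J(i, j) = v; changed = true; }
      }
    }
    // backward pass
    for (int j = W - 1; j >= 0; --j) {
      for (int i = H - 1; i >= 0; --i) {
        double v = J(i, j);
        if (i < H - 1 && J(i + 1, j) < v) v = J(i + 1, j);
        if (j < W - 1) {
          if (J(i, j + 1) < v) v = J(i, j + 1);
          if (i < H - 1 && J(i + 1, j + 1) < v) v = J(i + 1, j + 1);
          if (i > 0 && J(i - 1, j + 1) < v) v = J(i - 1, j + 1);
        }
        if (v < mask(i, j)) v = mask(i, j);
        if (v < J(i, j)) { J(i, j) = v; changed = true; }
      }
    }
  }
  return J;
}

// Chamfer (3-4)/3 distance to the nearest background pixel.
// [[Rcpp::export]]
NumericMatrix cpp_chamfer_distance(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double BIG = 1e30, A = 1.0, B = 4.0 / 3.0;
  NumericMatrix d(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0 && d(i - 1, j) + A < v) v = d(i - 1, j) + A;
      if (j > 0) {
        if (d(i, j - 1) + A < v) v = d(i, j - 1) + A;
        if (i > 0 && d(i - 1, j - 1) + B < v) v = d(i - 1, j - 1) + B;
        if (i < H - 1 && d(i + 1, j - 1) + B < v) v = d(i + 1, j - 1) + B;
      }
      d(i, j) = v;
    }
  }
  for (int j = W - 1; j >= 0; --j) {
    for (int i = H - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < H - 1 && d(i + 1, j) + A < v) v = d(i + 1, j) + A;
      if (j < W - 1) {
        if (d(i, j + 1) + A < v) v = d(i, j + 1) + A;
        if (i < H - 1 && d(i + 1, j + 1) + B < v) v = d(i + 1, j + 1) + B;
        if (i > 0 && d(i - 1, j + 1) + B < v) v = d(i - 1, j + 1) + B;
      }
      d(i, j) = v;
    }
  }
  return d;
}

// 2-D correlation with an arbitrary kernel; border: "reflect" (half-sample)
// or "replicate". origin_r/origin_c are 0-based kernel indices aligned with
// the output pixel.
// [[Rcpp::export]]
NumericMatrix cpp_correlate2(const NumericMatrix& img,
                             const NumericMatrix& kernel,
                             int origin_r, int origin_c,
                             std::string border) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  const bool reflect = (border == "reflect");
  NumericMatrix out(H, W);
  auto fix = [&](int idx, int n) {
    if (reflect) {
      while (idx < 0 || idx >= n) {
        if (idx < 0) idx = -idx - 1;
        if (idx >= n) idx = 2 * n - 1 - idx;
      }
    } else {
      if (idx < 0) idx = 0;
      if (idx >= n) idx = n - 1;
    }
    return idx;
  };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int b = 0; b < kw; ++b) {
        const int c = fix(j + b - origin_c, W);
        for (int a = 0; a < kh; ++a) {
          const int r = fix(i + a - origin_r, H);
          s += kernel(a, b) * img(r, c);
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}
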