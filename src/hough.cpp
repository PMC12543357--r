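// Line-feature pre-processing (Gaussian smoothing + Canny-style edges) and
// a progressive probabilistic Hough transform with the three classic knobs:
// accumulator threshold, minimum segment length, maximum bridgeable gap.
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = 0;
        if (xx >= w) xx = w - 1;
        acc += k[i + r] * img(y, xx);
      }
      tmp(y, x) = acc;
    }
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = 0;
        if (yy >= h) yy = h - 1;
        acc += k[i + r] * tmp(yy, x);
      }
      out(y, x) = acc;
    }
  return out;
}

// [[Rcpp::export(name = ".canny_cpp")]]
NumericMatrix canny_cpp(NumericMatrix img, double low, double high) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix mag(h, w), gxm(h, w), gym(h, w);
  for (int y = 1; y < h - 1; ++y)
    for (int x = 1; x < w - 1; ++x) {
      double gx = (img(y - 1, x + 1) + 2 * img(y, x + 1) + img(y + 1, x + 1)) -
                  (img(y - 1, x - 1) + 2 * img(y, x - 1) + img(y + 1, x - 1));
      double gy = (img(y + 1, x - 1) + 2 * img(y + 1, x) + img(y + 1, x + 1)) -
                  (img(y - 1, x - 1) + 2 * img(y - 1, x) + img(y - 1, x + 1));
      mag(y, x) = std::sqrt(gx * gx + gy * gy);
      gxm(y, x) = gx;
      gym(y, x) = gy;
    }
  // non-maximum suppression with bilinear interpolation along the true
  // gradient direction (quantized 8-neighbour NMS smears corners and
  // degrades endpoint localization), then hysteresis
  auto bilinear = [&](double x, double y) -> double {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    if (x0 < 0 || y0 < 0 || x0 + 1 >= w || y0 + 1 >= h) return 0.0;
    double fx = x - x0, fy = y - y0;
    return mag(y0, x0) * (1 - fx) * (1 - fy) +
           mag(y0, x0 + 1) * fx * (1 - fy) +
           mag(y0 + 1, x0) * (1 - fx) * fy +
           mag(y0 + 1, x0 + 1) * fx * fy;
  };
  NumericMatrix thin(h, w);
  for (int y = 1; y < h - 1; ++y)
    for (int x = 1; x < w - 1; ++x) {
      double m = mag(y, x);
      if (m <= 0) continue;
      double ux = gxm(y, x) / m, uy = gym(y, x) / m;
      double m1 = bilinear(x + ux, y + uy);
      double m2 = bilinear(x - ux, y - uy);
      if (m >= m1 && m >= m2) thin(y, x) = m;
    }
  NumericMatrix out(h, w);
  std::vector<std::pair<int, int>> stack;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (thin(y, x) >= high) {
        out(y, x) = 255;
        stack.emplace_back(x, y);
      }
  while (!stack.empty()) {
    auto [x, y] = stack.back();
    stack.pop_back();
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy;
        if (xx < 0 || yy < 0 || xx >= w || yy >= h) continue;
        if (out(yy, xx) == 0 && thin(yy, xx) >= low) {
          out(yy, xx) = 255;
          stack.emplace_back(xx, yy);
        }
      }
  }
  return out;
}

namespace {
struct HRng {
  uint64_t s;
  explicit HRng(uint32_t seed) : s(seed ? seed : 1234567u) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};
} // namespace

// Progressive probabilistic Hough. Edge points are consumed in a seeded
// random order; once a point's best accumulator bin reaches `threshold` the
// corresponding line is traced through the remaining edge mask, bridging
// runs of at most `max_gap` missing pixels, and kept if its end-to-end
// length is at least `min_len`. Accepted points are removed from the mask
// and unvoted from the accumulator, as in the classic formulation.
// [[Rcpp::export(name = ".hough_segments_cpp")]]
NumericMatrix hough_segments_cpp(NumericMatrix edges, int threshold,
                                 double min_len, double max_gap,
                                 int seed = 1) {
  int h = edges.nrow(), w = edges.ncol();
  const int n_theta = 180; // 1 degree resolution
  int max_rho = (int)std::ceil(std::sqrt((double)h * h + (double)w * w));
  int n_rho = 2 * max_rho + 1;
  std::vector<double> ct(n_theta), st(n_theta);
  for (int t = 0; t < n_theta; ++t) {
    double th = t * M_PI / n_theta;
    ct[t] = std::cos(th);
    st[t] = std::sin(th);
  }
  std::vector<int> accum((size_t)n_theta * n_rho, 0);
  std::vector<uint8_t> mask((size_t)h * w, 0);
  std::vector<std::pair<int, int>> pts;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (edges(y, x) > 0) {
        mask[(size_t)y * w + x] = 1;
        pts.emplace_back(x, y);
      }
  HRng rng((uint32_t)seed);
  for (size_t i = pts.size(); i > 1; --i)
    std::swap(pts[i - 1], pts[rng.below((int)i)]);

  std::vector<std::array<double, 4>> segs;
  for (auto [px, py] : pts) {
    if (!mask[(size_t)py * w + px]) continue;
    // vote
    int best_t = -1, best_v = 0;
    for (int t = 0; t < n_theta; ++t) {
      int rho = (int)std::lround(px * ct[t] + py * st[t]) + max_rho;
      int v = ++accum[(size_t)t * n_rho + rho];
      if (v > best_v) { best_v = v; best_t = t; }
    }
    if (best_v < threshold) continue;
    // trace along the line direction (-sin, cos) both ways
    double dx = -st[best_t], dy = ct[best_t];
    double ex[2] = {(double)px, (double)px}, ey[2] = {(double)py, (double)py};
    std::vector<std::pair<int, int>> line_pts;
    line_pts.emplace_back(px, py);
    for (int sgn = 0; sgn < 2; ++sgn) {
      double sdx = sgn ? -dx : dx, sdy = sgn ? -dy : dy;
      double gap = 0;
      for (int step = 1;; ++step) {
        int x = (int)std::lround(px + sdx * step);
        int y = (int)std::lround(py + sdy * step);
        if (x < 0 || y < 0 || x >= w || y >= h) break;
        // look for an edge pixel at the ideal position or 1 px perpendicular
        int fx = -1, fy = -1;
        for (int o = -1; o <= 1; ++o) {
          int xx = x + (std::abs(sdy) > std::abs(sdx) ? o : 0);
          int yy = y + (std::abs(sdy) > std::abs(sdx) ? 0 : o);
          if (xx < 0 || yy < 0 || xx >= w || yy >= h) continue;
          if (mask[(size_t)yy * w + xx]) { fx = xx; fy = yy; break; }
        }
        if (fx >= 0) {
          gap = 0;
          ex[sgn] = fx; ey[sgn] = fy;
          line_pts.emplace_back(fx, fy);
        } else {
          gap += 1;
          if (gap > max_gap) break;
        }
      }
    }
    // refine: total-least-squares line through the collected support,
    // dropping outliers (> 1.25 px perpendicular residual, matching the tracing tolerance), endpoints
    // from the extreme projections of the surviving pixels
    double mx = 0, my = 0;
    for (auto [lx, ly] : line_pts) { mx += lx; my += ly; }
    mx /= line_pts.size(); my /= line_pts.size();
    double sxx = 0, sxy = 0, syy = 0;
    for (auto [lx, ly] : line_pts) {
      sxx += (lx - mx) * (lx - mx);
      sxy += (lx - mx) * (ly - my);
      syy += (ly - my) * (ly - my);
    }
    double ang2 = 0.5 * std::atan2(2 * sxy, sxx - syy);
    double ux = std::cos(ang2), uy = std::sin(ang2);
    double pmin = 1e30, pmax = -1e30;
    double x_lo = 0, y_lo = 0, x_hi = 0, y_hi = 0;
    for (auto [lx, ly] : line_pts) {
      double along = (lx - mx) * ux + (ly - my) * uy;
      double perp = -(lx - mx) * uy + (ly - my) * ux;
      if (std::fabs(perp) > 1.25) continue;
      if (along < pmin) { pmin = along; x_lo = lx; y_lo = ly; }
      if (along > pmax) { pmax = along; x_hi = lx; y_hi = ly; }
    }
    double len = (pmax >= pmin) ? std::hypot(x_hi - x_lo, y_hi - y_lo) : 0.0;
    if (len >= min_len) {
      segs.push_back({x_lo, y_lo, x_hi, y_hi});
      // remove the segment's support and its votes
      for (auto [lx, ly] : line_pts) {
        if (!mask[(size_t)ly * w + lx]) continue;
        mask[(size_t)ly * w + lx] = 0;
        for (int t = 0; t < n_theta; ++t) {
          int rho = (int)std::lround(lx * ct[t] + ly * st[t]) + max_rho;
          --accum[(size_t)t * n_rho + rho];
        }
      }
    } else {
      // unpromising seed: drop it so it is not revisited
      mask[(size_t)py * w + px] = 0;
      for (int t = 0; t < n_theta; ++t) {
        int rho = (int)std::lround(px * ct[t] + py * st[t]) + max_rho;
        --accum[(size_t)t * n_rho + rho];
      }
    }
  }
  NumericMatrix out((int)segs.size(), 4);
  for (size_t i = 0; i < segs.size(); ++i)
    for (int j = 0; j < 4; ++j) out((int)i, j) = segs[i][j];
  return out;
}
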