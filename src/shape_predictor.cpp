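// Gradient-boosted cascade of regression trees for landmark prediction.
//
// The predictor starts from the training-set mean shape placed in the
// image's bounding box and refines it through `cascade_depth` stages. Each
// stage draws a pool of candidate pixel positions (indexed relative to the
// nearest mean-shape landmark), extracts their intensities under a
// per-sample similarity transform, and boosts `trees_per_cascade`
// depth-limited regression trees on pixel-intensity-difference features.
// Split candidates prefer nearby pixel pairs through an exponential prior
// exp(-dist/lambda). All randomness flows from one 32-bit seed, so a fixed
// (data, hyperparameters, seed) triple reproduces the model bit for bit.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// explicit xorshift-style generator: identical streams on every platform,
// no reliance on implementation-defined std distributions
struct Rng {
  uint64_t s;
  explicit Rng(uint32_t seed) : s(seed ? seed : 0x9e3779b9u) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int uint_below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Sample {
  int image;                  // index of the owning training image
  std::vector<double> cur;    // current shape estimate, normalized, 2L
  std::vector<double> target; // ground-truth shape, normalized, 2L
};

// similarity (scale+rotation) part of the transform taking the mean shape
// onto `cur`, least squares over landmarks; translation is implicit because
// feature offsets are anchored at a current landmark position
void similarity_mean_to_cur(const std::vector<double> &mean,
                            const std::vector<double> &cur, int L, double &a,
                            double &b) {
  double mx = 0, my = 0, cx = 0, cy = 0;
  for (int k = 0; k < L; ++k) {
    mx += mean[2 * k]; my += mean[2 * k + 1];
    cx += cur[2 * k];  cy += cur[2 * k + 1];
  }
  mx /= L; my /= L; cx /= L; cy /= L;
  double num_a = 0, num_b = 0, den = 0;
  for (int k = 0; k < L; ++k) {
    double x = mean[2 * k] - mx, y = mean[2 * k + 1] - my;
    double xp = cur[2 * k] - cx, yp = cur[2 * k + 1] - cy;
    num_a += x * xp + y * yp;
    num_b += x * yp - y * xp;
    den += x * x + y * y;
  }
  if (den < 1e-12) { a = 1.0; b = 0.0; return; }
  a = num_a / den;
  b = num_b / den;
}

inline double read_pixel(const NumericMatrix &img, double px, double py) {
  int x = (int)std::lround(px), y = (int)std::lround(py);
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (x >= img.ncol()) x = img.ncol() - 1;
  if (y >= img.nrow()) y = img.nrow() - 1;
  return img(y, x);
}

// extract the feature pool intensities for one sample
void extract_features(const NumericMatrix &img, const double *box,
                      const std::vector<double> &mean,
                      const std::vector<double> &cur, int L,
                      const std::vector<int> &anchor,
                      const std::vector<double> &delta, int P, double *feats) {
  double a, b;
  similarity_mean_to_cur(mean, cur, L, a, b);
  double left = box[0], top = box[1], bw = box[2], bh = box[3];
  for (int j = 0; j < P; ++j) {
    double dx = delta[2 * j], dy = delta[2 * j + 1];
    double u = cur[2 * anchor[j]] + a * dx - b * dy;
    double v = cur[2 * anchor[j] + 1] + b * dx + a * dy;
    feats[j] = read_pixel(img, left + u * bw, top + v * bh);
  }
}

struct SplitNode {
  int f1, f2;
  double thresh;
};

} // namespace

// [[Rcpp::export(name = ".train_cascade_cpp")]]
List train_cascade_cpp(List images, NumericMatrix shapes, NumericMatrix boxes,
                       List hp, int seed) {
  int n = images.size();
  if (n < 1) stop("empty training set");
  int L = shapes.ncol() / 2;
  int cascade_depth = as<int>(hp["cascade_depth"]);
  int tree_depth = as<int>(hp["tree_depth"]);
  int n_trees = as<int>(hp["trees_per_cascade"]);
  double nu = as<double>(hp["learning_rate"]);
  int oversampling = as<int>(hp["oversampling"]);
  int pool_size = as<int>(hp["feature_pool_size"]);
  int n_test_splits = as<int>(hp["test_splits"]);
  double padding = as<double>(hp["feature_pool_padding"]);
  double lambda = as<double>(hp["regularization"]);

  std::vector<NumericMatrix> imgs(n);
  for (int i = 0; i < n; ++i) imgs[i] = as<NumericMatrix>(images[i]);

  // normalized (box-relative) ground-truth shapes
  std::vector<std::vector<double>> norm(n, std::vector<double>(2 * L));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < L; ++k) {
      norm[i][2 * k] = (shapes(i, 2 * k) - boxes(i, 0)) / boxes(i, 2);
      norm[i][2 * k + 1] = (shapes(i, 2 * k + 1) - boxes(i, 1)) / boxes(i, 3);
    }
  std::vector<double> mean(2 * L, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 2 * L; ++d) mean[d] += norm[i][d];
  for (int d = 0; d < 2 * L; ++d) mean[d] /= n;

  Rng rng((uint32_t)seed);

  // oversampled training pool: first initialization is the mean shape, the
  // rest start from the shape of a randomly drawn other training image
  std::vector<Sample> samples;
  samples.reserve((size_t)n * oversampling);
  for (int i = 0; i < n; ++i)
    for (int o = 0; o < oversampling; ++o) {
      Sample s;
      s.image = i;
      s.target = norm[i];
      if (o == 0 || n == 1)
        s.cur = mean;
      else {
        int other = rng.uint_below(n - 1);
        if (other >= i) ++other;
        s.cur = norm[other];
      }
      samples.push_back(std::move(s));
    }
  int S = (int)samples.size();
  int n_nodes = (1 << tree_depth) - 1;
  int n_leaves = 1 << tree_depth;

  List cascades(cascade_depth);
  std::vector<double> feats((size_t)S * pool_size);
  const double *boxp = REAL(boxes);
  auto box_row = [&](int i, double *b4) {
    b4[0] = boxp[i]; b4[1] = boxp[i + n]; b4[2] = boxp[i + 2 * n];
    b4[3] = boxp[i + 3 * n];
  };

  for (int c = 0; c < cascade_depth; ++c) {
    // feature pool for this stage
    std::vector<double> pool_pos(2 * pool_size);
    std::vector<int> anchor(pool_size);
    std::vector<double> delta(2 * pool_size);
    for (int j = 0; j < pool_size; ++j) {
      double u = -padding + rng.u01() * (1.0 + 2 * padding);
      double v = -padding + rng.u01() * (1.0 + 2 * padding);
      pool_pos[2 * j] = u;
      pool_pos[2 * j + 1] = v;
      int best = 0;
      double bestd = 1e30;
      for (int k = 0; k < L; ++k) {
        double dx = u - mean[2 * k], dy = v - mean[2 * k + 1];
        double d2 = dx * dx + dy * dy;
        if (d2 < bestd) { bestd = d2; best = k; }
      }
      anchor[j] = best;
      delta[2 * j] = u - mean[2 * best];
      delta[2 * j + 1] = v - mean[2 * best + 1];
    }

    // features at the stage's starting shapes
    for (int s = 0; s < S; ++s) {
      double b4[4];
      box_row(samples[s].image, b4);
      extract_features(imgs[samples[s].image], b4, mean, samples[s].cur, L,
                       anchor, delta, pool_size, &feats[(size_t)s * pool_size]);
    }

    std::vector<std::vector<double>> resid(S, std::vector<double>(2 * L));
    for (int s = 0; s < S; ++s)
      for (int d = 0; d < 2 * L; ++d)
        resid[s][d] = samples[s].target[d] - samples[s].cur[d];

    IntegerVector all_f1(n_trees * n_nodes), all_f2(n_trees * n_nodes);
    NumericVector all_thresh(n_trees * n_nodes);
    NumericVector all_leaves((size_t)n_trees * n_leaves * 2 * L);

    std::vector<int> node_of(S);
    std::vector<double> sum_buf(2 * L);
    for (int t = 0; t < n_trees; ++t) {
      std::fill(node_of.begin(), node_of.end(), 0);
      std::vector<SplitNode> nodes(n_nodes);
      // breadth-first over the complete binary tree
      for (int nd = 0; nd < n_nodes; ++nd) {
        // members of this node
        std::vector<int> members;
        for (int s = 0; s < S; ++s)
          if (node_of[s] == nd) members.push_back(s);
        SplitNode best{0, 0, 0.0};
        double best_gain = -1.0;
        for (int q = 0; q < n_test_splits; ++q) {
          // pixel pair with exponential proximity prior
          int f1 = 0, f2 = 0;
          for (int attempt = 0; attempt < 64; ++attempt) {
            f1 = rng.uint_below(pool_size);
            f2 = rng.uint_below(pool_size);
            if (f1 == f2) continue;
            double dx = pool_pos[2 * f1] - pool_pos[2 * f2];
            double dy = pool_pos[2 * f1 + 1] - pool_pos[2 * f2 + 1];
            double accept = std::exp(-std::sqrt(dx * dx + dy * dy) / lambda);
            if (rng.u01() < accept) break;
          }
          double thresh = (rng.u01() * 256.0 - 128.0) / 2.0;
          // gain: |sum_l|^2/n_l + |sum_r|^2/n_r over residual vectors
          std::fill(sum_buf.begin(), sum_buf.end(), 0.0);
          int n_l = 0;
          for (int mi : members) {
            double fv = feats[(size_t)mi * pool_size + f1] -
                        feats[(size_t)mi * pool_size + f2];
            if (fv > thresh) {
              ++n_l;
              for (int d = 0; d < 2 * L; ++d) sum_buf[d] += resid[mi][d];
            }
          }
          int n_r = (int)members.size() - n_l;
          if (n_l == 0 || n_r == 0) continue;
          std::vector<double> sum_all(2 * L, 0.0);
          for (int mi : members)
            for (int d = 0; d < 2 * L; ++d) sum_all[d] += resid[mi][d];
          double gl = 0, gr = 0;
          for (int d = 0; d < 2 * L; ++d) {
            double sr = sum_all[d] - sum_buf[d];
            gl += sum_buf[d] * sum_buf[d];
            gr += sr * sr;
          }
          double gain = gl / n_l + gr / n_r;
          if (gain > best_gain) {
            best_gain = gain;
            best = SplitNode{f1, f2, thresh};
          }
        }
        nodes[nd] = best;
        // route members (children indices 2*nd+1, 2*nd+2)
        for (int mi : members) {
          double fv = feats[(size_t)mi * pool_size + best.f1] -
                      feats[(size_t)mi * pool_size + best.f2];
          node_of[mi] = 2 * nd + (fv > best.thresh ? 1 : 2);
        }
        all_f1[t * n_nodes + nd] = best.f1;
        all_f2[t * n_nodes + nd] = best.f2;
        all_thresh[t * n_nodes + nd] = best.thresh;
      }
      // leaves: shrunken mean residual; update shapes and residuals
      std::vector<std::vector<double>> leaf_sum(n_leaves,
                                                std::vector<double>(2 * L, 0.0));
      std::vector<int> leaf_n(n_leaves, 0);
      for (int s = 0; s < S; ++s) {
        int leaf = node_of[s] - n_nodes;
        ++leaf_n[leaf];
        for (int d = 0; d < 2 * L; ++d) leaf_sum[leaf][d] += resid[s][d];
      }
      for (int lf = 0; lf < n_leaves; ++lf) {
        size_t off = ((size_t)t * n_leaves + lf) * 2 * L;
        if (leaf_n[lf] > 0)
          for (int d = 0; d < 2 * L; ++d)
            all_leaves[off + d] = nu * leaf_sum[lf][d] / leaf_n[lf];
      }
      for (int s = 0; s < S; ++s) {
        size_t off = ((size_t)t * n_leaves + (node_of[s] - n_nodes)) * 2 * L;
        for (int d = 0; d < 2 * L; ++d) {
          samples[s].cur[d] += all_leaves[off + d];
          resid[s][d] -= all_leaves[off + d];
        }
      }
    }
    cascades[c] = List::create(
        _["anchor"] = IntegerVector(anchor.begin(), anchor.end()),
        _["delta"] = NumericVector(delta.begin(), delta.end()),
        _["pool_pos"] = NumericVector(pool_pos.begin(), pool_pos.end()),
        _["f1"] = all_f1, _["f2"] = all_f2, _["thresh"] = all_thresh,
        _["leaves"] = all_leaves);
  }

  return List::create(_["n_landmarks"] = L,
                      _["mean_shape"] = NumericVector(mean.begin(), mean.end()),
                      _["tree_depth"] = tree_depth,
                      _["trees_per_cascade"] = n_trees,
                      _["cascades"] = cascades);
}

// [[Rcpp::export(name = ".predict_cascade_cpp")]]
NumericMatrix predict_cascade_cpp(List model, NumericMatrix image,
                                  NumericVector box) {
  int L = as<int>(model["n_landmarks"]);
  NumericVector mean_v = model["mean_shape"];
  std::vector<double> mean(mean_v.begin(), mean_v.end());
  int tree_depth = as<int>(model["tree_depth"]);
  int n_trees = as<int>(model["trees_per_cascade"]);
  int n_nodes = (1 << tree_depth) - 1;
  int n_leaves = 1 << tree_depth;
  List cascades = model["cascades"];

  std::vector<double> cur = mean;
  double b4[4] = {box[0], box[1], box[2], box[3]};

  for (int c = 0; c < cascades.size(); ++c) {
    List cas = cascades[c];
    IntegerVector anchor_v = cas["anchor"];
    NumericVector delta_v = cas["delta"];
    IntegerVector f1 = cas["f1"], f2 = cas["f2"];
    NumericVector thresh = cas["thresh"], leaves = cas["leaves"];
    int P = anchor_v.size();
    std::vector<int> anchor(anchor_v.begin(), anchor_v.end());
    std::vector<double> delta(delta_v.begin(), delta_v.end());
    std::vector<double> feats(P);
    extract_features(image, b4, mean, cur, L, anchor, delta, P, feats.data());
    for (int t = 0; t < n_trees; ++t) {
      int nd = 0;
      while (nd < n_nodes) {
        double fv = feats[f1[t * n_nodes + nd]] - feats[f2[t * n_nodes + nd]];
        nd = 2 * nd + (fv > thresh[t * n_nodes + nd] ? 1 : 2);
      }
      size_t off = ((size_t)t * n_leaves + (nd - n_nodes)) * 2 * L;
      for (int d = 0; d < 2 * L; ++d) cur[d] += leaves[off + d];
    }
  }

  NumericMatrix out(L, 2);
  for (int k = 0; k < L; ++k) {
    double x = box[0] + cur[2 * k] * box[2];
    double y = box[1] + cur[2 * k + 1] * box[3];
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (x > image.ncol() - 1) x = image.ncol() - 1;
    if (y > image.nrow() - 1) y = image.nrow() - 1;
    out(k, 0) = x;
    out(k, 1) = y;
  }
  return out;
}
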