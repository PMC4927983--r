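#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// reflect index into [0, n-1] (mirror without repeating the edge sample,
// i.e. "reflect" padding: -1 -> 1, n -> n-2)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  int H = img.nrow(), W = img.ncol(), r = window / 2, k = window * window;
  NumericMatrix out(H, W);
  std::vector<double> buf(k);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect_idx(j + dj, W);
        for (int di = -r; di <= r; ++di)
          buf[m++] = img(reflect_idx(i + di, H), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + k / 2 - 1, buf.end());
        med = 0.5 * (med + buf[k / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Region growing by a FIFO queue: 8-connected flood from the seed; a
// neighbour joins when |I - mean(region)| <= tol, the mean being updated
// incrementally as each pixel is admitted.
// [[Rcpp::export]]
LogicalMatrix region_grow_cpp(NumericMatrix img, int seed_row, int seed_col,
                              double tol) {
  int H = img.nrow(), W = img.ncol();
  LogicalMatrix mask(H, W);
  std::queue<std::pair<int, int>> q;
  int sr = seed_row - 1, sc = seed_col - 1;
  double sum = img(sr, sc);
  long n = 1;
  mask(sr, sc) = true;
  q.push({sr, sc});
  while (!q.empty()) {
    auto p = q.front();
    q.pop();
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        int i = p.first + di, j = p.second + dj;
        if (i < 0 || i >= H || j < 0 || j >= W || mask(i, j)) continue;
        double mu = sum / n;
        if (std::fabs(img(i, j) - mu) <= tol) {
          mask(i, j) = true;
          sum += img(i, j);
          ++n;
          q.push({i, j});
        }
      }
    }
  }
  return mask;
}

// Connected-component labeling (connectivity 4 or 8), labels 1..n, 0 = bg.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      lab(i0, j0) = ++next;
      q.push({i0, j0});
      while (!q.empty()) {
        auto p = q.front();
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            if (connectivity == 4 && di != 0 && dj != 0) continue;
            int i = p.first + di, j = p.second + dj;
            if (i < 0 || i >= H || j < 0 || j >= W) continue;
            if (!mask(i, j) || lab(i, j)) continue;
            lab(i, j) = next;
            q.push({i, j});
          }
        }
      }
    }
  }
  return lab;
}

// One-dimensional online SOM on n x d feature rows. Linear learning-rate and
// neighbourhood-radius schedules over epochs; Gaussian neighbourhood on the
// unit chain; presentation order reshuffled per epoch with R's RNG so results
// follow set.seed(). Returns final weights, per-row BMU labels and the
// end-of-epoch quantization-error trace.
// [[Rcpp::export]]
List som_fit_cpp(NumericMatrix X, NumericMatrix init_w, int n_epochs,
                 double lr0, double lr1, double rad0, double rad1) {
  int n = X.nrow(), d = X.ncol(), U = init_w.nrow();
  NumericMatrix w = clone(init_w);
  NumericVector qe(n_epochs);
  Function sample_int("sample.int");
  for (int e = 0; e < n_epochs; ++e) {
    double f = (n_epochs > 1) ? (double)e / (n_epochs - 1) : 0.0;
    double lr = lr0 + (lr1 - lr0) * f;
    double rad = rad0 + (rad1 - rad0) * f;
    IntegerVector ord = sample_int(n, n);
    for (int t = 0; t < n; ++t) {
      int i = ord[t] - 1;
      int bmu = 0;
      double best = R_PosInf;
      for (int u = 0; u < U; ++u) {
        double s = 0;
        for (int k = 0; k < d; ++k) {
          double diff = X(i, k) - w(u, k);
          s += diff * diff;
        }
        if (s < best) { best = s; bmu = u; }
      }
      for (int u = 0; u < U; ++u) {
        double dist = std::fabs(u - bmu);
        double h;
        if (rad <= 1e-12) h = (dist == 0) ? 1.0 : 0.0;
        else h = std::exp(-(dist * dist) / (2.0 * rad * rad));
        if (h < 1e-12) continue;
        for (int k = 0; k < d; ++k)
          w(u, k) += lr * h * (X(i, k) - w(u, k));
      }
    }
    double s = 0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      for (int u = 0; u < U; ++u) {
        double sq = 0;
        for (int k = 0; k < d; ++k) {
          double diff = X(i, k) - w(u, k);
          sq += diff * diff;
        }
        if (sq < best) best = sq;
      }
      s += std::sqrt(best);
    }
    qe[e] = s / n;
  }
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < U; ++u) {
      double sq = 0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - w(u, k);
        sq += diff * diff;
      }
      if (sq < best) { best = sq; bmu = u; }
    }
    labels[i] = bmu + 1;
  }
  return List::create(_["weights"] = w, _["labels"] = labels, _["qe"] = qe);
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Online (per-sample) backpropagation for a d - h - m sigmoid network.
// Weights updated sample by sample with fixed learning rate eta; presentation
// order reshuffled per epoch with R's RNG. Stops when the full-pass MSE
// (mean over samples and outputs of squared error) reaches target_mse.
// [[Rcpp::export]]
List mlp_fit_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix W1,
                 NumericVector b1, NumericMatrix W2, NumericVector b2,
                 double eta, int max_epochs, double target_mse) {
  int n = X.nrow(), d = X.ncol(), h = W1.ncol(), m = W2.ncol();
  NumericMatrix w1 = clone(W1), w2 = clone(W2);
  NumericVector bb1 = clone(b1), bb2 = clone(b2);
  std::vector<double> hid(h), out(m), dout(m), dhid(h);
  std::vector<double> mse_trace;
  Function sample_int("sample.int");
  bool diverged = false;
  int epochs_run = 0;
  for (int e = 0; e < max_epochs; ++e) {
    IntegerVector ord = sample_int(n, n);
    for (int t = 0; t < n; ++t) {
      int i = ord[t] - 1;
      for (int j = 0; j < h; ++j) {
        double z = bb1[j];
        for (int k = 0; k < d; ++k) z += X(i, k) * w1(k, j);
        hid[j] = sigmoid(z);
      }
      for (int j = 0; j < m; ++j) {
        double z = bb2[j];
        for (int k = 0; k < h; ++k) z += hid[k] * w2(k, j);
        out[j] = sigmoid(z);
        dout[j] = (out[j] - Y(i, j)) * out[j] * (1.0 - out[j]);
      }
      for (int k = 0; k < h; ++k) {
        double s = 0;
        for (int j = 0; j < m; ++j) s += dout[j] * w2(k, j);
        dhid[k] = s * hid[k] * (1.0 - hid[k]);
      }
      for (int j = 0; j < m; ++j) {
        for (int k = 0; k < h; ++k) w2(k, j) -= eta * dout[j] * hid[k];
        bb2[j] -= eta * dout[j];
      }
      for (int j = 0; j < h; ++j) {
        for (int k = 0; k < d; ++k) w1(k, j) -= eta * dhid[j] * X(i, k);
        bb1[j] -= eta * dhid[j];
      }
    }
    // full-pass error after this epoch's updates
    double se = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < h; ++j) {
        double z = bb1[j];
        for (int k = 0; k < d; ++k) z += X(i, k) * w1(k, j);
        hid[j] = sigmoid(z);
      }
      for (int j = 0; j < m; ++j) {
        double z = bb2[j];
        for (int k = 0; k < h; ++k) z += hid[k] * w2(k, j);
        double err = sigmoid(z) - Y(i, j);
        se += err * err;
      }
    }
    double mse = se / (n * m);
    mse_trace.push_back(mse);
    epochs_run = e + 1;
    if (!std::isfinite(mse)) { diverged = true; break; }
    if (mse <= target_mse) break;
  }
  return List::create(_["W1"] = w1, _["b1"] = bb1, _["W2"] = w2,
                      _["b2"] = bb2, _["mse_trace"] = wrap(mse_trace),
                      _["epochs_run"] = epochs_run,
                      _["diverged"] = diverged);
}
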