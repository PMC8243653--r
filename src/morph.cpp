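// Intra-patient template morphology engine.
//
// For every evaluated beat, and for each (segment, neighborhood, lead)
// combination, a template is rebuilt from the neighboring beats:
// segments are aligned by maximum normalized cross-correlation (NCC)
// against a provisional element-wise median reference, outliers
// (alignment NCC below a threshold) are excluded, and the retained
// aligned segments are averaged. The beat is then scored against the
// template: maximum NCC, its lag, and the template's median per-sample
// standard deviation. Hot path of the package, hence C++.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double kEps = 1e-12;

// NCC between x and ref where x is shifted by `lag`: x[i] is compared
// with ref[i - lag] over the valid overlap. Zero-mean, unit-energy
// normalization on the overlapping parts. Returns 0 if either part has
// (numerically) zero variance.
double ncc_at_lag(const double* x, const double* ref, int n, int lag) {
  int lo = std::max(0, lag);
  int hi = std::min(n - 1, n - 1 + lag);
  int m = hi - lo + 1;
  if (m < 2) return 0.0;
  double mx = 0.0, mr = 0.0;
  for (int i = lo; i <= hi; ++i) {
    mx += x[i];
    mr += ref[i - lag];
  }
  mx /= m;
  mr /= m;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (int i = lo; i <= hi; ++i) {
    double a = x[i] - mx, b = ref[i - lag] - mr;
    sxy += a * b;
    sxx += a * a;
    syy += b * b;
  }
  if (sxx < kEps || syy < kEps) return 0.0;
  return sxy / std::sqrt(sxx * syy);
}

// Best lag in [-max_lag, max_lag]; ties resolved to smallest |lag|,
// then to the negative lag, by visiting lags in the order
// 0, -1, +1, -2, +2, ... and keeping strict improvements only.
void best_alignment(const double* x, const double* ref, int n, int max_lag,
                    int& lag_out, double& ncc_out) {
  double best = -2.0;
  int best_lag = 0;
  for (int a = 0; a <= max_lag; ++a) {
    for (int s = 0; s < (a == 0 ? 1 : 2); ++s) {
      int lag = (s == 0) ? -a : a;
      double v = ncc_at_lag(x, ref, n, lag);
      // strict improvement beyond float noise, so exact ties keep the
      // earlier-visited (smaller |lag|, negative-first) candidate
      if (v > best + 1e-12) {
        best = v;
        best_lag = lag;
      }
    }
  }
  lag_out = best_lag;
  ncc_out = best;
}

double median_inplace(std::vector<double>& v) {
  if (v.empty()) return NA_REAL;
  size_t k = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  double hi = v[k];
  if (v.size() % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + k - 1, v.begin() + k);
  return 0.5 * (hi + v[k - 1]);
}

struct TemplateResult {
  std::vector<double> mean_wave;
  std::vector<double> sd_wave;
  double median_sd;
  int n_used;
};

// beats: column-major (len x k). Builds the outlier-pruned aligned
// template. Shifted-out samples are filled with the reference value so
// at most max_lag edge samples per beat are affected.
TemplateResult build_template_core(const std::vector<double>& beats, int len,
                                   int k, double ncc_min, int max_lag) {
  if (k < 2) stop("build_template: need at least 2 beats");
  // provisional reference: element-wise median
  std::vector<double> ref(len);
  std::vector<double> buf(k);
  for (int i = 0; i < len; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = beats[j * len + i];
    std::vector<double> tmp(buf);
    ref[i] = median_inplace(tmp);
  }
  std::vector<int> lags(k);
  std::vector<double> nccs(k);
  for (int j = 0; j < k; ++j) {
    best_alignment(&beats[j * len], ref.data(), len, max_lag, lags[j], nccs[j]);
  }
  std::vector<int> keep;
  for (int j = 0; j < k; ++j) {
    if (nccs[j] >= ncc_min) keep.push_back(j);
  }
  if ((int)keep.size() < 2) {
    // floor rule: keep the two highest-NCC beats
    std::vector<int> order(k);
    for (int j = 0; j < k; ++j) order[j] = j;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return nccs[a] > nccs[b]; });
    keep.assign(order.begin(), order.begin() + 2);
    std::sort(keep.begin(), keep.end());
  }
  int nu = (int)keep.size();
  // aligned beat value at position i is x[i + lag] (undoes the lag)
  std::vector<double> mean(len, 0.0), m2(len, 0.0);
  std::vector<double> aligned(len);
  int cnt = 0;
  for (int j : keep) {
    const double* x = &beats[j * len];
    for (int i = 0; i < len; ++i) {
      int src = i + lags[j];
      aligned[i] = (src >= 0 && src < len) ? x[src] : ref[i];
    }
    ++cnt;
    for (int i = 0; i < len; ++i) {  // Welford update
      double d = aligned[i] - mean[i];
      mean[i] += d / cnt;
      m2[i] += d * (aligned[i] - mean[i]);
    }
  }
  std::vector<double> sdv(len);
  for (int i = 0; i < len; ++i) sdv[i] = std::sqrt(m2[i] / (nu - 1));
  std::vector<double> sdcopy(sdv);
  return TemplateResult{std::move(mean), std::move(sdv),
                        median_inplace(sdcopy), nu};
}

}  // namespace

// [[Rcpp::export(name = ".align_lag_cpp")]]
List align_lag_cpp(NumericVector x, NumericVector ref, int max_lag) {
  if (x.size() != ref.size()) stop("align_lag: length mismatch");
  int lag;
  double ncc;
  best_alignment(REAL(x), REAL(ref), x.size(), max_lag, lag, ncc);
  if (ncc <= -2.0 + 1e-9) {
    lag = 0;
    ncc = 0.0;
  }
  return List::create(_["lag"] = lag, _["ncc"] = ncc);
}

// [[Rcpp::export(name = ".build_template_cpp")]]
List build_template_cpp(NumericMatrix beats, double ncc_min, int max_lag) {
  int len = beats.nrow(), k = beats.ncol();
  std::vector<double> data(beats.begin(), beats.end());
  TemplateResult tr = build_template_core(data, len, k, ncc_min, max_lag);
  return List::create(
      _["mean_wave"] = NumericVector(tr.mean_wave.begin(), tr.mean_wave.end()),
      _["per_sample_sd"] = NumericVector(tr.sd_wave.begin(), tr.sd_wave.end()),
      _["median_sd"] = tr.median_sd, _["n_used"] = tr.n_used);
}

// Morphology features for one signal version.
//
// sig: n_samples x n_leads (>= 2 leads, first two used)
// r: 0-based R-peak samples of ALL beats (template context)
// eval: 0-based indices into r of the beats to evaluate
// seg_lo/seg_hi: 0-based-inclusive sample offsets per segment (length 4)
// nb: neighborhood sizes (e.g. 80, 20, 4)
//
// Output: length(eval) x (4 seg x |nb| x 2 leads x 3 stats), stats
// ordered (xcorr, lag, medsd), column-major over (stat, lead, nb, seg)
// fastest-to-slowest matching the R-side canonical names.
// [[Rcpp::export(name = ".morph_features_cpp")]]
NumericMatrix morph_features_cpp(NumericMatrix sig, IntegerVector r,
                                 IntegerVector eval, IntegerVector seg_lo,
                                 IntegerVector seg_hi, IntegerVector nb,
                                 int max_lag, double ncc_min) {
  const int ns = sig.nrow();
  const int nseg = seg_lo.size();
  const int nnb = nb.size();
  const int nleads = 2;
  if (sig.ncol() < nleads) stop("morphology requires 2 leads");
  const int nbeats = r.size();
  const int ncols = nseg * nnb * nleads * 3;
  NumericMatrix out(eval.size(), ncols);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int e = 0; e < eval.size(); ++e) {
    int b = eval[e];
    for (int s = 0; s < nseg; ++s) {
      int lo = seg_lo[s], hi = seg_hi[s];
      int len = hi - lo + 1;
      if (r[b] + lo < 0 || r[b] + hi >= ns) {
        stop("segment window out of record for evaluated beat %d", b);
      }
      for (int L = 0; L < nleads; ++L) {
        const double* lead = &sig(0, L);
        std::vector<double> beat_seg(len);
        for (int i = 0; i < len; ++i) beat_seg[i] = lead[r[b] + lo + i];
        for (int w = 0; w < nnb; ++w) {
          int half = nb[w] / 2;
          std::vector<double> neigh;
          neigh.reserve((size_t)len * nb[w]);
          int used = 0;
          for (int j = b - half; j <= b + half; ++j) {
            if (j == b || j < 0 || j >= nbeats) continue;
            if (r[j] + lo < 0 || r[j] + hi >= ns) continue;  // edge neighbor
            for (int i = 0; i < len; ++i) neigh.push_back(lead[r[j] + lo + i]);
            ++used;
          }
          if (used < 2) stop("fewer than 2 usable neighbor beats");
          TemplateResult tr =
              build_template_core(neigh, len, used, ncc_min, max_lag);
          int lag;
          double ncc;
          best_alignment(beat_seg.data(), tr.mean_wave.data(), len, max_lag,
                         lag, ncc);
          int col = ((s * nnb + w) * nleads + L) * 3;
          out(e, col + 0) = ncc;
          out(e, col + 1) = lag;
          out(e, col + 2) = tr.median_sd;
        }
      }
    }
  }
  return out;
}
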