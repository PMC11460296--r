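// Geometry kernels: separable cubic B-spline resampling (causal/anticausal
// prefilter so the spline interpolates the samples), nearest-neighbour
// resampling for label masks, and 6-connected component labelling.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using Rcpp::NumericVector;
using Rcpp::IntegerVector;

static const double POLE = -0.26794919243112270647;  // sqrt(3) - 2

// In-place interpolating-spline prefilter for one line (mirror boundaries).
static void prefilter_line(std::vector<double>& c) {
  const int n = (int)c.size();
  if (n == 1) return;
  const double z = POLE;
  const double gain = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) c[i] *= gain;
  // causal init under mirror boundaries: truncated geometric sum for long
  // lines, exact closed form for short ones
  const int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  double sum;
  if (horizon < n) {
    sum = c[0];
    double zk = z;
    for (int k = 1; k < horizon; ++k) { sum += zk * c[k]; zk *= z; }
  } else {
    const double z_n1 = std::pow(z, n - 1);
    sum = c[0] + z_n1 * c[n - 1];
    double zk = z, z2 = z_n1 * z_n1 / z;
    for (int k = 1; k < n - 1; ++k) {
      sum += (zk + z2) * c[k];
      zk *= z; z2 /= z;
    }
    sum /= (1.0 - z_n1 * z_n1);
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
  // anticausal init
  c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
  for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
}

static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Evaluate the cubic spline with coefficients c at continuous position t.
static double eval_spline(const std::vector<double>& c, double t) {
  const int n = (int)c.size();
  const int i = (int)std::floor(t);
  const double u = t - i;
  const double u2 = u * u, u3 = u2 * u;
  const double w0 = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  const double w1 = (4 - 6 * u2 + 3 * u3) / 6.0;
  const double w2 = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  const double w3 = u3 / 6.0;
  return w0 * c[mirror(i - 1, n)] + w1 * c[mirror(i, n)] +
         w2 * c[mirror(i + 1, n)] + w3 * c[mirror(i + 2, n)];
}

// Resample a 3D array along one axis with a cubic interpolating B-spline.
// vol is column-major with dims (d1, d2, d3); positions are continuous input
// indices for each output index along `axis` (0-based).
// [[Rcpp::export(name = ".resample_axis_bspline")]]
NumericVector resample_axis_bspline(NumericVector vol, IntegerVector dims,
                                    int axis, NumericVector positions) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int m = positions.size();
  int od[3] = { d1, d2, d3 };
  od[axis] = m;
  NumericVector out((R_xlen_t)od[0] * od[1] * od[2]);
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  const int n = dims[axis];
  // strides (column-major)
  const long s[3] = { 1, (long)d1, (long)d1 * d2 };
  const long so[3] = { 1, (long)od[0], (long)od[0] * od[1] };
  const int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  std::vector<double> line(n);
  for (int b = 0; b < dims[ob]; ++b)
    for (int a = 0; a < dims[oa]; ++a) {
      const long base = (long)a * s[oa] + (long)b * s[ob];
      for (int i = 0; i < n; ++i) line[i] = vol[base + (long)i * s[axis]];
      prefilter_line(line);
      const long obase = (long)a * so[oa] + (long)b * so[ob];
      for (int j = 0; j < m; ++j)
        out[obase + (long)j * so[axis]] = eval_spline(line, positions[j]);
    }
  return out;
}

// Nearest-neighbour resampling of a 3D array onto a new grid; pos* give the
// continuous input index for each output index along each axis.
// [[Rcpp::export(name = ".resample_nearest")]]
NumericVector resample_nearest(NumericVector vol, IntegerVector dims,
                               NumericVector pos1, NumericVector pos2,
                               NumericVector pos3) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int m1 = pos1.size(), m2 = pos2.size(), m3 = pos3.size();
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  std::vector<int> i1(m1), i2(m2), i3(m3);
  auto clampi = [](double p, int n) {
    int i = (int)std::lround(p);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  };
  for (int j = 0; j < m1; ++j) i1[j] = clampi(pos1[j], d1);
  for (int j = 0; j < m2; ++j) i2[j] = clampi(pos2[j], d2);
  for (int j = 0; j < m3; ++j) i3[j] = clampi(pos3[j], d3);
  long r = 0;
  for (int k = 0; k < m3; ++k)
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i, ++r)
        out[r] = vol[(long)i1[i] + (long)d1 * (i2[j] + (long)d2 * i3[k])];
  return out;
}

// 6-connected component labelling of a binary 3D array.
// Returns integer labels (0 = background, components numbered from 1 in
// decreasing size order).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const long n = (long)d1 * d2 * d3;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<long> stack;
  std::vector<long> sizes;  // per label
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    long sz = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      ++sz;
      const int i = (int)(v % d1), j = (int)((v / d1) % d2), k = (int)(v / ((long)d1 * d2));
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int q = 0; q < 6; ++q) {
        const int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
        const long w = (long)ii + (long)d1 * (jj + (long)d2 * kk);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> newlab(next + 1, 0);
  for (int r = 0; r < next; ++r) newlab[order[r] + 1] = r + 1;
  for (long s = 0; s < n; ++s) if (lab[s]) lab[s] = newlab[lab[s]];
  return lab;
}
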