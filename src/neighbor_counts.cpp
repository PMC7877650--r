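#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Per-point neighbor counts within each of a set of closed-ball radii.
// Uniform-grid cell index: cell edge >= max radius, so scanning the 3x3
// neighborhood of a point's cell covers every candidate neighbor.
// The center point itself is excluded ("other points" convention).
// [[Rcpp::export]]
IntegerMatrix cpp_radius_counts(NumericVector x, NumericVector y,
                                NumericVector radii) {
  const int n = x.size();
  const int d = radii.size();
  std::vector<double> r2(d);
  for (int k = 0; k < d; ++k) r2[k] = radii[k] * radii[k];
  const double rmax = radii[d - 1];
  const double rmax2 = r2[d - 1];

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  // cell edge ~ rmax/8 keeps the scanned block tight around the largest
  // ball; capped at ~1024 cells per side for tiny radii
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = std::max(rmax / 8.0, span / 1024.0);
  if (cell <= 0) cell = 1.0;
  int nx = (int)std::floor((xmax - xmin) / cell) + 1;
  int ny = (int)std::floor((ymax - ymin) / cell) + 1;
  int scan = (int)std::ceil(rmax / cell);

  // counting-sort points into cells
  std::vector<int> cid(n);
  std::vector<int> start((size_t)nx * ny + 1, 0);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((x[i] - xmin) / cell);
    int iy = (int)std::floor((y[i] - ymin) / cell);
    if (ix >= nx) ix = nx - 1;
    if (iy >= ny) iy = ny - 1;
    cid[i] = ix * ny + iy;
    ++start[cid[i] + 1];
  }
  for (size_t c = 1; c < start.size(); ++c) start[c] += start[c - 1];
  std::vector<int> order(n);
  {
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cid[i]]++] = i;
  }

  IntegerMatrix out(n, d);
  std::vector<int> hist(d);
  for (int i = 0; i < n; ++i) {
    std::fill(hist.begin(), hist.end(), 0);
    int ix = cid[i] / ny, iy = cid[i] % ny;
    for (int jx = std::max(0, ix - scan); jx <= std::min(nx - 1, ix + scan); ++jx) {
      // prune rows of cells whose nearest edge exceeds rmax
      double dxc = (jx < ix) ? (ix - jx - 1) * cell : (jx > ix) ? (jx - ix - 1) * cell : 0.0;
      if (dxc > rmax) continue;
      double ry = std::sqrt(rmax2 - dxc * dxc);
      int sy = (int)std::ceil(ry / cell) + 1;
      for (int jy = std::max(0, iy - sy); jy <= std::min(ny - 1, iy + sy); ++jy) {
        int c = jx * ny + jy;
        for (int p = start[c]; p < start[c + 1]; ++p) {
          int j = order[p];
          if (j == i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d2 = dx * dx + dy * dy;
          if (d2 <= rmax2) {
            int k = (int)(std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin());
            ++hist[k];
          }
        }
      }
    }
    int acc = 0;
    for (int k = 0; k < d; ++k) {
      acc += hist[k];
      out(i, k) = acc;
    }
  }
  return out;
}

// Online Kohonen SOM training. Codebook, grid positions (unit layout
// coordinates) and the full presentation order come from the caller so the
// run is reproducible from the R-side seed. Learning rate and neighborhood
// radius decay linearly over presentations. Returns the trained codebook and
// the mean quantization error (distance to BMU) measured after each epoch.
// [[Rcpp::export]]
List cpp_som_train(NumericMatrix data, NumericMatrix codebook0,
                   NumericMatrix gridpos, IntegerVector order,
                   int epochs, double alpha0, double alpha1,
                   double radius0, double radius1) {
  const int n = data.nrow(), p = data.ncol(), u = codebook0.nrow();
  NumericMatrix cb = clone(codebook0);
  const long total = (long)epochs * n;
  NumericVector qe(epochs);

  // pairwise squared grid distances between units
  std::vector<double> gd2((size_t)u * u);
  for (int a = 0; a < u; ++a)
    for (int b = 0; b < u; ++b) {
      double dx = gridpos(a, 0) - gridpos(b, 0);
      double dy = gridpos(a, 1) - gridpos(b, 1);
      gd2[(size_t)a * u + b] = dx * dx + dy * dy;
    }

  long t = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s, ++t) {
      int i = order[t];
      double frac = (total > 1) ? (double)t / (double)(total - 1) : 0.0;
      double alpha = alpha0 + (alpha1 - alpha0) * frac;
      double sigma = radius0 + (radius1 - radius0) * frac;
      // BMU
      int bmu = 0;
      double best = R_PosInf;
      for (int a = 0; a < u; ++a) {
        double d2 = 0;
        for (int q = 0; q < p; ++q) {
          double dd = data(i, q) - cb(a, q);
          d2 += dd * dd;
        }
        if (d2 < best) { best = d2; bmu = a; }
      }
      // adaptation with Gaussian neighborhood
      double inv = 1.0 / (2.0 * sigma * sigma);
      for (int a = 0; a < u; ++a) {
        double h = std::exp(-gd2[(size_t)bmu * u + a] * inv);
        if (h < 1e-4) continue;
        double ah = alpha * h;
        for (int q = 0; q < p; ++q)
          cb(a, q) += ah * (data(i, q) - cb(a, q));
      }
    }
    // quantization error after this epoch
    double tot = 0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      for (int a = 0; a < u; ++a) {
        double d2 = 0;
        for (int q = 0; q < p; ++q) {
          double dd = data(i, q) - cb(a, q);
          d2 += dd * dd;
        }
        if (d2 < best) best = d2;
      }
      tot += std::sqrt(best);
    }
    qe[e] = tot / n;
  }
  return List::create(_["codebook"] = cb, _["qe"] = qe);
}
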