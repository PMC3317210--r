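#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation under a mask,
// 8-connectivity, hybrid raster-scan + FIFO propagation (Vincent-style).
// Returns the stable reconstruction: the largest image <= mask obtainable
// by repeated geodesic dilation of the marker.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(nr, nc);
  for (int i = 0; i < nr * nc; ++i) J[i] = std::min(marker[i], mask[i]);

  // scan order is column-major (R storage order); N+ are already-visited
  // neighbours, N- the mirror set
  const int drp[4] = {-1, 0, 1, -1}, dcp[4] = {-1, -1, -1, 0};
  const int drm[4] = { 1, 0, -1,  1}, dcm[4] = { 1,  1,  1, 0};

  // forward pass
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drp[k], cc = c + dcp[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > m)
          m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  // backward pass, queue pixels that can still propagate
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > m)
          m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  }
  const int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        fifo.push(rr + cc * nr);
      }
    }
  }
  return J;
}

// 3D connected-component labeling of a logical volume (dims = rows, cols,
// slices), connectivity 26 or 6. Labels are assigned in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  const R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 26 && connectivity != 6) stop("connectivity must be 6 or 26");

  std::vector<int> dr, dc, ds;
  if (connectivity == 26) {
    for (int z = -1; z <= 1; ++z)
      for (int c = -1; c <= 1; ++c)
        for (int r = -1; r <= 1; ++r)
          if (r || c || z) { dr.push_back(r); dc.push_back(c); ds.push_back(z); }
  } else {
    int ar[6] = {-1, 1, 0, 0, 0, 0}, ac[6] = {0, 0, -1, 1, 0, 0}, as[6] = {0, 0, 0, 0, -1, 1};
    dr.assign(ar, ar + 6); dc.assign(ac, ac + 6); ds.assign(as, as + 6);
  }
  const int nn = (int)dr.size();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t plane = (R_xlen_t)nr * nc;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int r = (int)(p % nr), c = (int)((p / nr) % nc), s = (int)(p / plane);
      for (int k = 0; k < nn; ++k) {
        int rr = r + dr[k], cc = c + dc[k], ss = s + ds[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || ss < 0 || ss >= ns) continue;
        R_xlen_t q = rr + (R_xlen_t)cc * nr + (R_xlen_t)ss * plane;
        if (mask[q] && labels[q] == 0) { labels[q] = next; stack.push_back(q); }
      }
    }
  }
  return labels;
}

static inline double Phi(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

// Render a superposition of pixel-integrated 2D Gaussian cells into a patch.
// par holds (x, y, zc) per cell in 1-based patch coordinates (x = column,
// y = row); zc is the continuous axial position in [1, ns]: the cell's home
// slice is floor(zc) and the fractional part is the split fraction
// apportioned to the next slice (a sectioned cell).
static void render_mixture(const double* par, int ncell, double* model,
                           int nr, int nc, int ns,
                           double It, double sigma,
                           std::vector<double>& roww, std::vector<double>& colw) {
  const R_xlen_t plane = (R_xlen_t)nr * nc;
  for (int j = 0; j < ncell; ++j) {
    double x = par[3 * j], y = par[3 * j + 1], zc = par[3 * j + 2];
    if (zc < 1) zc = 1;
    if (zc > ns) zc = ns;
    int h = (int)std::floor(zc) - 1;
    if (h > ns - 1) h = ns - 1;
    double z = zc - 1 - h;
    double wh = 1.0 - z, wn = z;
    if (h + 1 >= ns) { wh = 1.0; wn = 0.0; }
    for (int r = 0; r < nr; ++r)
      roww[r] = Phi((r + 1.5 - y) / sigma) - Phi((r + 0.5 - y) / sigma);
    for (int c = 0; c < nc; ++c)
      colw[c] = Phi((c + 1.5 - x) / sigma) - Phi((c + 0.5 - x) / sigma);
    for (int c = 0; c < nc; ++c) {
      double base = It * colw[c];
      for (int r = 0; r < nr; ++r) {
        double v = base * roww[r];
        model[r + (R_xlen_t)c * nr + (R_xlen_t)h * plane] += wh * v;
        if (wn > 0) model[r + (R_xlen_t)c * nr + (R_xlen_t)(h + 1) * plane] += wn * v;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_render_mixture(NumericVector par, IntegerVector dims,
                                 double It, double sigma) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  const int ncell = par.size() / 3;
  NumericVector model((R_xlen_t)nr * nc * ns);
  std::vector<double> roww(nr), colw(nc);
  render_mixture(REAL(par), ncell, REAL(model), nr, nc, ns,
                 It, sigma, roww, colw);
  return model;
}

// Least-squares objective for n fixed-shape, fixed-intensity model cells:
// sum over patch voxels of (patch - model)^2, plus smooth quadratic
// penalties keeping the axial position zc inside [1, ns], the center
// inside the patch domain (an excess cell must not park its fixed
// intensity outside the objective's support), and near-coplanar cell
// centers at least dmin apart in-plane.
// [[Rcpp::export]]
double cpp_mix_obj(NumericVector par, NumericVector patch, IntegerVector dims,
                   double It, double sigma, double dmin, double lambda) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  const int ncell = par.size() / 3;
  const R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (patch.size() != n) stop("patch length does not match dims");
  std::vector<double> model(n, 0.0), roww(nr), colw(nc);
  render_mixture(REAL(par), ncell, model.data(), nr, nc, ns,
                 It, sigma, roww, colw);
  double sse = 0.0;
  const double* px = REAL(patch);
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = px[i] - model[i];
    sse += d * d;
  }
  double pen = 0.0;
  for (int j = 0; j < ncell; ++j) {
    double x = par[3 * j], y = par[3 * j + 1], zr = par[3 * j + 2];
    double zc = zr < 1 ? 1 : (zr > ns ? ns : zr);
    pen += lambda * (zr - zc) * (zr - zc);
    double dx = x < 0.5 ? 0.5 - x : (x > nc + 0.5 ? x - nc - 0.5 : 0.0);
    double dy = y < 0.5 ? 0.5 - y : (y > nr + 0.5 ? y - nr - 0.5 : 0.0);
    pen += lambda * (dx * dx + dy * dy);
  }
  for (int j = 0; j < ncell; ++j) {
    for (int k = j + 1; k < ncell; ++k) {
      double dz = std::fabs(par[3 * j + 2] - par[3 * k + 2]);
      if (dz >= 1) continue;  // sections are thick: different slices never overlap
      double dx = par[3 * j] - par[3 * k], dy = par[3 * j + 1] - par[3 * k + 1];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < dmin) pen += lambda * (1 - dz) * (dmin - d) * (dmin - d);
    }
  }
  return sse + pen;
}
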