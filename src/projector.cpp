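#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grid convention shared with the R side: square n x n label map,
// pixel size px (mm), image center at the rotation isocenter, row
// index increasing downward.  Internally we work in (x, v) coordinates
// with v = -y so that both indices increase with the coordinate.
//
// Fan-beam geometry: for view angle beta the source sits at
// (-sad*sin(beta), sad*cos(beta)) and the flat detector line passes
// through (+(sdd-sad)*sin(beta), -(sdd-sad)*cos(beta)) with in-plane
// axis (cos(beta), sin(beta)); u is the signed detector coordinate.

struct Ray {
  double sx, sv, dx, dv; // source and detector point, (x, v) mm
};

static inline Ray make_ray(double beta, double u, double sad, double sdd) {
  double sb = std::sin(beta), cb = std::cos(beta);
  Ray r;
  r.sx = -sad * sb;
  r.sv = -(sad * cb);
  double ddist = sdd - sad;
  double px_ = ddist * sb + u * cb;
  double py_ = -ddist * cb + u * sb;
  r.dx = px_;
  r.dv = -py_;
  return r;
}

// Amanatides-Woo traversal of the pixel grid; calls f(row, col, len_mm)
template <typename F>
static void traverse(const Ray& r, int n, double px, F f) {
  double x0 = -0.5 * n * px; // grid min in both x and v
  double ex = r.dx - r.sx, ev = r.dv - r.sv;
  double L = std::sqrt(ex * ex + ev * ev);
  if (L <= 0) return;
  ex /= L; ev /= L;
  // clip parametric range to the bounding box
  double tmin = 0.0, tmax = L;
  for (int axis = 0; axis < 2; ++axis) {
    double s = axis ? r.sv : r.sx;
    double d = axis ? ev : ex;
    if (std::fabs(d) < 1e-12) {
      if (s <= x0 || s >= x0 + n * px) return;
    } else {
      double t1 = (x0 - s) / d, t2 = (x0 + n * px - s) / d;
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
    }
  }
  if (tmin >= tmax) return;
  double t = tmin + 1e-9;
  double cx = r.sx + t * ex, cv = r.sv + t * ev;
  int ix = (int)std::floor((cx - x0) / px);
  int iv = (int)std::floor((cv - x0) / px);
  ix = std::min(std::max(ix, 0), n - 1);
  iv = std::min(std::max(iv, 0), n - 1);
  int stepx = ex > 0 ? 1 : -1, stepv = ev > 0 ? 1 : -1;
  double tdx = std::fabs(ex) > 1e-12 ? px / std::fabs(ex) : 1e30;
  double tdv = std::fabs(ev) > 1e-12 ? px / std::fabs(ev) : 1e30;
  double tmx, tmv;
  if (std::fabs(ex) > 1e-12) {
    double xb = x0 + (ix + (stepx > 0 ? 1 : 0)) * px;
    tmx = (xb - r.sx) / ex;
  } else tmx = 1e30;
  if (std::fabs(ev) > 1e-12) {
    double vb = x0 + (iv + (stepv > 0 ? 1 : 0)) * px;
    tmv = (vb - r.sv) / ev;
  } else tmv = 1e30;
  double tcur = tmin;
  while (tcur < tmax - 1e-9) {
    double tnext = std::min(std::min(tmx, tmv), tmax);
    double seg = tnext - tcur;
    if (seg > 0 && ix >= 0 && ix < n && iv >= 0 && iv < n)
      f(iv, ix, seg);
    if (tmx < tmv) { ix += stepx; tmx += tdx; }
    else           { iv += stepv; tmv += tdv; }
    tcur = tnext;
    if (ix < 0 || ix >= n || iv < 0 || iv >= n) break;
  }
}

// [[Rcpp::export]]
NumericVector cpp_trace_paths(IntegerMatrix labels, int n_mat, double px,
                              NumericVector angles, NumericVector det_u,
                              double sad, double sdd) {
  int n = labels.nrow();
  if (labels.ncol() != n) stop("label map must be square");
  int nv = angles.size(), nd = det_u.size();
  NumericVector out(nd * (R_xlen_t)nv * n_mat);
  for (int v = 0; v < nv; ++v) {
    for (int d = 0; d < nd; ++d) {
      Ray r = make_ray(angles[v], det_u[d], sad, sdd);
      double* base = &out[0];
      traverse(r, n, px, [&](int row, int col, double len) {
        int m = labels(row, col) - 1;
        base[d + (R_xlen_t)nd * v + (R_xlen_t)nd * nv * m] += len / 10.0; // cm
      });
    }
  }
  out.attr("dim") = IntegerVector::create(nd, nv, n_mat);
  return out;
}

// line integrals of an arbitrary image: sum(value * length), length in cm
// [[Rcpp::export]]
NumericMatrix cpp_forward_image(NumericMatrix img, double px,
                                NumericVector angles, NumericVector det_u,
                                double sad, double sdd) {
  int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  int nv = angles.size(), nd = det_u.size();
  NumericMatrix out(nd, nv);
  for (int v = 0; v < nv; ++v) {
    for (int d = 0; d < nd; ++d) {
      Ray r = make_ray(angles[v], det_u[d], sad, sdd);
      double acc = 0.0;
      traverse(r, n, px, [&](int row, int col, double len) {
        acc += img(row, col) * len / 10.0;
      });
      out(d, v) = acc;
    }
  }
  return out;
}

// distance-weighted fan-beam backprojection of filtered projections
// q: (n_det x n_views) sampled on the virtual detector at the
// isocenter, uniform coordinates u = u0 + (i-1)*du (mm)
// [[Rcpp::export]]
NumericMatrix cpp_backproject_fan(NumericMatrix q, NumericVector angles,
                                  double u0, double du, double sad,
                                  int out_n, double out_px) {
  int nd = q.nrow(), nv = angles.size();
  if (q.ncol() != nv) stop("projection/view mismatch");
  NumericMatrix img(out_n, out_n);
  std::vector<double> sb(nv), cb(nv);
  for (int v = 0; v < nv; ++v) { sb[v] = std::sin(angles[v]); cb[v] = std::cos(angles[v]); }
  double c0 = (out_n + 1) / 2.0;
  for (int i = 0; i < out_n; ++i) {       // row (y decreasing)
    double y = (c0 - (i + 1)) * out_px;
    for (int j = 0; j < out_n; ++j) {     // col (x increasing)
      double x = ((j + 1) - c0) * out_px;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        double xr = x * cb[v] + y * sb[v];
        double yr = -x * sb[v] + y * cb[v];
        double L = sad - yr;
        if (L <= 1e-6) continue;
        double u = xr * sad / L;
        double fi = (u - u0) / du;
        int i0 = (int)std::floor(fi);
        if (i0 < 0 || i0 >= nd - 1) continue;
        double w = fi - i0;
        double val = (1.0 - w) * q(i0, v) + w * q(i0 + 1, v);
        acc += val * sad * sad / (L * L);
      }
      img(i, j) = acc;
    }
  }
  return img;
}

// 4-connected component labeling of a logical mask
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + nr * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + nr * qj);
          }
        }
      }
    }
  }
  return lab;
}
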