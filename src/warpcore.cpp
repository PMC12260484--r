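// Low-level resampling and registration kernels.
//
// Conventions (shared with the R layer):
//  - arrays are stored in (x, y, z) axis order, column-major as R arrays;
//  - voxel (i, j, k), 0-based, has its *center* at origin + (i,j,k) * spacing (mm);
//  - all physical coordinates and displacements are millimetres.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Snap tolerance (in continuous voxel index units) under which a sample point
// is treated as lying exactly on a voxel center, so that identity resampling
// is bit-exact.
static const double SNAP_EPS = 1e-9;

// Trilinear sample at continuous voxel index (ix, iy, iz).
// If grad != NULL it receives the intensity gradient in *index* units.
// Outside [0, n-1] on any axis returns `bg` with zero gradient.
static inline double sample_index(const double *d, const int nx, const int ny,
                                  const int nz, double ix, double iy, double iz,
                                  const double bg, double *grad) {
  if (grad) grad[0] = grad[1] = grad[2] = 0.0;
  if (ix < -SNAP_EPS || iy < -SNAP_EPS || iz < -SNAP_EPS ||
      ix > nx - 1 + SNAP_EPS || iy > ny - 1 + SNAP_EPS ||
      iz > nz - 1 + SNAP_EPS)
    return bg;
  // clamp the sub-eps overshoot
  if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
  if (ix > nx - 1) ix = nx - 1;
  if (iy > ny - 1) iy = ny - 1;
  if (iz > nz - 1) iz = nz - 1;

  int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy), z0 = (int)std::floor(iz);
  double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  int x1, y1, z1;
  if (!grad) {
    // snap to exact centers for bit-exact identity warps
    if (fx < SNAP_EPS) fx = 0.0; else if (fx > 1.0 - SNAP_EPS) { fx = 0.0; x0++; }
    if (fy < SNAP_EPS) fy = 0.0; else if (fy > 1.0 - SNAP_EPS) { fy = 0.0; y0++; }
    if (fz < SNAP_EPS) fz = 0.0; else if (fz > 1.0 - SNAP_EPS) { fz = 0.0; z0++; }
    x1 = (fx > 0.0) ? x0 + 1 : x0;
    y1 = (fy > 0.0) ? y0 + 1 : y0;
    z1 = (fz > 0.0) ? z0 + 1 : z0;
  } else {
    // gradient path: keep the full 8-voxel support so the derivative does
    // not vanish when a sample lands exactly on a voxel center
    if (x0 > nx - 2) x0 = nx - 2;
    if (y0 > ny - 2) y0 = ny - 2;
    if (z0 > nz - 2) z0 = nz - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    fx = ix - x0; fy = iy - y0; fz = iz - z0;
    x1 = (nx > 1) ? x0 + 1 : x0;
    y1 = (ny > 1) ? y0 + 1 : y0;
    z1 = (nz > 1) ? z0 + 1 : z0;
  }

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  #define VOX(i, j, k) d[(i) * sx + (j) * sy + (k) * sz]
  const double c000 = VOX(x0, y0, z0), c100 = VOX(x1, y0, z0);
  const double c010 = VOX(x0, y1, z0), c110 = VOX(x1, y1, z0);
  const double c001 = VOX(x0, y0, z1), c101 = VOX(x1, y0, z1);
  const double c011 = VOX(x0, y1, z1), c111 = VOX(x1, y1, z1);
  #undef VOX

  const double c00 = c000 + (c100 - c000) * fx;
  const double c10 = c010 + (c110 - c010) * fx;
  const double c01 = c001 + (c101 - c001) * fx;
  const double c11 = c011 + (c111 - c011) * fx;
  const double c0 = c00 + (c10 - c00) * fy;
  const double c1 = c01 + (c11 - c01) * fy;
  if (grad) {
    // d/dfx
    const double g00 = c100 - c000, g10 = c110 - c010;
    const double g01 = c101 - c001, g11 = c111 - c011;
    const double gx0 = g00 + (g10 - g00) * fy, gx1 = g01 + (g11 - g01) * fy;
    grad[0] = gx0 + (gx1 - gx0) * fz;
    grad[1] = (c10 - c00) + ((c11 - c01) - (c10 - c00)) * fz;
    grad[2] = c1 - c0;
  }
  return c0 + (c1 - c0) * fz;
}

// Sample a volume at arbitrary physical points (mm). pts is n x 3.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector data, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *d = REAL(data);
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double ix = (pts(i, 0) - origin[0]) / spacing[0];
    const double iy = (pts(i, 1) - origin[1]) / spacing[1];
    const double iz = (pts(i, 2) - origin[2]) / spacing[2];
    out[i] = sample_index(d, nx, ny, nz, ix, iy, iz, background, NULL);
  }
  return out;
}

// Pull-warp: out(p) = src(p + disp(p)) evaluated on the output grid.
// dispx/y/z have either length prod(odim) or length 1 (uniform shift).
// [[Rcpp::export]]
NumericVector cpp_warp_pull(NumericVector src, IntegerVector sdim,
                            NumericVector sspacing, NumericVector sorigin,
                            IntegerVector odim, NumericVector ospacing,
                            NumericVector oorigin, NumericVector dispx,
                            NumericVector dispy, NumericVector dispz,
                            double background) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  const double *d = REAL(src);
  const bool ux = dispx.size() == 1, uy = dispy.size() == 1, uz = dispz.size() == 1;
  NumericVector out((R_xlen_t)ox * oy * oz);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    const double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      const double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        const double px = oorigin[0] + i * ospacing[0];
        const double qx = px + (ux ? dispx[0] : dispx[idx]);
        const double qy = py + (uy ? dispy[0] : dispy[idx]);
        const double qz = pz + (uz ? dispz[0] : dispz[idx]);
        out[idx] = sample_index(d, nx, ny, nz,
                                (qx - sorigin[0]) / sspacing[0],
                                (qy - sorigin[1]) / sspacing[1],
                                (qz - sorigin[2]) / sspacing[2],
                                background, NULL);
      }
    }
  }
  return out;
}

// Separable Gaussian blur, sigma in voxels, reflecting boundaries.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dim,
                                double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double ks = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + radius];
  }
  for (double &v : k) v /= ks;
  NumericVector cur = clone(data);
  NumericVector nxt(data.size());
  const int n[3] = {nx, ny, nz};
  const R_xlen_t strd[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int na = n[ax];
    if (na < 2) continue;
    const R_xlen_t sa = strd[ax];
    const double *src = REAL(cur);
    double *dst = REAL(nxt);
    const R_xlen_t total = (R_xlen_t)nx * ny * nz;
    for (R_xlen_t idx = 0; idx < total; ++idx) {
      const int a = (int)((idx / sa) % na);
      double acc = 0.0;
      for (int o = -radius; o <= radius; ++o) {
        int aa = a + o;
        if (aa < 0) aa = -aa;               // reflect
        if (aa > na - 1) aa = 2 * (na - 1) - aa;
        acc += k[o + radius] * src[idx + (R_xlen_t)(aa - a) * sa];
      }
      dst[idx] = acc;
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Cubic B-spline basis (uniform), t in [0,1).
static inline void bspline_w(const double t, double *w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
  w[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
  w[3] = t3 / 6.0;
}

struct FFDGrid {
  const double *coef;  // ncx*ncy*ncz*3
  int ncx, ncy, ncz;
  double ox, oy, oz;   // physical position of control point (0,0,0)
  double sx, sy, sz;   // control spacing, mm
};

// Evaluate the FFD displacement (mm) at physical point p, optionally storing
// the support indices/weights for the gradient pass. Returns false if the
// point's 4x4x4 support is not fully inside the control lattice.
static inline bool ffd_eval(const FFDGrid &g, const double px, const double py,
                            const double pz, double *disp, int *i0,
                            double *wx, double *wy, double *wz) {
  const double ux = (px - g.ox) / g.sx;
  const double uy = (py - g.oy) / g.sy;
  const double uz = (pz - g.oz) / g.sz;
  const int ix = (int)std::floor(ux), iy = (int)std::floor(uy), iz = (int)std::floor(uz);
  if (ix - 1 < 0 || iy - 1 < 0 || iz - 1 < 0 || ix + 2 >= g.ncx ||
      iy + 2 >= g.ncy || iz + 2 >= g.ncz)
    return false;
  bspline_w(ux - ix, wx);
  bspline_w(uy - iy, wy);
  bspline_w(uz - iz, wz);
  i0[0] = ix - 1; i0[1] = iy - 1; i0[2] = iz - 1;
  const R_xlen_t plane = (R_xlen_t)g.ncx * g.ncy;
  const R_xlen_t comp = plane * g.ncz;
  disp[0] = disp[1] = disp[2] = 0.0;
  for (int c = 0; c < 4; ++c) {
    for (int b = 0; b < 4; ++b) {
      const double wyz = wy[b] * wz[c];
      R_xlen_t base = (R_xlen_t)(i0[0]) + (R_xlen_t)(i0[1] + b) * g.ncx +
                      (R_xlen_t)(i0[2] + c) * plane;
      for (int a = 0; a < 4; ++a) {
        const double w = wx[a] * wyz;
        const R_xlen_t ci = base + a;
        disp[0] += w * g.coef[ci];
        disp[1] += w * g.coef[ci + comp];
        disp[2] += w * g.coef[ci + 2 * comp];
      }
    }
  }
  return true;
}

// Dense evaluation of an FFD displacement field on an output grid.
// Returns a vector of length prod(odim)*3 (component-major like the coef).
// Points outside the lattice support get zero displacement.
// [[Rcpp::export]]
NumericVector cpp_ffd_field(NumericVector coef, IntegerVector cdim,
                            NumericVector corigin, NumericVector cspacing,
                            IntegerVector odim, NumericVector ospacing,
                            NumericVector oorigin) {
  FFDGrid g = {REAL(coef), cdim[0], cdim[1], cdim[2],
               corigin[0], corigin[1], corigin[2],
               cspacing[0], cspacing[1], cspacing[2]};
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  const R_xlen_t nvox = (R_xlen_t)ox * oy * oz;
  NumericVector out(nvox * 3);
  double disp[3], wx[4], wy[4], wz[4];
  int i0[3];
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    const double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      const double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        const double px = oorigin[0] + i * ospacing[0];
        if (ffd_eval(g, px, py, pz, disp, i0, wx, wy, wz)) {
          out[idx] = disp[0];
          out[idx + nvox] = disp[1];
          out[idx + 2 * nvox] = disp[2];
        }
      }
    }
  }
  return out;
}

// Objective + analytic gradient for FFD registration.
// Warped moving W(p) = M(p + u(p)) compared with fixed F(p) over the fixed
// grid (sub-sampled by `stride`). metric: 0 = SSD (mean squared difference),
// 1 = 1 - r^2 (squared global Pearson correlation; handles inverted contrast).
// A discrete bending penalty (mean squared second difference of the control
// lattice, per mm^2 of control spacing) times `bendweight` is added.
// [[Rcpp::export]]
List cpp_ffd_loss(NumericVector fixedv, IntegerVector fdim,
                  NumericVector fspacing, NumericVector forigin,
                  NumericVector mov, IntegerVector mdim,
                  NumericVector mspacing, NumericVector morigin,
                  NumericVector coef, IntegerVector cdim,
                  NumericVector corigin, NumericVector cspacing,
                  int metric, double bendweight, int stride,
                  double background, LogicalVector maskv) {
  FFDGrid g = {REAL(coef), cdim[0], cdim[1], cdim[2],
               corigin[0], corigin[1], corigin[2],
               cspacing[0], cspacing[1], cspacing[2]};
  const int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const double *F = REAL(fixedv);
  const double *M = REAL(mov);
  const int *MK = (maskv.size() > 0) ? LOGICAL(maskv) : (const int *)0;
  if (stride < 1) stride = 1;

  std::vector<double> wv, fv, gxv, gyv, gzv;
  std::vector<double> pxv, pyv, pzv;
  const R_xlen_t approx = ((R_xlen_t)fx / stride + 1) *
                          ((R_xlen_t)fy / stride + 1) *
                          ((R_xlen_t)fz / stride + 1);
  wv.reserve(approx); fv.reserve(approx);
  gxv.reserve(approx); gyv.reserve(approx); gzv.reserve(approx);
  pxv.reserve(approx); pyv.reserve(approx); pzv.reserve(approx);

  double disp[3], wx[4], wy[4], wz[4], grad[3];
  int i0[3];
  for (int k = 0; k < fz; k += stride) {
    const double pz = forigin[2] + k * fspacing[2];
    for (int j = 0; j < fy; j += stride) {
      const double py = forigin[1] + j * fspacing[1];
      for (int i = 0; i < fx; i += stride) {
        if (MK && !MK[(R_xlen_t)i + (R_xlen_t)j * fx + (R_xlen_t)k * fx * fy])
          continue;
        const double px = forigin[0] + i * fspacing[0];
        if (!ffd_eval(g, px, py, pz, disp, i0, wx, wy, wz)) continue;
        const double qx = px + disp[0], qy = py + disp[1], qz = pz + disp[2];
        const double w = sample_index(M, mx, my, mz,
                                      (qx - morigin[0]) / mspacing[0],
                                      (qy - morigin[1]) / mspacing[1],
                                      (qz - morigin[2]) / mspacing[2],
                                      background, grad);
        wv.push_back(w);
        fv.push_back(F[(R_xlen_t)i + (R_xlen_t)j * fx + (R_xlen_t)k * fx * fy]);
        // gradient in mm^-1
        gxv.push_back(grad[0] / mspacing[0]);
        gyv.push_back(grad[1] / mspacing[1]);
        gzv.push_back(grad[2] / mspacing[2]);
        pxv.push_back(px); pyv.push_back(py); pzv.push_back(pz);
      }
    }
  }
  const R_xlen_t n = (R_xlen_t)wv.size();
  if (n < 8) stop("FFD support does not cover the fixed image");

  // metric value and dL/dw_k
  std::vector<double> dldw(n);
  double loss;
  if (metric == 0) {
    double s = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) {
      const double r = wv[t] - fv[t];
      s += r * r;
      dldw[t] = 2.0 * r / n;
    }
    loss = s / n;
  } else {
    double mw = 0.0, mf = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) { mw += wv[t]; mf += fv[t]; }
    mw /= n; mf /= n;
    double sww = 0.0, sff = 0.0, swf = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) {
      const double a = wv[t] - mw, b = fv[t] - mf;
      sww += a * a; sff += b * b; swf += a * b;
    }
    if (sww <= 0.0 || sff <= 0.0)
      stop("degenerate (constant) image in correlation metric");
    const double r = swf / std::sqrt(sww * sff);
    // loss = 1 - r: maximize *positive* correlation. The caller flips the
    // moving image's sign beforehand if the modalities are contrast-
    // inverted; a sign-blind (r^2) metric would accept the half-pitch
    // bright-on-bright alignment of periodic grid images.
    loss = 1.0 - r;
    // dr/dw_k = (b_k - r*sqrt(sff/sww)*a_k) / sqrt(sww*sff)
    const double den = std::sqrt(sww * sff);
    const double ratio = r * std::sqrt(sff / sww);
    for (R_xlen_t t = 0; t < n; ++t) {
      const double a = wv[t] - mw, b = fv[t] - mf;
      dldw[t] = -(b - ratio * a) / den;
    }
  }

  // back-propagate to control coefficients
  const R_xlen_t plane = (R_xlen_t)g.ncx * g.ncy;
  const R_xlen_t comp = plane * g.ncz;
  NumericVector gradc(coef.size());
  double *GC = REAL(gradc);
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!ffd_eval(g, pxv[t], pyv[t], pzv[t], disp, i0, wx, wy, wz)) continue;
    const double dldx = dldw[t] * gxv[t];
    const double dldy = dldw[t] * gyv[t];
    const double dldz = dldw[t] * gzv[t];
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        const double wyz = wy[b] * wz[c];
        R_xlen_t base = (R_xlen_t)(i0[0]) + (R_xlen_t)(i0[1] + b) * g.ncx +
                        (R_xlen_t)(i0[2] + c) * plane;
        for (int a = 0; a < 4; ++a) {
          const double w = wx[a] * wyz;
          const R_xlen_t ci = base + a;
          GC[ci] += w * dldx;
          GC[ci + comp] += w * dldy;
          GC[ci + 2 * comp] += w * dldz;
        }
      }
    }
  }

  // bending penalty: mean squared second difference of the control lattice
  // along each axis, per component, normalised by control spacing^2.
  double bend = 0.0;
  R_xlen_t nterms = 0;
  const double inv2[3] = {1.0 / (g.sx * g.sx), 1.0 / (g.sy * g.sy),
                          1.0 / (g.sz * g.sz)};
  const double *C = REAL(coef);
  std::vector<double> bgrad(coef.size(), 0.0);
  for (int comp_i = 0; comp_i < 3; ++comp_i) {
    const double *Cc = C + comp_i * comp;
    double *Bc = bgrad.data() + comp_i * comp;
    for (int k = 0; k < g.ncz; ++k) {
      for (int j = 0; j < g.ncy; ++j) {
        for (int i = 0; i < g.ncx; ++i) {
          const R_xlen_t ci = (R_xlen_t)i + (R_xlen_t)j * g.ncx + (R_xlen_t)k * plane;
          for (int ax = 0; ax < 3; ++ax) {
            if ((ax == 0 && (i < 1 || i >= g.ncx - 1)) ||
                (ax == 1 && (j < 1 || j >= g.ncy - 1)) ||
                (ax == 2 && (k < 1 || k >= g.ncz - 1)))
              continue;
            const R_xlen_t step = (ax == 0) ? 1
                                 : (ax == 1) ? (R_xlen_t)g.ncx : plane;
            const double d2 = (Cc[ci - step] - 2.0 * Cc[ci] + Cc[ci + step]) * inv2[ax];
            bend += d2 * d2;
            ++nterms;
            const double f = 2.0 * d2 * inv2[ax];
            Bc[ci - step] += f;
            Bc[ci] += -2.0 * f;
            Bc[ci + step] += f;
          }
        }
      }
    }
  }
  if (nterms > 0) {
    bend /= nterms;
    const double scale = bendweight / nterms;
    for (R_xlen_t t = 0; t < gradc.size(); ++t) GC[t] += scale * bgrad[t];
  }
  loss += bendweight * bend;

  return List::create(_["loss"] = loss, _["grad"] = gradc, _["n"] = n,
                      _["bend"] = bend, _["nterms"] = nterms);
}
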