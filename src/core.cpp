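#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- brute-force full cross-correlation (verification oracle) ----
// corr[t] = sum_v a[v] * b[v - t], t in [-(db-1), da-1] per dimension.
// Output array dims da + db - 1; index j maps to t = j - (db - 1) (0-based).
// [[Rcpp::export]]
NumericVector cpp_corr_full(NumericVector a, IntegerVector da,
                            NumericVector b, IntegerVector db) {
  const int ax = da[0], ay = da[1], az = da[2];
  const int bx = db[0], by = db[1], bz = db[2];
  const int ox = ax + bx - 1, oy = ay + by - 1, oz = az + bz - 1;
  NumericVector out(ox * (double)oy * oz);
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  const double *A = a.begin(), *B = b.begin();
  double *O = out.begin();
  for (int tz = -(bz - 1); tz < az; ++tz) {
    int z0 = std::max(0, tz), z1 = std::min(az - 1, tz + bz - 1);
    for (int ty = -(by - 1); ty < ay; ++ty) {
      int y0 = std::max(0, ty), y1 = std::min(ay - 1, ty + by - 1);
      for (int tx = -(bx - 1); tx < ax; ++tx) {
        int x0 = std::max(0, tx), x1 = std::min(ax - 1, tx + bx - 1);
        double s = 0.0;
        for (int z = z0; z <= z1; ++z)
          for (int y = y0; y <= y1; ++y) {
            const double *arow = A + (size_t)(z * ay + y) * ax;
            const double *brow = B + (size_t)((z - tz) * by + (y - ty)) * bx - tx;
            for (int x = x0; x <= x1; ++x) s += arow[x] * brow[x];
          }
        O[((size_t)(tz + bz - 1) * oy + (ty + by - 1)) * ox + (tx + bx - 1)] = s;
      }
    }
  }
  return out;
}

// ---- grid rasterization ----
// core: indicator, voxel center within (r - delta) of any atom
// surface: indicator, voxel center within (r + sigma) of an atom, minus core
// charge: trilinear spread of partial charges
// pair: trilinear unit spread into the channel of the atom's coarse type
// Voxel centers at origin + (i + 0.5) h; type index 1..ntypes, 0 = untyped.
// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix xyz, NumericVector radius, NumericVector charge,
                   IntegerVector type, NumericVector origin, double h,
                   IntegerVector dims, double delta, double sigma, int ntypes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector core(nvox), surf(nvox), chg(nvox), pair(nvox * ntypes);
  core.attr("dim") = dims; surf.attr("dim") = dims; chg.attr("dim") = dims;
  pair.attr("dim") = IntegerVector::create(nx, ny, nz, ntypes);
  const int n = xyz.nrow();
  for (int i = 0; i < n; ++i) {
    const double x = xyz(i, 0), y = xyz(i, 1), z = xyz(i, 2);
    const double rc = radius[i] - delta, rs = radius[i] + sigma;
    const double rc2 = rc > 0 ? rc * rc : -1.0, rs2 = rs * rs;
    // sphere rasterization over bounding box of the outer shell
    int ix0 = std::max(0, (int)std::floor((x - rs - origin[0]) / h - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((x + rs - origin[0]) / h - 0.5));
    int iy0 = std::max(0, (int)std::floor((y - rs - origin[1]) / h - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((y + rs - origin[1]) / h - 0.5));
    int iz0 = std::max(0, (int)std::floor((z - rs - origin[2]) / h - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((z + rs - origin[2]) / h - 0.5));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + (iz + 0.5) * h - z;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + (iy + 0.5) * h - y;
        double dyz2 = dy * dy + dz * dz;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + (ix + 0.5) * h - x;
          double d2 = dx * dx + dyz2;
          if (d2 > rs2) continue;
          size_t v = ((size_t)iz * ny + iy) * nx + ix;
          if (d2 <= rc2) core[v] = 1.0; else surf[v] = 1.0;
        }
      }
    }
    // trilinear spreading of charge and type density
    double u0 = (x - origin[0]) / h - 0.5;
    double u1 = (y - origin[1]) / h - 0.5;
    double u2 = (z - origin[2]) / h - 0.5;
    int i0 = (int)std::floor(u0), j0 = (int)std::floor(u1), k0 = (int)std::floor(u2);
    double fx = u0 - i0, fy = u1 - j0, fz = u2 - k0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          size_t v = ((size_t)kk * ny + jj) * nx + ii;
          chg[v] += w * charge[i];
          if (type[i] >= 1 && type[i] <= ntypes)
            pair[v + nvox * (size_t)(type[i] - 1)] += w;
        }
  }
  // a voxel claimed as core by any atom is not surface
  for (size_t v = 0; v < nvox; ++v) if (core[v] > 0) surf[v] = 0.0;
  return List::create(_["core"] = core, _["surface"] = surf,
                      _["charge"] = chg, _["pair"] = pair);
}

// ---- continuous inter-molecular energy: soft-core 12-6 + screened Coulomb ----
static inline double pair_e(double r2, double sig, double qq, double e0,
                            double soft2, double kap, double epsd) {
  double rho2 = r2 + soft2, rho = std::sqrt(rho2);
  double s2 = sig * sig / rho2, s6 = s2 * s2 * s2;
  double e = e0 * (s6 * s6 - 2.0 * s6);
  if (qq != 0.0)
    e += 332.0 * qq * std::exp(-kap * std::sqrt(r2)) / (epsd * rho);
  return e;
}

// [[Rcpp::export]]
double cpp_pair_energy(NumericMatrix xa, NumericVector qa, NumericVector ra,
                       NumericMatrix xb, NumericVector qb, NumericVector rb,
                       double e0, double soft, double kap, double epsd,
                       double cutoff) {
  const int na = xa.nrow(), nb = xb.nrow();
  const double soft2 = soft * soft, cut2 = cutoff * cutoff;
  double e = 0.0;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double dx = xa(i,0)-xb(j,0), dy = xa(i,1)-xb(j,1), dz = xa(i,2)-xb(j,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > cut2) continue;
      e += pair_e(r2, ra[i] + rb[j], qa[i] * qb[j], e0, soft2, kap, epsd);
    }
  return e;
}

// [[Rcpp::export]]
int cpp_clash_count(NumericMatrix xa, NumericVector ra,
                    NumericMatrix xb, NumericVector rb, double factor) {
  int n = 0;
  for (int i = 0; i < xa.nrow(); ++i)
    for (int j = 0; j < xb.nrow(); ++j) {
      double dx = xa(i,0)-xb(j,0), dy = xa(i,1)-xb(j,1), dz = xa(i,2)-xb(j,2);
      double lim = factor * (ra[i] + rb[j]);
      if (dx*dx + dy*dy + dz*dz < lim * lim) ++n;
    }
  return n;
}

// gradient of the pair energy with respect to ligand atom positions
static double energy_grad(const NumericMatrix &xr, const NumericVector &qr,
                          const NumericVector &rr, const std::vector<double> &xl,
                          const NumericVector &ql, const NumericVector &rl,
                          double e0, double soft2, double kap, double epsd,
                          double cut2, std::vector<double> &g) {
  const int nr = xr.nrow(), nl = (int)ql.size();
  double e = 0.0;
  std::fill(g.begin(), g.end(), 0.0);
  for (int j = 0; j < nl; ++j) {
    double gx = 0, gy = 0, gz = 0;
    for (int i = 0; i < nr; ++i) {
      double dx = xl[3*j] - xr(i,0), dy = xl[3*j+1] - xr(i,1), dz = xl[3*j+2] - xr(i,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > cut2) continue;
      double sig = rr[i] + rl[j], qq = qr[i] * ql[j];
      double rho2 = r2 + soft2, rho = std::sqrt(rho2);
      double s2 = sig * sig / rho2, s6 = s2 * s2 * s2;
      e += e0 * (s6 * s6 - 2.0 * s6);
      // dE/d(rho2) for LJ part
      double dEdrho2 = e0 * (-6.0 * s6 * s6 + 6.0 * s6) / rho2;
      double fx = 2.0 * dEdrho2 * dx, fy = 2.0 * dEdrho2 * dy, fz = 2.0 * dEdrho2 * dz;
      if (qq != 0.0) {
        double r = std::sqrt(r2) + 1e-12;
        double ee = 332.0 * qq * std::exp(-kap * r) / epsd;
        e += ee / rho;
        // d/dx [ ee(r)/rho ]: ee' = -kap*ee; drho/dx = x/rho; dr/dx = x/r
        double c = (-kap * ee / rho) / r - ee / (rho2 * rho);
        fx += c * dx; fy += c * dy; fz += c * dz;
      }
      gx += fx; gy += fy; gz += fz;
    }
    g[3*j] = gx; g[3*j+1] = gy; g[3*j+2] = gz;
  }
  return e;
}

static void apply_rigid(const std::vector<double> &x0, const double c[3],
                        const double th[3], const double t[3],
                        std::vector<double> &x) {
  // rotation by axis-angle th about c, then translation t (Rodrigues)
  double a = std::sqrt(th[0]*th[0] + th[1]*th[1] + th[2]*th[2]);
  double kx = 0, ky = 0, kz = 1, ca = std::cos(a), sa = std::sin(a);
  if (a > 1e-12) { kx = th[0]/a; ky = th[1]/a; kz = th[2]/a; }
  int n = (int)x0.size() / 3;
  for (int j = 0; j < n; ++j) {
    double px = x0[3*j] - c[0], py = x0[3*j+1] - c[1], pz = x0[3*j+2] - c[2];
    double dot = kx*px + ky*py + kz*pz;
    double cx = ky*pz - kz*py, cy = kz*px - kx*pz, cz = kx*py - ky*px;
    x[3*j]   = c[0] + t[0] + px*ca + cx*sa + kx*dot*(1-ca);
    x[3*j+1] = c[1] + t[1] + py*ca + cy*sa + ky*dot*(1-ca);
    x[3*j+2] = c[2] + t[2] + pz*ca + cz*sa + kz*dot*(1-ca);
  }
}

// Rigid-body steepest-descent minimization of one ligand pose against a
// fixed receptor.  Displacement from the input pose is capped (RMSD).
// [[Rcpp::export]]
List cpp_minimize_rigid(NumericMatrix xr, NumericVector qr, NumericVector rr,
                        NumericMatrix xl, NumericVector ql, NumericVector rl,
                        double e0, double soft, double kap, double epsd,
                        double cutoff, int maxit, double max_rmsd) {
  const int nl = xl.nrow();
  const double soft2 = soft * soft, cut2 = cutoff * cutoff;
  std::vector<double> x0(3 * nl), x(3 * nl), xtry(3 * nl), g(3 * nl);
  double c[3] = {0, 0, 0};
  for (int j = 0; j < nl; ++j) {
    x0[3*j] = xl(j,0); x0[3*j+1] = xl(j,1); x0[3*j+2] = xl(j,2);
    c[0] += xl(j,0); c[1] += xl(j,1); c[2] += xl(j,2);
  }
  c[0] /= nl; c[1] /= nl; c[2] /= nl;
  x = x0;
  double th[3] = {0, 0, 0}, tr[3] = {0, 0, 0};   // cumulative pose update
  double e = energy_grad(xr, qr, rr, x, ql, rl, e0, soft2, kap, epsd, cut2, g);
  const double e_init = e;
  double alpha = 0.05;
  int it = 0;
  for (; it < maxit; ++it) {
    // net gradient wrt translation and wrt rotation about the start centroid
    double gt[3] = {0, 0, 0}, gw[3] = {0, 0, 0};
    for (int j = 0; j < nl; ++j) {
      gt[0] += g[3*j]; gt[1] += g[3*j+1]; gt[2] += g[3*j+2];
      double px = x[3*j] - (c[0] + tr[0]), py = x[3*j+1] - (c[1] + tr[1]),
             pz = x[3*j+2] - (c[2] + tr[2]);
      gw[0] += py * g[3*j+2] - pz * g[3*j+1];
      gw[1] += pz * g[3*j]   - px * g[3*j+2];
      gw[2] += px * g[3*j+1] - py * g[3*j];
    }
    double gn = std::sqrt(gt[0]*gt[0]+gt[1]*gt[1]+gt[2]*gt[2]
                        + gw[0]*gw[0]+gw[1]*gw[1]+gw[2]*gw[2]);
    if (gn < 1e-6 * nl) break;
    bool accepted = false;
    while (alpha > 1e-5) {
      double sc_t = alpha / nl, sc_w = alpha / (nl * 10.0);
      double tht[3] = {th[0] - sc_w*gw[0], th[1] - sc_w*gw[1], th[2] - sc_w*gw[2]};
      double trt[3] = {tr[0] - sc_t*gt[0], tr[1] - sc_t*gt[1], tr[2] - sc_t*gt[2]};
      apply_rigid(x0, c, tht, trt, xtry);
      double ms = 0.0;
      for (int j = 0; j < 3 * nl; ++j) {
        double d = xtry[j] - x0[j]; ms += d * d;
      }
      if (std::sqrt(ms / nl) > max_rmsd) { alpha *= 0.5; continue; }
      double etry = energy_grad(xr, qr, rr, xtry, ql, rl, e0, soft2, kap,
                                epsd, cut2, g);
      if (etry < e - 1e-12) {
        e = etry; x = xtry;
        th[0]=tht[0]; th[1]=tht[1]; th[2]=tht[2];
        tr[0]=trt[0]; tr[1]=trt[1]; tr[2]=trt[2];
        alpha = std::min(alpha * 1.5, 1.0);
        accepted = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!accepted) break;
  }
  NumericMatrix xout(nl, 3);
  double ms = 0.0;
  for (int j = 0; j < nl; ++j) {
    xout(j,0) = x[3*j]; xout(j,1) = x[3*j+1]; xout(j,2) = x[3*j+2];
    for (int k = 0; k < 3; ++k) {
      double d = x[3*j+k] - x0[3*j+k]; ms += d * d;
    }
  }
  return List::create(_["xyz"] = xout, _["energy_init"] = e_init,
                      _["energy"] = e, _["iterations"] = it,
                      _["rmsd_moved"] = std::sqrt(ms / nl),
                      _["theta"] = NumericVector::create(th[0], th[1], th[2]),
                      _["trans"] = NumericVector::create(tr[0], tr[1], tr[2]));
}
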