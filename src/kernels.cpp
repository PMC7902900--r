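#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic golden-angle spiral point set on the unit sphere.
static void spiral_points(int n, std::vector<double>& px,
                          std::vector<double>& py, std::vector<double>& pz) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  px.resize(n); py.resize(n); pz.resize(n);
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }
}

// [[Rcpp::export]]
NumericVector sasa_kernel(NumericMatrix coords, NumericVector radii,
                          IntegerVector target, IntegerVector occluder,
                          double probe, int n_points) {
  int nt = target.size(), no = occluder.size();
  std::vector<double> px, py, pz;
  spiral_points(n_points, px, py, pz);
  NumericVector area(nt);
  for (int a = 0; a < nt; ++a) {
    int i = target[a];
    double ri = radii[i] + probe;
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    // occluders within reach of atom i's expanded sphere
    std::vector<int> near;
    near.reserve(no);
    for (int b = 0; b < no; ++b) {
      int j = occluder[b];
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi, dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = ri + rj;
      if (d2 < rr * rr) near.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double x = xi + ri * px[k], y = yi + ri * py[k], z = zi + ri * pz[k];
      bool buried = false;
      for (size_t b = 0; b < near.size(); ++b) {
        int j = near[b];
        double rj = radii[j] + probe;
        double dx = x - coords(j, 0), dy = y - coords(j, 1), dz = z - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[a] = 4.0 * M_PI * ri * ri * ((double)acc / n_points);
  }
  return area;
}

// Fraction of frames in which each residue pair has min heavy-atom
// distance <= cutoff (inclusive). coords: natom x 3 x nframes array.
// resindex: 0-based contiguous residue index per atom (length natom);
// use_atom: logical per atom (heavy-atom mask).
// [[Rcpp::export]]
NumericMatrix contact_fraction_matrix(NumericVector coords, IntegerVector resindex,
                                      LogicalVector use_atom, int n_res,
                                      double cutoff) {
  IntegerVector dims = coords.attr("dim");
  int natom = dims[0], nframes = dims[2];
  double c2 = cutoff * cutoff;
  std::vector<int> atoms;
  for (int i = 0; i < natom; ++i) if (use_atom[i]) atoms.push_back(i);
  int na = atoms.size();
  NumericMatrix count(n_res, n_res);
  std::vector<char> touched(n_res * (size_t)n_res);
  const double* cp = coords.begin();
  for (int f = 0; f < nframes; ++f) {
    std::fill(touched.begin(), touched.end(), 0);
    const double* fx = cp + (size_t)f * natom * 3;
    for (int a = 0; a < na; ++a) {
      int i = atoms[a];
      int ri = resindex[i];
      double xi = fx[i], yi = fx[i + natom], zi = fx[i + 2 * natom];
      for (int b = a + 1; b < na; ++b) {
        int j = atoms[b];
        int rj = resindex[j];
        if (ri == rj) continue;
        size_t key = (size_t)std::min(ri, rj) * n_res + std::max(ri, rj);
        if (touched[key]) continue;
        double dx = fx[j] - xi, dy = fx[j + natom] - yi, dz = fx[j + 2 * natom] - zi;
        if (dx * dx + dy * dy + dz * dz <= c2) touched[key] = 1;
      }
    }
    for (int r = 0; r < n_res; ++r)
      for (int s = r + 1; s < n_res; ++s)
        if (touched[(size_t)r * n_res + s]) { count(r, s) += 1; count(s, r) += 1; }
  }
  for (int r = 0; r < n_res; ++r)
    for (int s = 0; s < n_res; ++s) count(r, s) /= nframes;
  return count;
}

// Pairwise RMSD matrix over already-superposed frames (no per-pair refit).
// coords: nsel x 3 x nframes.
// [[Rcpp::export]]
NumericMatrix pairwise_rmsd_matrix(NumericVector coords) {
  IntegerVector dims = coords.attr("dim");
  int n = dims[0], nf = dims[2];
  NumericMatrix out(nf, nf);
  const double* cp = coords.begin();
  for (int f = 0; f < nf; ++f) {
    const double* a = cp + (size_t)f * n * 3;
    for (int g = f + 1; g < nf; ++g) {
      const double* b = cp + (size_t)g * n * 3;
      double s = 0;
      for (int k = 0; k < 3 * n; ++k) { double d = a[k] - b[k]; s += d * d; }
      double r = std::sqrt(s / n);
      out(f, g) = r; out(g, f) = r;
    }
  }
  return out;
}

// Finite-difference Poisson(-Boltzmann, linearized) solver on a uniform
// grid with successive over-relaxation (red-black Gauss-Seidel).
// Nodes at origin + (i,j,k)*h.  Face dielectric from the midpoint's
// position relative to the union of atom spheres (uniform=true forces
// eps_in everywhere).  Charges spread trilinearly.  Dirichlet boundary
// from (Debye-Hueckel screened) monopoles in the exterior dielectric.
// Returns potential (kcal/mol/e) interpolated at eval points.
// [[Rcpp::export]]
List pb_fd_solve(NumericMatrix coords, NumericVector q, NumericVector radii,
                 NumericVector origin, IntegerVector npts, double h,
                 double eps_in, double eps_out, bool uniform,
                 double kappa, NumericMatrix eval_points,
                 double tol, int max_iter, double omega) {
  const double kcoul = 332.0636;
  const double fourpi_k = 4.0 * M_PI * kcoul;
  int nx = npts[0], ny = npts[1], nz = npts[2];
  size_t nn = (size_t)nx * ny * nz;
  int natom = coords.nrow();
  double bc_eps = uniform ? eps_in : eps_out;

  std::vector<double> phi(nn, 0.0), rhs(nn, 0.0);
  std::vector<float> epsx(nn), epsy(nn), epsz(nn);
  std::vector<char> outside(nn, 1);

  auto idx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };

  // dielectric maps: eps on the +x/+y/+z faces of each node, harmonically
  // averaged from the exact fraction of the inter-node edge inside the
  // atom spheres (per-atom exact chord length, combined by max; exact for
  // non-overlapping spheres and a mild underestimate for overlaps)
  if (uniform) {
    std::fill(epsx.begin(), epsx.end(), (float)eps_in);
    std::fill(epsy.begin(), epsy.end(), (float)eps_in);
    std::fill(epsz.begin(), epsz.end(), (float)eps_in);
  } else {
    std::vector<float> fxv(nn, 0.0f), fyv(nn, 0.0f), fzv(nn, 0.0f);
    auto chord = [&](double d_along, double perp2, double r2) -> double {
      // fraction of segment t in [0, h] with (d_along + t)^2 + perp2 < r2
      double rad = r2 - perp2;
      if (rad <= 0) return 0.0;
      double s = std::sqrt(rad);
      double t1 = std::max(0.0, -d_along - s), t2 = std::min(h, -d_along + s);
      return t2 > t1 ? (t2 - t1) / h : 0.0;
    };
    for (int a = 0; a < natom; ++a) {
      double r = radii[a];
      if (r <= 0) continue;
      double ax = coords(a, 0) - origin[0], ay = coords(a, 1) - origin[1],
             az = coords(a, 2) - origin[2];
      int i0 = std::max(0, (int)std::floor((ax - r) / h) - 1);
      int i1 = std::min(nx - 1, (int)std::ceil((ax + r) / h) + 1);
      int j0 = std::max(0, (int)std::floor((ay - r) / h) - 1);
      int j1 = std::min(ny - 1, (int)std::ceil((ay + r) / h) + 1);
      int k0 = std::max(0, (int)std::floor((az - r) / h) - 1);
      int k1 = std::min(nz - 1, (int)std::ceil((az + r) / h) + 1);
      double r2 = r * r;
      for (int k = k0; k <= k1; ++k) {
        double dz = k * h - az, dz2 = dz * dz;
        for (int j = j0; j <= j1; ++j) {
          double dy = j * h - ay, dy2 = dy * dy;
          for (int i = i0; i <= i1; ++i) {
            double dx = i * h - ax;
            size_t id = idx(i, j, k);
            double f;
            f = chord(dx, dy2 + dz2, r2);
            if (f > fxv[id]) fxv[id] = (float)f;
            f = chord(dy, dx * dx + dz2, r2);
            if (f > fyv[id]) fyv[id] = (float)f;
            f = chord(dz, dx * dx + dy2, r2);
            if (f > fzv[id]) fzv[id] = (float)f;
            if (dx * dx + dy2 + dz2 < r2) outside[id] = 0;
          }
        }
      }
    }
    for (size_t id = 0; id < nn; ++id) {
      epsx[id] = (float)(1.0 / (fxv[id] / eps_in + (1.0 - fxv[id]) / eps_out));
      epsy[id] = (float)(1.0 / (fyv[id] / eps_in + (1.0 - fyv[id]) / eps_out));
      epsz[id] = (float)(1.0 / (fzv[id] / eps_in + (1.0 - fzv[id]) / eps_out));
    }
  }

  // trilinear charge spreading
  for (int a = 0; a < natom; ++a) {
    if (q[a] == 0.0) continue;
    double ax = (coords(a, 0) - origin[0]) / h, ay = (coords(a, 1) - origin[1]) / h,
           az = (coords(a, 2) - origin[2]) / h;
    int i = (int)std::floor(ax), j = (int)std::floor(ay), k = (int)std::floor(az);
    if (i < 0 || j < 0 || k < 0 || i >= nx - 1 || j >= ny - 1 || k >= nz - 1)
      stop("charge outside grid interior; increase padding");
    double fx = ax - i, fy = ay - j, fz = az - k;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          rhs[idx(i + di, j + dj, k + dk)] += fourpi_k * q[a] * w / h;
        }
  }

  // Dirichlet boundary: screened monopole sum in exterior dielectric
  auto bc_phi = [&](double x, double y, double z) -> double {
    double s = 0;
    for (int a = 0; a < natom; ++a) {
      if (q[a] == 0.0) continue;
      double dx = x - coords(a, 0), dy = y - coords(a, 1), dz = z - coords(a, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      double scr = (kappa > 0 && !uniform) ? std::exp(-kappa * r) : 1.0;
      s += kcoul * q[a] * scr / (bc_eps * r);
    }
    return s;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          phi[idx(i, j, k)] = bc_phi(origin[0] + i * h, origin[1] + j * h,
                                     origin[2] + k * h);
      }

  // SOR sweeps (red-black ordering)
  double kap2h2 = kappa * kappa * h * h * eps_out;
  double maxdelta = 0;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    maxdelta = 0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + color) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            size_t id = idx(i, j, k);
            double ex1 = epsx[id], ex0 = epsx[id - 1];
            double ey1 = epsy[id], ey0 = epsy[id - (size_t)nx];
            double ez1 = epsz[id], ez0 = epsz[id - (size_t)nx * ny];
            double num = ex1 * phi[id + 1] + ex0 * phi[id - 1] +
                         ey1 * phi[id + nx] + ey0 * phi[id - (size_t)nx] +
                         ez1 * phi[id + (size_t)nx * ny] +
                         ez0 * phi[id - (size_t)nx * ny] + rhs[id];
            double den = ex1 + ex0 + ey1 + ey0 + ez1 + ez0;
            if (kappa > 0 && !uniform && outside[id]) den += kap2h2;
            double nv = num / den;
            double d = nv - phi[id];
            phi[id] += omega * d;
            double ad = std::fabs(d);
            if (ad > maxdelta) maxdelta = ad;
          }
        }
    }
    if (maxdelta < tol) break;
  }
  bool converged = (maxdelta < tol);

  // trilinear interpolation of phi at evaluation points
  int ne = eval_points.nrow();
  NumericVector out(ne);
  for (int e = 0; e < ne; ++e) {
    double ax = (eval_points(e, 0) - origin[0]) / h,
           ay = (eval_points(e, 1) - origin[1]) / h,
           az = (eval_points(e, 2) - origin[2]) / h;
    int i = (int)std::floor(ax), j = (int)std::floor(ay), k = (int)std::floor(az);
    if (i < 0 || j < 0 || k < 0 || i >= nx - 1 || j >= ny - 1 || k >= nz - 1)
      stop("evaluation point outside grid interior");
    double fx = ax - i, fy = ay - j, fz = az - k;
    double s = 0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          s += w * phi[idx(i + di, j + dj, k + dk)];
        }
    out[e] = s;
  }
  return List::create(_["phi"] = out, _["iterations"] = it,
                      _["residual"] = maxdelta, _["converged"] = converged);
}
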