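#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Voxel grids are passed as flat logical/numeric vectors in R array order
// (x fastest), with dims = (nx, ny, nz). All distances in Angstrom.

static inline int vox_index(int ix, int iy, int iz, const int* d) {
  return ix + d[0] * (iy + d[1] * iz);
}

// [[Rcpp::export]]
LogicalVector cpp_inside_mask(NumericMatrix vox, NumericMatrix atoms,
                              NumericVector radii) {
  const int n = vox.nrow(), m = atoms.nrow();
  LogicalVector out(n);
  if (m == 0) return out;
  // cell list: each atom is binned into every cell its sphere's AABB
  // overlaps, so a point only queries its own cell
  const double cell = 3.0;
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) { lo[c] = R_PosInf; hi[c] = R_NegInf; }
  double maxR = 0.0;
  for (int j = 0; j < m; ++j) {
    for (int c = 0; c < 3; ++c) {
      if (atoms(j, c) < lo[c]) lo[c] = atoms(j, c);
      if (atoms(j, c) > hi[c]) hi[c] = atoms(j, c);
    }
    if (radii[j] > maxR) maxR = radii[j];
  }
  for (int c = 0; c < 3; ++c) { lo[c] -= maxR + 1e-6; hi[c] += maxR + 1e-6; }
  int nc[3];
  for (int c = 0; c < 3; ++c)
    nc[c] = std::max(1, (int)std::ceil((hi[c] - lo[c]) / cell));
  std::vector<std::vector<int> > bins(nc[0] * nc[1] * nc[2]);
  for (int j = 0; j < m; ++j) {
    int c0[3], c1[3];
    for (int c = 0; c < 3; ++c) {
      c0[c] = std::max(0, (int)((atoms(j, c) - radii[j] - lo[c]) / cell));
      c1[c] = std::min(nc[c] - 1,
                       (int)((atoms(j, c) + radii[j] - lo[c]) / cell));
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx)
          bins[cx + nc[0] * (cy + nc[1] * cz)].push_back(j);
  }
  for (int i = 0; i < n; ++i) {
    const double px = vox(i, 0), py = vox(i, 1), pz = vox(i, 2);
    bool inside = false;
    if (px >= lo[0] && px <= hi[0] && py >= lo[1] && py <= hi[1] &&
        pz >= lo[2] && pz <= hi[2]) {
      const int cx = std::min(nc[0] - 1, (int)((px - lo[0]) / cell));
      const int cy = std::min(nc[1] - 1, (int)((py - lo[1]) / cell));
      const int cz = std::min(nc[2] - 1, (int)((pz - lo[2]) / cell));
      const std::vector<int>& b = bins[cx + nc[0] * (cy + nc[1] * cz)];
      for (size_t q = 0; q < b.size(); ++q) {
        const int j = b[q];
        const double dx = atoms(j, 0) - px, dy = atoms(j, 1) - py,
                     dz = atoms(j, 2) - pz;
        if (dx * dx + dy * dy + dz * dz <= radii[j] * radii[j]) {
          inside = true;
          break;
        }
      }
    }
    out[i] = inside;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_atom_dist(NumericMatrix vox, NumericMatrix atoms) {
  const int n = vox.nrow(), m = atoms.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = vox(i, 0), py = vox(i, 1), pz = vox(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = atoms(j, 0) - px, dy = atoms(j, 1) - py,
                   dz = atoms(j, 2) - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Minimum distance from each voxel center to any atom's vdW surface
// (negative inside an atom).
// [[Rcpp::export]]
NumericVector cpp_min_surface_dist(NumericMatrix vox, NumericMatrix atoms,
                                   NumericVector radii) {
  const int n = vox.nrow(), m = atoms.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = vox(i, 0), py = vox(i, 1), pz = vox(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = atoms(j, 0) - px, dy = atoms(j, 1) - py,
                   dz = atoms(j, 2) - pz;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[j];
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Fraction of rays from each voxel center that intersect an atom sphere
// within `cutoff` along the ray. Directions are unit vectors (rows of dirs).
// Exact ray-sphere test accelerated by a uniform cell list: atoms are
// binned into every cell their sphere's bounding box overlaps, and each
// ray walks its cells with an Amanatides-Woo traversal.
// [[Rcpp::export]]
NumericVector cpp_ray_burial(NumericMatrix vox, NumericMatrix atoms,
                             NumericVector radii, NumericMatrix dirs,
                             double cutoff) {
  const int n = vox.nrow(), m = atoms.nrow(), k = dirs.nrow();
  NumericVector out(n);
  if (m == 0) return out;
  const double cell = 3.0;
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) { lo[c] = R_PosInf; hi[c] = R_NegInf; }
  double maxR = 0.0;
  for (int j = 0; j < m; ++j) {
    for (int c = 0; c < 3; ++c) {
      if (atoms(j, c) < lo[c]) lo[c] = atoms(j, c);
      if (atoms(j, c) > hi[c]) hi[c] = atoms(j, c);
    }
    if (radii[j] > maxR) maxR = radii[j];
  }
  for (int c = 0; c < 3; ++c) { lo[c] -= maxR + 1e-6; hi[c] += maxR + 1e-6; }
  int nc[3];
  for (int c = 0; c < 3; ++c)
    nc[c] = std::max(1, (int)std::ceil((hi[c] - lo[c]) / cell));
  const int ncells = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > bins(ncells);
  for (int j = 0; j < m; ++j) {
    int c0[3], c1[3];
    for (int c = 0; c < 3; ++c) {
      c0[c] = std::max(0, (int)((atoms(j, c) - radii[j] - lo[c]) / cell));
      c1[c] = std::min(nc[c] - 1,
                       (int)((atoms(j, c) + radii[j] - lo[c]) / cell));
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx)
          bins[cx + nc[0] * (cy + nc[1] * cz)].push_back(j);
  }
  for (int i = 0; i < n; ++i) {
    const double p[3] = {vox(i, 0), vox(i, 1), vox(i, 2)};
    int hits = 0;
    for (int r = 0; r < k; ++r) {
      const double u[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
      // clip ray segment [0, cutoff] against the cell-grid AABB
      double t0 = 0.0, t1 = cutoff;
      bool miss = false;
      for (int c = 0; c < 3; ++c) {
        if (std::fabs(u[c]) < 1e-12) {
          if (p[c] < lo[c] || p[c] > hi[c]) { miss = true; break; }
        } else {
          double ta = (lo[c] - p[c]) / u[c], tb = (hi[c] - p[c]) / u[c];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { miss = true; break; }
        }
      }
      if (miss) continue;
      // Amanatides-Woo traversal from t0 to t1
      const double eps = 1e-9;
      double start[3];
      int cc[3], step[3];
      double tmax[3], tdelta[3];
      for (int c = 0; c < 3; ++c) {
        start[c] = p[c] + (t0 + eps) * u[c];
        cc[c] = (int)((start[c] - lo[c]) / cell);
        if (cc[c] < 0) cc[c] = 0;
        if (cc[c] >= nc[c]) cc[c] = nc[c] - 1;
        if (u[c] > eps) {
          step[c] = 1;
          tmax[c] = ((cc[c] + 1) * cell + lo[c] - p[c]) / u[c];
          tdelta[c] = cell / u[c];
        } else if (u[c] < -eps) {
          step[c] = -1;
          tmax[c] = (cc[c] * cell + lo[c] - p[c]) / u[c];
          tdelta[c] = -cell / u[c];
        } else {
          step[c] = 0;
          tmax[c] = R_PosInf;
          tdelta[c] = R_PosInf;
        }
      }
      bool hit = false;
      while (true) {
        const std::vector<int>& b =
          bins[cc[0] + nc[0] * (cc[1] + nc[1] * cc[2])];
        for (size_t q = 0; q < b.size(); ++q) {
          const int j = b[q];
          const double ax = atoms(j, 0) - p[0], ay = atoms(j, 1) - p[1],
                       az = atoms(j, 2) - p[2];
          const double t = ax * u[0] + ay * u[1] + az * u[2];
          if (t <= 0.0 || t > cutoff) continue;
          const double d2 = ax * ax + ay * ay + az * az - t * t;
          if (d2 <= radii[j] * radii[j]) { hit = true; break; }
        }
        if (hit) break;
        // advance to next cell
        int axis = 0;
        if (tmax[1] < tmax[axis]) axis = 1;
        if (tmax[2] < tmax[axis]) axis = 2;
        if (tmax[axis] > t1) break;
        cc[axis] += step[axis];
        if (cc[axis] < 0 || cc[axis] >= nc[axis]) break;
        tmax[axis] += tdelta[axis];
      }
      if (hit) ++hits;
    }
    out[i] = (double)hits / (double)k;
  }
  return out;
}

// Surrogate probe energy: per-atom 6-12 potential with separate attractive
// and repulsive well depths, plus a flat polar bonus within polar_cut for
// atoms with bonus > 0. E_j = eps_rep*(rm/r)^12 - 2*eps_att*(rm/r)^6 - bonus.
// [[Rcpp::export]]
NumericVector cpp_probe_energy(NumericMatrix vox, NumericMatrix atoms,
                               NumericVector eps_att, NumericVector eps_rep,
                               NumericVector rmin, NumericVector bonus,
                               double polar_cut, double cutoff) {
  const int n = vox.nrow(), m = atoms.nrow();
  NumericVector out(n);
  const double cut2 = cutoff * cutoff, pol2 = polar_cut * polar_cut;
  for (int i = 0; i < n; ++i) {
    const double px = vox(i, 0), py = vox(i, 1), pz = vox(i, 2);
    double e = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = atoms(j, 0) - px, dy = atoms(j, 1) - py,
                   dz = atoms(j, 2) - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2 || d2 <= 1e-12) continue;
      const double s2 = (rmin[j] * rmin[j]) / d2;
      const double s6 = s2 * s2 * s2;
      e += eps_rep[j] * s6 * s6 - 2.0 * eps_att[j] * s6;
      if (bonus[j] > 0.0 && d2 <= pol2) e -= bonus[j];
    }
    out[i] = e;
  }
  return out;
}

static std::vector<std::array<int, 3> > ball_offsets(double radius) {
  std::vector<std::array<int, 3> > off;
  const int r = (int)std::floor(radius + 1e-9);
  const double r2 = radius * radius + 1e-9;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r2) {
          std::array<int, 3> a = {{dx, dy, dz}};
          off.push_back(a);
        }
  return off;
}

// Binary erosion by a Euclidean ball (radius in voxel units).
// Out-of-grid treated as background, so the grid border erodes.
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims, double radius) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<std::array<int, 3> > off = ball_offsets(radius);
  LogicalVector out(mask.size());
  for (int iz = 0; iz < d[2]; ++iz)
    for (int iy = 0; iy < d[1]; ++iy)
      for (int ix = 0; ix < d[0]; ++ix) {
        const int v = vox_index(ix, iy, iz, d);
        if (!mask[v]) { out[v] = false; continue; }
        bool keep = true;
        for (size_t q = 0; q < off.size(); ++q) {
          const int jx = ix + off[q][0], jy = iy + off[q][1],
                    jz = iz + off[q][2];
          if (jx < 0 || jy < 0 || jz < 0 || jx >= d[0] || jy >= d[1] ||
              jz >= d[2] || !mask[vox_index(jx, jy, jz, d)]) {
            keep = false;
            break;
          }
        }
        out[v] = keep;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims,
                         double radius) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<std::array<int, 3> > off = ball_offsets(radius);
  LogicalVector out(mask.size());
  for (int iz = 0; iz < d[2]; ++iz)
    for (int iy = 0; iy < d[1]; ++iy)
      for (int ix = 0; ix < d[0]; ++ix) {
        const int v = vox_index(ix, iy, iz, d);
        bool hit = false;
        for (size_t q = 0; q < off.size(); ++q) {
          const int jx = ix + off[q][0], jy = iy + off[q][1],
                    jz = iz + off[q][2];
          if (jx >= 0 && jy >= 0 && jz >= 0 && jx < d[0] && jy < d[1] &&
              jz < d[2] && mask[vox_index(jx, jy, jz, d)]) {
            hit = true;
            break;
          }
        }
        out[v] = hit;
      }
  return out;
}

// 26-connected component labelling; background 0, labels 1..k in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int iz = 0; iz < d[2]; ++iz)
    for (int iy = 0; iy < d[1]; ++iy)
      for (int ix = 0; ix < d[0]; ++ix) {
        const int v = vox_index(ix, iy, iz, d);
        if (!mask[v] || lab[v] != 0) continue;
        ++next;
        lab[v] = next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          const int u = stack.back();
          stack.pop_back();
          const int ux = u % d[0], uy = (u / d[0]) % d[1], uz = u / (d[0] * d[1]);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int jx = ux + dx, jy = uy + dy, jz = uz + dz;
                if (jx < 0 || jy < 0 || jz < 0 || jx >= d[0] || jy >= d[1] ||
                    jz >= d[2])
                  continue;
                const int w = vox_index(jx, jy, jz, d);
                if (mask[w] && lab[w] == 0) {
                  lab[w] = next;
                  stack.push_back(w);
                }
              }
        }
      }
  return lab;
}

// Morphological reconstruction: 26-connected flood fill of `mask` from
// voxels that are TRUE in `markers` (markers assumed subset of mask).
// [[Rcpp::export]]
LogicalVector cpp_reconstruct(LogicalVector markers, LogicalVector mask,
                              IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  LogicalVector out(mask.size(), false);
  std::vector<int> stack;
  for (int v = 0; v < (int)mask.size(); ++v)
    if (markers[v] && mask[v] && !out[v]) {
      out[v] = true;
      stack.push_back(v);
      while (!stack.empty()) {
        const int u = stack.back();
        stack.pop_back();
        const int ux = u % d[0], uy = (u / d[0]) % d[1], uz = u / (d[0] * d[1]);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int jx = ux + dx, jy = uy + dy, jz = uz + dz;
              if (jx < 0 || jy < 0 || jz < 0 || jx >= d[0] || jy >= d[1] ||
                  jz >= d[2])
                continue;
              const int w = vox_index(jx, jy, jz, d);
              if (mask[w] && !out[w]) {
                out[w] = true;
                stack.push_back(w);
              }
            }
      }
    }
  return out;
}

// Boundary surface of a voxel set. Each exposed face contributes
// spacing^2 * |n . e_face|, where n is the local outward normal estimated
// from the occupancy within `normal_radius` voxels; degenerate normals fall
// back to full face weight. Also returns the raw exposed-face count.
// [[Rcpp::export]]
List cpp_surface_area(LogicalVector mask, IntegerVector dims, double spacing,
                      double normal_radius) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<std::array<int, 3> > off = ball_offsets(normal_radius);
  const int face_dx[6] = {1, -1, 0, 0, 0, 0};
  const int face_dy[6] = {0, 0, 1, -1, 0, 0};
  const int face_dz[6] = {0, 0, 0, 0, 1, -1};
  double area = 0.0;
  int faces = 0;
  for (int iz = 0; iz < d[2]; ++iz)
    for (int iy = 0; iy < d[1]; ++iy)
      for (int ix = 0; ix < d[0]; ++ix) {
        const int v = vox_index(ix, iy, iz, d);
        if (!mask[v]) continue;
        // exposed faces of this voxel
        int exp_face[6];
        int n_exp = 0;
        for (int f = 0; f < 6; ++f) {
          const int jx = ix + face_dx[f], jy = iy + face_dy[f],
                    jz = iz + face_dz[f];
          const bool occ = jx >= 0 && jy >= 0 && jz >= 0 && jx < d[0] &&
                           jy < d[1] && jz < d[2] &&
                           mask[vox_index(jx, jy, jz, d)];
          if (!occ) exp_face[n_exp++] = f;
        }
        if (n_exp == 0) continue;
        faces += n_exp;
        // local normal: minus the centroid of occupied offsets
        double gx = 0, gy = 0, gz = 0;
        for (size_t q = 0; q < off.size(); ++q) {
          const int jx = ix + off[q][0], jy = iy + off[q][1],
                    jz = iz + off[q][2];
          if (jx >= 0 && jy >= 0 && jz >= 0 && jx < d[0] && jy < d[1] &&
              jz < d[2] && mask[vox_index(jx, jy, jz, d)]) {
            gx += off[q][0]; gy += off[q][1]; gz += off[q][2];
          }
        }
        const double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
        for (int q = 0; q < n_exp; ++q) {
          const int f = exp_face[q];
          if (gn < 1e-9) {
            area += 1.0;  // isolated voxel: raw face weight
          } else {
            const double ndote = -(gx * face_dx[f] + gy * face_dy[f] +
                                   gz * face_dz[f]) / gn;
            area += std::fabs(ndote);
          }
        }
      }
  return List::create(_["area"] = area * spacing * spacing,
                      _["faces"] = faces,
                      _["raw_area"] = (double)faces * spacing * spacing);
}

// Atoms having at least one voxel center within `cutoff`.
// [[Rcpp::export]]
LogicalVector cpp_atoms_near_voxels(NumericMatrix atoms, NumericMatrix vox,
                                    double cutoff) {
  const int m = atoms.nrow(), n = vox.nrow();
  LogicalVector out(m);
  const double cut2 = cutoff * cutoff;
  for (int j = 0; j < m; ++j) {
    const double px = atoms(j, 0), py = atoms(j, 1), pz = atoms(j, 2);
    bool near = false;
    for (int i = 0; i < n; ++i) {
      const double dx = vox(i, 0) - px, dy = vox(i, 1) - py,
                   dz = vox(i, 2) - pz;
      if (dx * dx + dy * dy + dz * dz <= cut2) { near = true; break; }
    }
    out[j] = near;
  }
  return out;
}
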