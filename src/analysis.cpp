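#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement component for an orthorhombic box.
static inline double mimg(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

static inline double dist2(const double* a, const double* b,
                           const double* box) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  if (box) {
    dx = mimg(dx, box[0]);
    dy = mimg(dy, box[1]);
    dz = mimg(dz, box[2]);
  }
  return dx * dx + dy * dy + dz * dz;
}

// Column-major n x 3 coordinate access.
struct Coords {
  const double* p;
  R_xlen_t n;
  Coords(const NumericMatrix& m) : p(m.begin()), n(m.nrow()) {}
  void get(R_xlen_t i, double* out) const {
    out[0] = p[i];
    out[1] = p[i + n];
    out[2] = p[i + 2 * n];
  }
};

// All-pairs contact count with strict '< cutoff' semantics; optional
// minimum-image convention when box lengths are supplied.
// [[Rcpp::export(name = ".cpp_count_contacts_brute")]]
int cpp_count_contacts_brute(NumericMatrix xa, NumericMatrix xb,
                             double cutoff, Nullable<NumericVector> box_) {
  const double c2 = cutoff * cutoff;
  double boxv[3];
  const double* box = nullptr;
  if (box_.isNotNull()) {
    NumericVector b(box_);
    boxv[0] = b[0]; boxv[1] = b[1]; boxv[2] = b[2];
    box = boxv;
  }
  Coords A(xa), B(xb);
  int count = 0;
  double pa[3], pb[3];
  for (R_xlen_t i = 0; i < A.n; ++i) {
    A.get(i, pa);
    for (R_xlen_t j = 0; j < B.n; ++j) {
      B.get(j, pb);
      if (dist2(pa, pb, box) < c2) ++count;
    }
  }
  return count;
}

// Simple cell list over one coordinate set (no periodic wrap; used for the
// finite nanodisc geometry).  Cells have edge >= cutoff so only the 27
// neighbouring cells need scanning.
struct CellList {
  double lo[3];
  int dim[3];
  double cell;
  std::vector<int> head;   // first atom in cell, -1 if empty
  std::vector<int> next;   // linked list over atoms

  CellList(const Coords& X, const std::vector<int>& idx, double cutoff) {
    double hi[3];
    double p[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i : idx) {
      X.get(i, p);
      for (int k = 0; k < 3; ++k) {
        if (p[k] < lo[k]) lo[k] = p[k];
        if (p[k] > hi[k]) hi[k] = p[k];
      }
    }
    cell = cutoff > 1e-9 ? cutoff : 1.0;
    // widen cells if the span is huge so the grid stays small; cells must
    // never be smaller than the cutoff or the 27-cell scan would miss pairs
    for (int k = 0; k < 3; ++k) {
      double span = hi[k] - lo[k];
      if (std::isfinite(span) && span / cell > 256.0) cell = span / 256.0;
    }
    for (int k = 0; k < 3; ++k) {
      double span = hi[k] - lo[k];
      dim[k] = std::isfinite(span)
                   ? std::max(1, (int)std::floor(span / cell) + 1)
                   : 1;
    }
    head.assign((size_t)dim[0] * dim[1] * dim[2], -1);
    next.assign(X.n, -1);
    for (int i : idx) {
      X.get(i, p);
      int c = cell_of(p);
      next[i] = head[c];
      head[c] = i;
    }
  }
  int clamp(int v, int d) const {
    return v < 0 ? 0 : (v >= d ? d - 1 : v);
  }
  int cell_of(const double* p) const {
    int ix = clamp((int)std::floor((p[0] - lo[0]) / cell), dim[0]);
    int iy = clamp((int)std::floor((p[1] - lo[1]) / cell), dim[1]);
    int iz = clamp((int)std::floor((p[2] - lo[2]) / cell), dim[2]);
    return ix + dim[0] * (iy + dim[1] * iz);
  }
  template <typename F>
  void neighbours(const double* p, F f) const {
    int ix = (int)std::floor((p[0] - lo[0]) / cell);
    int iy = (int)std::floor((p[1] - lo[1]) / cell);
    int iz = (int)std::floor((p[2] - lo[2]) / cell);
    int x0 = std::max(0, ix - 1), x1 = std::min(dim[0] - 1, ix + 1);
    int y0 = std::max(0, iy - 1), y1 = std::min(dim[1] - 1, iy + 1);
    int z0 = std::max(0, iz - 1), z1 = std::min(dim[2] - 1, iz + 1);
    for (int cx = x0; cx <= x1; ++cx)
      for (int cy = y0; cy <= y1; ++cy)
        for (int cz = z0; cz <= z1; ++cz)
          for (int j = head[cx + dim[0] * (cy + dim[1] * cz)]; j != -1;
               j = next[j])
            f(j);
  }
};

// Cell-list accelerated contact count (strict '< cutoff'), no PBC.
// [[Rcpp::export(name = ".cpp_count_contacts_cell")]]
int cpp_count_contacts_cell(NumericMatrix xa, NumericMatrix xb,
                            double cutoff) {
  Coords A(xa), B(xb);
  std::vector<int> idx((size_t)B.n);
  for (R_xlen_t i = 0; i < B.n; ++i) idx[i] = (int)i;
  CellList cl(B, idx, cutoff);
  const double c2 = cutoff * cutoff;
  int count = 0;
  double pa[3], pb[3];
  for (R_xlen_t i = 0; i < A.n; ++i) {
    A.get(i, pa);
    cl.neighbours(pa, [&](int j) {
      B.get(j, pb);
      double dx = pa[0] - pb[0], dy = pa[1] - pb[1], dz = pa[2] - pb[2];
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    });
  }
  return count;
}

// Grouped contact counts for one frame: probe atoms carry a group label
// (residue slot), target atoms carry a group label (moiety slot); returns
// an n_pg x n_tg integer matrix of atom-pair counts within 'cutoff'.
// Indices are 0-based; groups are 0-based slot ids.
// [[Rcpp::export(name = ".cpp_grouped_contact_counts")]]
IntegerMatrix cpp_grouped_contact_counts(NumericMatrix coords,
                                         IntegerVector probe_idx,
                                         IntegerVector probe_grp,
                                         IntegerVector target_idx,
                                         IntegerVector target_grp,
                                         int n_pg, int n_tg, double cutoff) {
  Coords X(coords);
  std::vector<int> tidx(target_idx.begin(), target_idx.end());
  std::vector<int> tg((size_t)X.n, -1);
  for (R_xlen_t k = 0; k < target_idx.size(); ++k)
    tg[target_idx[k]] = target_grp[k];
  CellList cl(X, tidx, cutoff);
  IntegerMatrix out(n_pg, n_tg);
  const double c2 = cutoff * cutoff;
  double pa[3], pb[3];
  for (R_xlen_t k = 0; k < probe_idx.size(); ++k) {
    X.get(probe_idx[k], pa);
    int g = probe_grp[k];
    cl.neighbours(pa, [&](int j) {
      X.get(j, pb);
      double dx = pa[0] - pb[0], dy = pa[1] - pb[1], dz = pa[2] - pb[2];
      if (dx * dx + dy * dy + dz * dz < c2) out(g, tg[j]) += 1;
    });
  }
  return out;
}

// Shrake-Rupley SASA for the surface atoms against the occluder set.
// sphere_pts: n_points x 3 unit vectors (deterministic golden spiral).
// A sphere point survives if it is not strictly inside any other occluder's
// expanded sphere (radius r_j + probe).
// [[Rcpp::export(name = ".cpp_sasa_atoms")]]
NumericVector cpp_sasa_atoms(NumericMatrix coords, IntegerVector surface_idx,
                             IntegerVector occ_idx, NumericVector radii,
                             double probe, NumericMatrix sphere_pts) {
  Coords X(coords);
  const int np = sphere_pts.nrow();
  const double* sp = sphere_pts.begin();
  NumericVector out(surface_idx.size());
  double rmax = 0.0;
  for (R_xlen_t k = 0; k < occ_idx.size(); ++k)
    rmax = std::max(rmax, radii[occ_idx[k]]);
  std::vector<int> oidx(occ_idx.begin(), occ_idx.end());
  // neighbour search radius: Ri + rmax + probe covers all possible occluders
  double pi_[3], pj[3];
  std::vector<double> nx, ny, nz, nr2;
  for (R_xlen_t s = 0; s < surface_idx.size(); ++s) {
    int i = surface_idx[s];
    double Ri = radii[i] + probe;
    X.get(i, pi_);
    double reach = Ri + rmax + probe;
    double reach2 = reach * reach;
    nx.clear(); ny.clear(); nz.clear(); nr2.clear();
    for (int j : oidx) {
      if (j == i) continue;
      X.get(j, pj);
      double dx = pj[0] - pi_[0], dy = pj[1] - pi_[1], dz = pj[2] - pi_[2];
      if (dx * dx + dy * dy + dz * dz <= reach2) {
        nx.push_back(pj[0]); ny.push_back(pj[1]); nz.push_back(pj[2]);
        double rj = radii[j] + probe;
        nr2.push_back(rj * rj);
      }
    }
    int acc = 0;
    const size_t nn = nx.size();
    for (int q = 0; q < np; ++q) {
      double px = pi_[0] + Ri * sp[q];
      double py = pi_[1] + Ri * sp[q + np];
      double pz = pi_[2] + Ri * sp[q + 2 * np];
      bool buried = false;
      for (size_t j = 0; j < nn; ++j) {
        double dx = px - nx[j], dy = py - ny[j], dz = pz - nz[j];
        if (dx * dx + dy * dy + dz * dz < nr2[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[s] = (double)acc / np * 4.0 * M_PI * Ri * Ri;
  }
  return out;
}

// Cutoff-truncated Coulomb + Lennard-Jones pair sum between two disjoint
// groups.  Lorentz-Berthelot combining; strict '< cutoff'; errors on
// near-singular pair separations.
// [[Rcpp::export(name = ".cpp_nonbonded_energy")]]
NumericVector cpp_nonbonded_energy(NumericMatrix coords, IntegerVector ia,
                                   IntegerVector ib, NumericVector charge,
                                   NumericVector sigma, NumericVector epsilon,
                                   double cutoff, double clash_floor,
                                   double coulomb_k) {
  Coords X(coords);
  const double c2 = cutoff * cutoff;
  const double f2 = clash_floor * clash_floor;
  double ecoul = 0.0, elj = 0.0;
  double pa[3], pb[3];
  for (R_xlen_t u = 0; u < ia.size(); ++u) {
    int i = ia[u];
    X.get(i, pa);
    for (R_xlen_t v = 0; v < ib.size(); ++v) {
      int j = ib[v];
      X.get(j, pb);
      double dx = pa[0] - pb[0], dy = pa[1] - pb[1], dz = pa[2] - pb[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= c2) continue;
      if (d2 < f2)
        stop("clash error: atoms %d and %d are %.4f A apart", i + 1, j + 1,
             std::sqrt(d2));
      double d = std::sqrt(d2);
      ecoul += coulomb_k * charge[i] * charge[j] / d;
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double eij = std::sqrt(epsilon[i] * epsilon[j]);
      if (eij > 0.0) {
        double sr2 = sij * sij / d2;
        double sr6 = sr2 * sr2 * sr2;
        elj += 4.0 * eij * (sr6 * sr6 - sr6);
      }
    }
  }
  return NumericVector::create(ecoul, elj);
}
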