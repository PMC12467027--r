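#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/(mol K)

struct GridSet {
  std::vector<const double*> maps; // per-atom-usable grid value arrays
  const int* excl;                 // exclusion mask (LGLSXP data)
  double ox, oy, oz, spacing;
  int nx, ny, nz;

  // nearest-voxel linear index (R column-major, x fastest), -1 if outside
  inline long lin_index(double x, double y, double z) const {
    int i = (int)std::floor((x - ox) / spacing + 0.5);
    if (i < 0 || i >= nx) return -1;
    int j = (int)std::floor((y - oy) / spacing + 0.5);
    if (j < 0 || j >= ny) return -1;
    int k = (int)std::floor((z - oz) / spacing + 0.5);
    if (k < 0 || k >= nz) return -1;
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
};

struct Topology {
  std::vector<int> map_idx;   // 0-based grid index per atom, -1 unmapped
  std::vector<char> heavy;
  std::vector<double> mass;
  double total_mass;
  // rotatable dihedrals
  std::vector<std::array<int,4>> dih_atoms;       // 0-based
  std::vector<std::vector<int>> dih_moving;       // 0-based
  std::vector<std::pair<int,int>> clash_pairs;    // 0-based
  double excl_penalty, barrier, clash_dist, clash_k, intra_weight;
};

static inline double lgfe_of(const std::vector<double>& X, int n,
                             const GridSet& g, const Topology& top) {
  double e = 0.0;
  for (int a = 0; a < n; ++a) {
    if (!top.heavy[a]) continue;
    long li = g.lin_index(X[a], X[a + n], X[a + 2 * n]);
    if (li < 0) continue;            // bulk
    if (g.excl[li]) { e += top.excl_penalty; continue; }
    int m = top.map_idx[a];
    if (m >= 0) e += g.maps[m][li];
  }
  return e;
}

static inline double dihedral_angle(const std::vector<double>& X, int n,
                                    const std::array<int,4>& q) {
  double b1[3], b2[3], b3[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = X[q[1] + d * n] - X[q[0] + d * n];
    b2[d] = X[q[2] + d * n] - X[q[1] + d * n];
    b3[d] = X[q[3] + d * n] - X[q[2] + d * n];
  }
  double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                   b1[0]*b2[1]-b1[1]*b2[0] };
  double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                   b2[0]*b3[1]-b2[1]*b3[0] };
  double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                   n1[0]*b2[1]-n1[1]*b2[0] };
  double nb2 = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
  double x = n1[0]*n2[0] + n1[1]*n2[1] + n1[2]*n2[2];
  double y = (m1[0]*n2[0] + m1[1]*n2[1] + m1[2]*n2[2]) / nb2;
  return std::atan2(y, x);
}

static inline double intra_of(const std::vector<double>& X, int n,
                              const Topology& top) {
  double e = 0.0;
  for (size_t t = 0; t < top.dih_atoms.size(); ++t) {
    double phi = dihedral_angle(X, n, top.dih_atoms[t]);
    e += 0.5 * top.barrier * (1.0 + std::cos(3.0 * phi));
  }
  double dc = top.clash_dist, dc2 = dc * dc;
  for (size_t p = 0; p < top.clash_pairs.size(); ++p) {
    int i = top.clash_pairs[p].first, j = top.clash_pairs[p].second;
    double dx = X[i] - X[j];
    double dy = X[i + n] - X[j + n];
    double dz = X[i + 2*n] - X[j + 2*n];
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 < dc2) {
      double d = std::sqrt(d2);
      e += 0.5 * top.clash_k * (dc - d) * (dc - d);
    }
  }
  return e;
}

static inline void rot_from_axis_angle(const double* u, double ang,
                                       double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang), t = 1.0 - c;
  R[0][0] = c + u[0]*u[0]*t;
  R[0][1] = u[0]*u[1]*t - u[2]*s;
  R[0][2] = u[0]*u[2]*t + u[1]*s;
  R[1][0] = u[0]*u[1]*t + u[2]*s;
  R[1][1] = c + u[1]*u[1]*t;
  R[1][2] = u[1]*u[2]*t - u[0]*s;
  R[2][0] = u[0]*u[2]*t - u[1]*s;
  R[2][1] = u[1]*u[2]*t + u[0]*s;
  R[2][2] = c + u[2]*u[2]*t;
}

static inline void random_unit(double* u) {
  double nrm = 0.0;
  do {
    u[0] = norm_rand(); u[1] = norm_rand(); u[2] = norm_rand();
    nrm = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  } while (nrm < 1e-12);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

// One Metropolis MC / simulated-annealing stage.
// xyz: n x 3; temperature ramps linearly t_start -> t_end across steps.
// Returns final and best-seen (by LGFE) coordinates plus diagnostics.
// [[Rcpp::export]]
List cpp_mc_stage(NumericMatrix xyz,
                  IntegerVector map_idx, LogicalVector heavy,
                  NumericVector mass,
                  List grids, LogicalVector excl,
                  NumericVector origin, double spacing, IntegerVector dims,
                  List dihedrals, IntegerMatrix clash_pairs,
                  double excl_penalty, double barrier, double clash_dist,
                  double clash_k, double intra_weight,
                  int n_steps, double t_start, double t_end,
                  double max_trans, double max_rot, double max_dih,
                  bool return_log) {
  const int n = xyz.nrow();
  GridSet g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.spacing = spacing;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.excl = LOGICAL(excl);
  for (int m = 0; m < grids.size(); ++m) {
    NumericVector gv = grids[m];
    g.maps.push_back(REAL(gv));
  }
  Topology top;
  top.map_idx.assign(map_idx.begin(), map_idx.end());
  top.heavy.resize(n);
  top.mass.assign(mass.begin(), mass.end());
  top.total_mass = 0.0;
  for (int a = 0; a < n; ++a) {
    top.heavy[a] = heavy[a] ? 1 : 0;
    top.total_mass += top.mass[a];
  }
  for (int t = 0; t < dihedrals.size(); ++t) {
    List dd = dihedrals[t];
    IntegerVector q = dd["atoms"];
    IntegerVector mv = dd["moving"];
    std::array<int,4> qa = { q[0]-1, q[1]-1, q[2]-1, q[3]-1 };
    top.dih_atoms.push_back(qa);
    std::vector<int> mvv(mv.size());
    for (int i = 0; i < mv.size(); ++i) mvv[i] = mv[i] - 1;
    top.dih_moving.push_back(mvv);
  }
  for (int p = 0; p < clash_pairs.nrow(); ++p)
    top.clash_pairs.push_back(std::make_pair(clash_pairs(p,0)-1,
                                             clash_pairs(p,1)-1));
  top.excl_penalty = excl_penalty;
  top.barrier = barrier;
  top.clash_dist = clash_dist;
  top.clash_k = clash_k;
  top.intra_weight = intra_weight;

  std::vector<double> cur(3 * n), prop(3 * n), best(3 * n);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) cur[a + d * n] = xyz(a, d);

  double cur_lgfe = lgfe_of(cur, n, g, top);
  double cur_intra = intra_of(cur, n, top);
  double cur_e = cur_lgfe + intra_weight * cur_intra;
  best = cur;
  double best_lgfe = cur_lgfe, best_e = cur_e;

  const int n_dih = (int)top.dih_atoms.size();
  const int n_kinds = 2 + (n_dih > 0 ? 1 : 0);
  int n_accept = 0, n_uphill_T0 = 0;

  NumericVector log_T, log_dE;
  LogicalVector log_acc;
  if (return_log) {
    log_T = NumericVector(n_steps);
    log_dE = NumericVector(n_steps);
    log_acc = LogicalVector(n_steps);
  }

  for (int step = 0; step < n_steps; ++step) {
    double T = (n_steps > 1)
      ? t_start + (t_end - t_start) * ((double)step / (double)(n_steps - 1))
      : t_start;
    int kind = (int)(unif_rand() * n_kinds);
    if (kind >= n_kinds) kind = n_kinds - 1;

    prop = cur;
    if (kind == 0) {                       // translate
      if (max_trans > 0) {
        double u[3]; random_unit(u);
        double r = unif_rand() * max_trans;
        for (int a = 0; a < n; ++a) {
          prop[a]       += u[0] * r;
          prop[a + n]   += u[1] * r;
          prop[a + 2*n] += u[2] * r;
        }
      }
    } else if (kind == 1) {                // rigid rotation about COM
      if (max_rot > 0) {
        double u[3]; random_unit(u);
        double ang = (2.0 * unif_rand() - 1.0) * max_rot * M_PI / 180.0;
        double R[3][3]; rot_from_axis_angle(u, ang, R);
        double cx = 0, cy = 0, cz = 0;
        for (int a = 0; a < n; ++a) {
          cx += top.mass[a] * cur[a];
          cy += top.mass[a] * cur[a + n];
          cz += top.mass[a] * cur[a + 2*n];
        }
        cx /= top.total_mass; cy /= top.total_mass; cz /= top.total_mass;
        for (int a = 0; a < n; ++a) {
          double x = cur[a] - cx, y = cur[a + n] - cy, z = cur[a + 2*n] - cz;
          prop[a]       = cx + R[0][0]*x + R[0][1]*y + R[0][2]*z;
          prop[a + n]   = cy + R[1][0]*x + R[1][1]*y + R[1][2]*z;
          prop[a + 2*n] = cz + R[2][0]*x + R[2][1]*y + R[2][2]*z;
        }
      }
    } else {                               // dihedral
      if (max_dih > 0) {
        int t = (int)(unif_rand() * n_dih);
        if (t >= n_dih) t = n_dih - 1;
        double ang = (2.0 * unif_rand() - 1.0) * max_dih * M_PI / 180.0;
        const std::array<int,4>& q = top.dih_atoms[t];
        int ja = q[1], ka = q[2];
        double ax[3] = { cur[ka] - cur[ja], cur[ka + n] - cur[ja + n],
                         cur[ka + 2*n] - cur[ja + 2*n] };
        double nrm = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
        if (nrm > 1e-12) {
          ax[0] /= nrm; ax[1] /= nrm; ax[2] /= nrm;
          double R[3][3]; rot_from_axis_angle(ax, ang, R);
          double px = cur[ka], py = cur[ka + n], pz = cur[ka + 2*n];
          const std::vector<int>& mv = top.dih_moving[t];
          for (size_t ii = 0; ii < mv.size(); ++ii) {
            int a = mv[ii];
            double x = cur[a] - px, y = cur[a + n] - py,
                   z = cur[a + 2*n] - pz;
            prop[a]       = px + R[0][0]*x + R[0][1]*y + R[0][2]*z;
            prop[a + n]   = py + R[1][0]*x + R[1][1]*y + R[1][2]*z;
            prop[a + 2*n] = pz + R[2][0]*x + R[2][1]*y + R[2][2]*z;
          }
        }
      }
    }

    double p_lgfe = lgfe_of(prop, n, g, top);
    double p_intra = intra_of(prop, n, top);
    double p_e = p_lgfe + intra_weight * p_intra;
    double dE = p_e - cur_e;
    bool accept;
    if (dE <= 0) accept = true;
    else if (T <= 0) accept = false;
    else accept = (unif_rand() < std::exp(-dE / (KB * T)));

    if (return_log) { log_T[step] = T; log_dE[step] = dE; log_acc[step] = accept; }
    if (accept) {
      if (dE > 0 && T <= 0) ++n_uphill_T0;  // should never happen
      cur.swap(prop);
      cur_lgfe = p_lgfe; cur_intra = p_intra; cur_e = p_e;
      ++n_accept;
      if (cur_lgfe < best_lgfe) {
        best = cur; best_lgfe = cur_lgfe; best_e = cur_e;
      }
    }
  }

  NumericMatrix fin(n, 3), bst(n, 3);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) {
      fin(a, d) = cur[a + d * n];
      bst(a, d) = best[a + d * n];
    }
  List out = List::create(
    _["final_xyz"] = fin, _["final_lgfe"] = cur_lgfe,
    _["final_energy"] = cur_e,
    _["best_xyz"] = bst, _["best_lgfe"] = best_lgfe,
    _["best_energy"] = best_e,
    _["n_accepted"] = n_accept, _["n_uphill_at_T0"] = n_uphill_T0);
  if (return_log) {
    out["log"] = DataFrame::create(_["temperature"] = log_T,
                                   _["delta_e"] = log_dE,
                                   _["accepted"] = log_acc);
  }
  return out;
}

// Scoring cross-check helper: LGFE + intramolecular surrogate of one
// conformation through the compiled path.
// [[Rcpp::export]]
List cpp_score(NumericMatrix xyz,
               IntegerVector map_idx, LogicalVector heavy,
               NumericVector mass,
               List grids, LogicalVector excl,
               NumericVector origin, double spacing, IntegerVector dims,
               List dihedrals, IntegerMatrix clash_pairs,
               double excl_penalty, double barrier, double clash_dist,
               double clash_k, double intra_weight) {
  const int n = xyz.nrow();
  GridSet g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.spacing = spacing;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.excl = LOGICAL(excl);
  for (int m = 0; m < grids.size(); ++m) {
    NumericVector gv = grids[m];
    g.maps.push_back(REAL(gv));
  }
  Topology top;
  top.map_idx.assign(map_idx.begin(), map_idx.end());
  top.heavy.resize(n);
  top.mass.assign(mass.begin(), mass.end());
  for (int a = 0; a < n; ++a) top.heavy[a] = heavy[a] ? 1 : 0;
  for (int t = 0; t < dihedrals.size(); ++t) {
    List dd = dihedrals[t];
    IntegerVector q = dd["atoms"];
    std::array<int,4> qa = { q[0]-1, q[1]-1, q[2]-1, q[3]-1 };
    top.dih_atoms.push_back(qa);
  }
  for (int p = 0; p < clash_pairs.nrow(); ++p)
    top.clash_pairs.push_back(std::make_pair(clash_pairs(p,0)-1,
                                             clash_pairs(p,1)-1));
  top.excl_penalty = excl_penalty;
  top.barrier = barrier;
  top.clash_dist = clash_dist;
  top.clash_k = clash_k;
  top.intra_weight = intra_weight;
  std::vector<double> X(3 * n);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) X[a + d * n] = xyz(a, d);
  double l = lgfe_of(X, n, g, top);
  double i = intra_of(X, n, top);
  return List::create(_["lgfe"] = l, _["intra"] = i,
                      _["energy"] = l + intra_weight * i);
}
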