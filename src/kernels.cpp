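#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
// [[Rcpp::export]]
NumericMatrix cpp_sphere_points(int n) {
  NumericMatrix pts(n, 3);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * i;
    pts(i, 0) = r * std::cos(th);
    pts(i, 1) = r * std::sin(th);
    pts(i, 2) = z;
  }
  return pts;
}

// Shrake-Rupley accessible surface area per atom.
// coord: n x 3, radii: n (vdW, Angstrom). A sample point on the inflated
// sphere of atom i is accessible if outside every neighbour's inflated sphere.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coord, NumericVector radii,
                       double probe, int n_points) {
  int n = coord.nrow();
  NumericMatrix unit = cpp_sphere_points(n_points);
  std::vector<double> ux(n_points), uy(n_points), uz(n_points);
  for (int p = 0; p < n_points; ++p) {
    ux[p] = unit(p, 0); uy[p] = unit(p, 1); uz[p] = unit(p, 2);
  }
  std::vector<double> X(n), Y(n), Z(n), R(n);
  for (int i = 0; i < n; ++i) {
    X[i] = coord(i, 0); Y[i] = coord(i, 1); Z[i] = coord(i, 2);
    R[i] = radii[i] + probe;
  }
  NumericVector out(n);
  std::vector<double> nx, ny, nz, nr2, nd2;
  nx.reserve(128); ny.reserve(128); nz.reserve(128);
  nr2.reserve(128); nd2.reserve(128);
  for (int i = 0; i < n; ++i) {
    double ri = R[i], xi = X[i], yi = Y[i], zi = Z[i];
    nx.clear(); ny.clear(); nz.clear(); nr2.clear(); nd2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = X[j] - xi, dy = Y[j] - yi, dz = Z[j] - zi;
      double lim = ri + R[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) {
        nx.push_back(dx); ny.push_back(dy); nz.push_back(dz);
        nr2.push_back(R[j] * R[j]); nd2.push_back(d2);
      }
    }
    // nearest neighbours first: earlier loop exit for buried points
    size_t m = nx.size();
    std::vector<size_t> ord(m);
    for (size_t k = 0; k < m; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(),
              [&](size_t a, size_t b) { return nd2[a] < nd2[b]; });
    std::vector<double> sx(m), sy(m), sz(m), sr2(m);
    for (size_t k = 0; k < m; ++k) {
      sx[k] = nx[ord[k]]; sy[k] = ny[ord[k]]; sz[k] = nz[ord[k]];
      sr2[k] = nr2[ord[k]];
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = ri * ux[p], py = ri * uy[p], pz = ri * uz[p];
      bool free_pt = true;
      for (size_t k = 0; k < m; ++k) {
        double dx = px - sx[k], dy = py - sy[k], dz = pz - sz[k];
        if (dx * dx + dy * dy + dz * dz < sr2[k]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[i] = (double)acc / n_points * 4.0 * M_PI * ri * ri;
  }
  return out;
}

// All index pairs (i from A, j from B) with dist(A_i, B_j) < cutoff
// (half-open interval [0, cutoff)). Returns a 2-column 1-based matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix A, NumericMatrix B, double cutoff) {
  int n = A.nrow(), m = B.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    double xi = A(i, 0), yi = A(i, 1), zi = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = B(j, 0) - xi, dy = B(j, 1) - yi, dz = B(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// Atom-atom contact counts binned by atom class. A partner atom within
// cutoff of ANY atom of a residue counts once for that residue. Pairs of
// sequence neighbours (|seqid| difference <= 1) are excluded.
// [[Rcpp::export]]
IntegerMatrix cpp_atom_contact_counts(NumericMatrix coord, IntegerVector res,
                                      IntegerVector seqid, IntegerVector cls,
                                      int n_res, int n_cls, double cutoff) {
  int n = coord.nrow();
  double c2 = cutoff * cutoff;
  IntegerMatrix out(n_res, n_cls);
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = coord(i,0); Y[i] = coord(i,1); Z[i] = coord(i,2); }
  // stamp[r*n + j]: partner atom j already counted for residue r
  std::vector<unsigned char> stamp((size_t)n_res * n, 0);
  for (int i = 0; i < n; ++i) {
    int ri = res[i] - 1;
    for (int j = 0; j < n; ++j) {
      if (res[j] == res[i]) continue;
      int ds = seqid[i] - seqid[j];
      if (ds >= -1 && ds <= 1) continue;
      double dx = X[j]-X[i], dy = Y[j]-Y[i], dz = Z[j]-Z[i];
      if (dx*dx + dy*dy + dz*dz < c2) {
        size_t key = (size_t)ri * n + j;
        if (!stamp[key]) { stamp[key] = 1; out(ri, cls[j] - 1)++; }
      }
    }
  }
  return out;
}

// Greedy fixed-backbone repack sweeps. env holds all heavy atoms; rows
// [slot, slot+len) of residue k's block are overwritten by the chosen
// candidate. Candidate coordinates are passed concatenated; cand_off[k] and
// cand_n[k] delimit residue k's candidates, each of block length len[k].
// orders is n_sweeps x n_rep of 1-based residue visit orders. Returns the
// chosen candidate index per residue and the energy trace (after
// initialisation and after each executed sweep).
// [[Rcpp::export]]
List cpp_repack(NumericMatrix env, NumericVector env_rad,
                IntegerVector env_seq,
                LogicalVector env_sc,
                IntegerVector slot, IntegerVector len,
                IntegerVector res_id,
                NumericMatrix cand_xyz, NumericVector cand_rad,
                IntegerVector cand_off, IntegerVector cand_n,
                NumericVector nlp, IntegerVector nlp_off,
                IntegerVector init_idx,
                NumericMatrix ca, IntegerMatrix orders,
                double w_st, double w_rot, double scale,
                double const_energy) {
  int m = env.nrow(), n_rep = slot.size();
  std::vector<double> X(m), Y(m), Z(m), R(m);
  for (int i = 0; i < m; ++i) {
    X[i] = env(i,0); Y[i] = env(i,1); Z[i] = env(i,2); R[i] = env_rad[i];
  }
  int nc = cand_xyz.nrow();
  std::vector<double> CX(nc), CY(nc), CZ(nc), CR(nc);
  for (int i = 0; i < nc; ++i) {
    CX[i] = cand_xyz(i,0); CY[i] = cand_xyz(i,1); CZ[i] = cand_xyz(i,2);
    CR[i] = cand_rad[i];
  }
  // neighbour lists per repackable residue: env atoms possibly in clash
  // range of any of its candidates (generous static cutoffs)
  std::vector< std::vector<int> > nb(n_rep);
  for (int k = 0; k < n_rep; ++k) {
    double cax = ca(k,0), cay = ca(k,1), caz = ca(k,2);
    for (int j = 0; j < m; ++j) {
      if (env_seq[j] == res_id[k]) continue;
      double dx = X[j]-cax, dy = Y[j]-cay, dz = Z[j]-caz;
      double d2 = dx*dx + dy*dy + dz*dz;
      bool movable = env_sc[j];
      double lim = movable ? 20.0 : 13.0;
      if (d2 < lim * lim) nb[k].push_back(j);
    }
  }
  std::vector<int> cur(n_rep);
  for (int k = 0; k < n_rep; ++k) cur[k] = init_idx[k] - 1;

  // write candidate j of residue k into its env block
  auto install = [&](int k, int j) {
    int s = slot[k] - 1, co = cand_off[k] - 1 + j * len[k];
    for (int a = 0; a < len[k]; ++a) {
      X[s+a] = CX[co+a]; Y[s+a] = CY[co+a]; Z[s+a] = CZ[co+a];
    }
  };
  for (int k = 0; k < n_rep; ++k) install(k, cur[k]);

  // clash energy of candidate j of residue k against current environment
  auto cand_e = [&](int k, int j) {
    double e = 0.0;
    int co = cand_off[k] - 1 + j * len[k];
    const std::vector<int>& nbk = nb[k];
    for (size_t t = 0; t < nbk.size(); ++t) {
      int q = nbk[t];
      double xq = X[q], yq = Y[q], zq = Z[q], rq = R[q];
      for (int a = 0; a < len[k]; ++a) {
        double lim = scale * (CR[co+a] + rq);
        double dx = CX[co+a]-xq, dy = CY[co+a]-yq, dz = CZ[co+a]-zq;
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < lim*lim) { double ov = lim - std::sqrt(d2); e += ov*ov; }
      }
    }
    return w_st * e + w_rot * nlp[nlp_off[k] - 1 + j];
  };

  // full steric over the environment (pairs with >= 1 side-chain atom,
  // different residues), for the initial trace point
  double e_st0 = 0.0;
  for (int i = 0; i < m - 1; ++i) {
    for (int j = i + 1; j < m; ++j) {
      if (env_seq[i] == env_seq[j]) continue;
      if (!env_sc[i] && !env_sc[j]) continue;
      double lim = scale * (R[i] + R[j]);
      double dx = X[j]-X[i], dy = Y[j]-Y[i], dz = Z[j]-Z[i];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < lim*lim) { double ov = lim - std::sqrt(d2); e_st0 += ov*ov; }
    }
  }
  double e_rot = 0.0;
  for (int k = 0; k < n_rep; ++k) e_rot += nlp[nlp_off[k] - 1 + cur[k]];
  double total = w_st * e_st0 + w_rot * e_rot + const_energy;
  std::vector<double> trace;
  trace.push_back(total);

  int n_sweeps = orders.nrow();
  for (int sw = 0; sw < n_sweeps; ++sw) {
    bool changed = false;
    for (int t = 0; t < n_rep; ++t) {
      int k = orders(sw, t) - 1;
      double e_cur = cand_e(k, cur[k]);
      double best_e = e_cur; int best_j = -1;
      for (int j = 0; j < cand_n[k]; ++j) {
        if (j == cur[k]) continue;
        double ej = cand_e(k, j);
        if (ej < best_e - 1e-9) { best_e = ej; best_j = j; }
      }
      if (best_j >= 0) {
        total += best_e - e_cur;   // pairs involving k counted once
        cur[k] = best_j;
        install(k, best_j);
        changed = true;
      }
    }
    trace.push_back(total);
    if (!changed) break;
  }
  return List::create(_["idx"] = IntegerVector(cur.begin(), cur.end()),
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["energy"] = total);
}

// Soft-sphere clash energy: sum over atom pairs of different residues with at
// least one side-chain atom of max(0, scale*(ri+rj) - d)^2.
// seqid encodes chain and sequence position so distinct residues differ.
// [[Rcpp::export]]
double cpp_steric_energy(NumericMatrix coord, NumericVector radii,
                         IntegerVector seqid, LogicalVector sidechain,
                         double scale) {
  int n = coord.nrow();
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double xi = coord(i, 0), yi = coord(i, 1), zi = coord(i, 2);
    for (int j = i + 1; j < n; ++j) {
      if (seqid[i] == seqid[j]) continue;
      if (!sidechain[i] && !sidechain[j]) continue;
      double lim = scale * (radii[i] + radii[j]);
      double dx = coord(j, 0) - xi, dy = coord(j, 1) - yi, dz = coord(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) {
        double ov = lim - std::sqrt(d2);
        e += ov * ov;
      }
    }
  }
  return e;
}

// Clash energy of one candidate side chain against an environment.
// Environment atoms belonging to the candidate's own residue are skipped.
// [[Rcpp::export]]
double cpp_steric_cand(NumericMatrix cand, NumericVector cand_radii,
                       int cand_seqid,
                       NumericMatrix env, NumericVector env_radii,
                       IntegerVector env_seqid, double scale) {
  double e = 0.0;
  int nc = cand.nrow(), ne = env.nrow();
  for (int j = 0; j < ne; ++j) {
    if (env_seqid[j] == cand_seqid) continue;
    double xj = env(j, 0), yj = env(j, 1), zj = env(j, 2);
    for (int i = 0; i < nc; ++i) {
      double lim = scale * (cand_radii[i] + env_radii[j]);
      double dx = cand(i, 0) - xj, dy = cand(i, 1) - yj, dz = cand(i, 2) - zj;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) {
        double ov = lim - std::sqrt(d2);
        e += ov * ov;
      }
    }
  }
  return e;
}
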