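// 3D Cellular Potts Model core: Hamiltonian tallies and Metropolis dynamics.
//
// Lattice layout: integer labels in a flat vector, axis order (z, y, x),
// index = z + nz * (y + ny * x), matching R's array layout for dim (nz,ny,nx).
// Label 0 is medium. Sites outside the box count as medium for contact and
// area terms (no-flux walls) but are never flip targets; a copy source drawn
// outside the box is a null attempt.
//
// Neighbourhood shells follow the squared-Euclidean-distance convention:
// order k includes all offsets with 0 < dz^2+dy^2+dx^2 <= k, giving
// 6 / 18 / 26 / 32 neighbours for orders 1..4.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Offsets {
  std::vector<int> dz, dy, dx;
  int n() const { return (int)dz.size(); }
};

static Offsets shell_offsets(int order) {
  Offsets o;
  int r = (int)std::floor(std::sqrt((double)order));
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      for (int c = -r; c <= r; ++c) {
        int d2 = a * a + b * b + c * c;
        if (d2 > 0 && d2 <= order) {
          o.dz.push_back(a); o.dy.push_back(b); o.dx.push_back(c);
        }
      }
  return o;
}

struct Grid {
  int nz, ny, nx;
  long n() const { return (long)nz * ny * nx; }
  bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
  long at(int z, int y, int x) const {
    return (long)z + (long)nz * ((long)y + (long)ny * x);
  }
  void coords(long i, int &z, int &y, int &x) const {
    z = (int)(i % nz);
    long rest = i / nz;
    y = (int)(rest % ny);
    x = (int)(rest / ny);
  }
};

// Full tally of per-label volume V, boundary-pair area A (contact-order
// neighbourhood), and total unlike-pair counts split into cell-cell and
// cell-medium. Each unordered site pair is counted once; pairs with one end
// outside the box are counted once per in-box end.
// [[Rcpp::export]]
List cpm_tally_cpp(IntegerVector lattice, IntegerVector dims,
                   int contact_order, int max_label) {
  Grid g{dims[0], dims[1], dims[2]};
  Offsets off = shell_offsets(contact_order);
  std::vector<double> V(max_label + 1, 0.0), A(max_label + 1, 0.0);
  double cc = 0.0, cm = 0.0;
  for (long i = 0; i < g.n(); ++i) {
    int a = lattice[i];
    if (a > 0) V[a] += 1.0;
    int z, y, x;
    g.coords(i, z, y, x);
    for (int k = 0; k < off.n(); ++k) {
      int tz = z + off.dz[k], ty = y + off.dy[k], tx = x + off.dx[k];
      if (!g.inside(tz, ty, tx)) {
        // out-of-box neighbour acts as medium; count this pair once (here)
        if (a > 0) { A[a] += 1.0; cm += 1.0; }
        continue;
      }
      long j = g.at(tz, ty, tx);
      if (j <= i) continue;  // count in-box pairs once
      int b = lattice[j];
      if (a == b) continue;
      if (a > 0) A[a] += 1.0;
      if (b > 0) A[b] += 1.0;
      if (a > 0 && b > 0) cc += 1.0; else cm += 1.0;
    }
  }
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["A"] = NumericVector(A.begin(), A.end()),
                      _["total_cc"] = cc, _["total_cm"] = cm);
}

static double hamiltonian_from(const std::vector<double> &V,
                               const std::vector<double> &A,
                               double cc, double cm,
                               const NumericVector &Vt, const NumericVector &At,
                               double lambda_V, double lambda_A,
                               double J_cc, double J_cm) {
  double H = J_cc * cc + J_cm * cm;
  int L = (int)V.size() - 1;
  for (int l = 1; l <= L; ++l) {
    if (l < Vt.size() && R_finite(Vt[l])) {
      double dv = V[l] - Vt[l];
      H += lambda_V * dv * dv;
    }
    if (l < At.size() && R_finite(At[l])) {
      double da = A[l] - At[l];
      H += lambda_A * da * da;
    }
  }
  return H;
}

// Hamiltonian recomputed from scratch (the oracle path).
// [[Rcpp::export]]
double cpm_hamiltonian_cpp(IntegerVector lattice, IntegerVector dims,
                           int contact_order, NumericVector Vt,
                           NumericVector At, double lambda_V, double lambda_A,
                           double J_cc, double J_cm) {
  int max_label = 0;
  for (long i = 0; i < (long)lattice.size(); ++i)
    if (lattice[i] > max_label) max_label = lattice[i];
  int targ_max = std::max((int)Vt.size(), (int)At.size()) - 1;
  if (targ_max > max_label) max_label = targ_max;
  List t = cpm_tally_cpp(lattice, dims, contact_order, max_label);
  NumericVector V = t["V"], A = t["A"];
  std::vector<double> Vs(V.begin(), V.end()), As(A.begin(), A.end());
  return hamiltonian_from(Vs, As, t["total_cc"], t["total_cm"], Vt, At,
                          lambda_V, lambda_A, J_cc, J_cm);
}

// Metropolis label-copy dynamics. Runs `n_attempts` site-update attempts;
// one Monte Carlo step (MCS) is `mcs_len` attempts (= lattice size in the
// standard convention). Incremental caches (V, A, contact totals, running H)
// are updated on every accepted flip.
//
// Returns the final lattice, per-attempt records (when requested), the
// running-H trace sampled at every MCS boundary, snapshots at the requested
// MCS indices, and the final caches.
// [[Rcpp::export]]
List cpm_run_cpp(IntegerVector lattice, IntegerVector dims,
                 int potts_order, int contact_order,
                 NumericVector Vt, NumericVector At,
                 double lambda_V, double lambda_A,
                 double J_cc, double J_cm, double temperature,
                 double n_attempts_d, int mcs_len,
                 IntegerVector snapshot_at, bool record_attempts) {
  if (temperature <= 0) stop("temperature must be > 0");
  Grid g{dims[0], dims[1], dims[2]};
  long N = g.n();
  long n_attempts = (long)n_attempts_d;
  Offsets potts = shell_offsets(potts_order);
  Offsets cont = shell_offsets(contact_order);

  IntegerVector lat = clone(lattice);
  int max_label = 0;
  for (long i = 0; i < N; ++i)
    if (lat[i] > max_label) max_label = lat[i];
  int targ_max = std::max((int)Vt.size(), (int)At.size()) - 1;
  if (targ_max > max_label) max_label = targ_max;

  List t0 = cpm_tally_cpp(lat, dims, contact_order, max_label);
  NumericVector V0 = t0["V"], A0 = t0["A"];
  std::vector<double> V(V0.begin(), V0.end()), A(A0.begin(), A0.end());
  double cc = t0["total_cc"], cm = t0["total_cm"];
  double H = hamiltonian_from(V, A, cc, cm, Vt, At, lambda_V, lambda_A,
                              J_cc, J_cm);

  long n_mcs = mcs_len > 0 ? n_attempts / mcs_len : 0;
  NumericVector H_trace(n_mcs + 1);
  H_trace[0] = H;
  std::vector<long> snap_at(snapshot_at.begin(), snapshot_at.end());
  List snapshots(snap_at.size());
  for (size_t s = 0; s < snap_at.size(); ++s)
    if (snap_at[s] == 0) snapshots[s] = clone(lat);

  NumericVector deltas(record_attempts ? n_attempts : 0);
  IntegerVector status(record_attempts ? n_attempts : 0);  // -1 null, 0 rej, 1 acc

  long n_acc = 0, n_null = 0;
  std::vector<int> touched;          // labels with pending dA
  std::vector<double> dA(max_label + 1, 0.0);

  for (long att = 0; att < n_attempts; ++att) {
    long s = (long)std::floor(unif_rand() * N);
    if (s >= N) s = N - 1;
    int k = (int)std::floor(unif_rand() * potts.n());
    if (k >= potts.n()) k = potts.n() - 1;
    int z, y, x;
    g.coords(s, z, y, x);
    int sz = z + potts.dz[k], sy = y + potts.dy[k], sx = x + potts.dx[k];
    bool is_null = false;
    int a = lat[s], b = -1;
    if (!g.inside(sz, sy, sx)) {
      is_null = true;  // out-of-box source: null attempt
    } else {
      b = lat[g.at(sz, sy, sx)];
      if (b == a) is_null = true;
    }
    if (is_null) {
      ++n_null;
      if (record_attempts) { deltas[att] = NA_REAL; status[att] = -1; }
    } else {
      double dH = 0.0, dcc = 0.0, dcm = 0.0;
      touched.clear();
      if (a > 0) { dA[a] = 0.0; touched.push_back(a); }
      if (b > 0 && b != a) { dA[b] = 0.0; touched.push_back(b); }
      for (int kk = 0; kk < cont.n(); ++kk) {
        int tz = z + cont.dz[kk], ty = y + cont.dy[kk], tx = x + cont.dx[kk];
        int c = 0;
        bool cell_c = false;
        if (g.inside(tz, ty, tx)) {
          c = lat[g.at(tz, ty, tx)];
          cell_c = c > 0;
        }
        if (cell_c && c != a && c != b &&
            dA[c] == 0.0 &&
            std::find(touched.begin(), touched.end(), c) == touched.end())
          touched.push_back(c);
        if (a != c) {
          if (a > 0) dA[a] -= 1.0;
          if (cell_c) dA[c] -= 1.0;
          if (a > 0 && cell_c) dcc -= 1.0; else dcm -= 1.0;
        }
        if (b != c) {
          if (b > 0) dA[b] += 1.0;
          if (cell_c) dA[c] += 1.0;
          if (b > 0 && cell_c) dcc += 1.0; else dcm += 1.0;
        }
      }
      if (a > 0 && a < Vt.size() && R_finite(Vt[a])) {
        double d0 = V[a] - Vt[a];
        dH += lambda_V * ((d0 - 1.0) * (d0 - 1.0) - d0 * d0);
      }
      if (b > 0 && b < Vt.size() && R_finite(Vt[b])) {
        double d0 = V[b] - Vt[b];
        dH += lambda_V * ((d0 + 1.0) * (d0 + 1.0) - d0 * d0);
      }
      for (int l : touched) {
        if (dA[l] != 0.0 && l < At.size() && R_finite(At[l])) {
          double d0 = A[l] - At[l];
          dH += lambda_A * ((d0 + dA[l]) * (d0 + dA[l]) - d0 * d0);
        }
      }
      dH += J_cc * dcc + J_cm * dcm;

      bool accept = dH <= 0.0 || unif_rand() < std::exp(-dH / temperature);
      if (record_attempts) { deltas[att] = dH; status[att] = accept ? 1 : 0; }
      if (accept) {
        lat[s] = b;
        if (a > 0) V[a] -= 1.0;
        if (b > 0) V[b] += 1.0;
        for (int l : touched) { A[l] += dA[l]; dA[l] = 0.0; }
        cc += dcc; cm += dcm;
        H += dH;
        ++n_acc;
      } else {
        for (int l : touched) dA[l] = 0.0;
      }
    }
    if (mcs_len > 0 && (att + 1) % mcs_len == 0) {
      long m = (att + 1) / mcs_len;
      if (m <= n_mcs) H_trace[m] = H;
      for (size_t sidx = 0; sidx < snap_at.size(); ++sidx)
        if (snap_at[sidx] == m) snapshots[sidx] = clone(lat);
    }
  }

  return List::create(
    _["lattice"] = lat,
    _["V"] = NumericVector(V.begin(), V.end()),
    _["A"] = NumericVector(A.begin(), A.end()),
    _["total_cc"] = cc, _["total_cm"] = cm,
    _["H"] = H, _["H_trace"] = H_trace,
    _["n_accepted"] = (double)n_acc, _["n_null"] = (double)n_null,
    _["snapshots"] = snapshots,
    _["deltaH"] = deltas, _["status"] = status);
}

// Number of offsets in a neighbourhood shell (exposed for tests/documentation).
// [[Rcpp::export]]
int cpm_shell_size_cpp(int order) { return shell_offsets(order).n(); }
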