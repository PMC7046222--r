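// Constrained joining dynamics for a chain of sticky hard spheres.
//
// A chain of N spheres (backbone bonds hold consecutive beads at contact)
// is compacted by repeatedly picking a random unlinked pair and pulling it
// together under hard constraints: formed links are held at their contact
// distance and overlaps between any two spheres are resolved by projecting
// the pair back to contact (SHAKE-style, propagated locally through the
// constraint network). The helper attraction is not a physical force; it
// only realizes the joining attempt.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <chrono>

using namespace Rcpp;

struct Params {
  double tol_contact  = 1e-2;  // success when gap <= tol_contact * contact distance
  double tol_overlap  = 1e-3;  // relative overlap beyond which exclusion is violated
  double tol_bond     = 1e-2;  // relative slack allowed on formed links
  double step_size    = 0.15;  // displacement per bead per step (model units)
  int    max_steps    = 0;     // resolved to 1000 * N when 0
  int    stall_window = 5;     // steps without pair-distance decrease => failure
  double stall_eps    = 5e-2;  // minimal decrease that counts as progress
};

struct Sim {
  int N = 0;
  std::vector<double> X;     // 3N coords, bead k at [3k, 3k+1, 3k+2]
  std::vector<double> r;     // bead radii (unit diameter => r = 0.5)
  std::vector<int> ba, bb;   // bond endpoints (0-based)
  std::vector<double> blen;  // bond rest length = r[a] + r[b]
  Params p;

  // Verlet neighbour list (covers every pair that can touch)
  std::vector<int> nba, nbb;
  std::vector<char> nbbond;  // pair is a formed link (cached: hot loops)
  std::vector<double> Xref;
  double skin = 0.15;
  double rmax = 0.5;

  // constraint incidence: bead -> constraint ids
  // (bond b has id b, neighbour pair q has id ba.size() + q)
  std::vector<std::vector<int> > inc;
  std::vector<char> inset;
  std::vector<int> active;

  // projection tolerances: a constraint counts as satisfied below act_tol
  // (orders below the loosest invariant tolerance, tol_overlap ~ 1e-3
  // relative on contact distances of order 1). A step whose relaxation
  // cannot push the worst violation below infeasible_tol is aborted: that
  // pull cannot proceed without breaking constraints.
  static constexpr double act_tol = 1e-5;        // skip corrections below this
  static constexpr double exit_tol = 5e-5;       // round exit: good enough
  static constexpr double infeasible_tol = 1e-3;

  // run diagnostics
  double max_bond_viol = 0.0;     // max relative deviation of a bond from contact
  double max_overlap_viol = 0.0;  // max relative overlap of any pair
  long long n_steps = 0;
  long long n_corrections = 0;
  int n_rank_tests = 0;
  double t_cg = 0, t_relax = 0, t_rank = 0;  // seconds, coarse attribution
  static double now() {
    return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
  }
  bool check_every_step = false;

  double d2(int i, int j) const {
    const double dx = X[3*i] - X[3*j], dy = X[3*i+1] - X[3*j+1], dz = X[3*i+2] - X[3*j+2];
    return dx*dx + dy*dy + dz*dz;
  }
  double dist(int i, int j) const { return std::sqrt(d2(i, j)); }

  double cutoff() const { return 2.0 * rmax + skin; }

  static long long cell_key(int cx, int cy, int cz) {
    const long long M = 1 << 20, K = 1LL << 21;
    return ((cx + M) * K + (cy + M)) * K + (cz + M);
  }

  void rebuild_incidence() {
    inc.assign(N, std::vector<int>());
    const size_t B = ba.size();
    for (size_t b = 0; b < B; ++b) {
      inc[ba[b]].push_back((int)b);
      inc[bb[b]].push_back((int)b);
    }
    for (size_t q = 0; q < nba.size(); ++q) {
      inc[nba[q]].push_back((int)(B + q));
      inc[nbb[q]].push_back((int)(B + q));
    }
    inset.assign(B + nba.size(), 0);
    active.clear();
  }

  void build_nb() {
    nba.clear(); nbb.clear();
    const double cut = cutoff(), cut2 = cut * cut, inv = 1.0 / cut;
    std::unordered_map<long long, std::vector<int> > cells;
    cells.reserve(2 * N);
    std::vector<int> cx(N), cy(N), cz(N);
    for (int i = 0; i < N; ++i) {
      cx[i] = (int)std::floor(X[3*i]   * inv);
      cy[i] = (int)std::floor(X[3*i+1] * inv);
      cz[i] = (int)std::floor(X[3*i+2] * inv);
      cells[cell_key(cx[i], cy[i], cz[i])].push_back(i);
    }
    for (int i = 0; i < N; ++i) {
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay)
          for (int az = -1; az <= 1; ++az) {
            std::unordered_map<long long, std::vector<int> >::const_iterator it =
              cells.find(cell_key(cx[i] + ax, cy[i] + ay, cz[i] + az));
            if (it == cells.end()) continue;
            const std::vector<int>& bucket = it->second;
            for (size_t q = 0; q < bucket.size(); ++q) {
              int j = bucket[q];
              if (j > i && d2(i, j) < cut2) { nba.push_back(i); nbb.push_back(j); }
            }
          }
    }
    Xref = X;
    nbbond.resize(nba.size());
    for (size_t q = 0; q < nba.size(); ++q)
      nbbond[q] = bondset.count(pairkey(nba[q], nbb[q])) ? 1 : 0;
    rebuild_incidence();
  }

  void add_bond(int i, int j) {
    ba.push_back(i); bb.push_back(j); blen.push_back(r[i] + r[j]);
    bondset.insert(pairkey(i, j));
  }

  double max_disp2() const {
    double m = 0;
    for (int i = 0; i < 3 * N; i += 3) {
      const double dx = X[i] - Xref[i], dy = X[i+1] - Xref[i+1], dz = X[i+2] - Xref[i+2];
      const double s = dx*dx + dy*dy + dz*dz;
      if (s > m) m = s;
    }
    return m;
  }

  void maybe_rebuild() {
    const double h = 0.5 * skin;
    if (max_disp2() > h * h) build_nb();
  }

  void activate_bead(int bead) {
    const std::vector<int>& cs = inc[bead];
    for (size_t k = 0; k < cs.size(); ++k)
      if (!inset[cs[k]]) { inset[cs[k]] = 1; active.push_back(cs[k]); }
  }

  // correct constraint c if violated; returns its violation magnitude
  // before correction (0 when satisfied)
  double correct(int c) {
    const size_t B = ba.size();
    int i, j; double L; bool is_bond;
    if ((size_t)c < B) { i = ba[c]; j = bb[c]; L = blen[c]; is_bond = true; }
    else { const size_t q = c - B; i = nba[q]; j = nbb[q]; L = r[i] + r[j]; is_bond = false; }
    double dx = X[3*j] - X[3*i], dy = X[3*j+1] - X[3*i+1], dz = X[3*j+2] - X[3*i+2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d < 1e-12) { dx = L; dy = 0; dz = 0; d = 1e-12; }
    const double diff = d - L;
    // bonds are held at contact from both sides; plain pairs only pushed apart
    const double viol = is_bond ? std::fabs(diff) : (diff < 0 ? -diff : 0.0);
    if (viol <= act_tol) return viol;
    const double cfac = 0.5 * diff / d;
    X[3*i]   += cfac * dx; X[3*i+1] += cfac * dy; X[3*i+2] += cfac * dz;
    X[3*j]   -= cfac * dx; X[3*j+1] -= cfac * dy; X[3*j+2] -= cfac * dz;
    ++n_corrections;
    activate_bead(i);
    activate_bead(j);
    return viol;
  }

  // Gauss-Seidel rounds over a locally grown active constraint set: start
  // from the constraints incident to the seed beads, let each correction
  // pull its neighbourhood into the set, and drop constraints once they
  // are satisfied (they return when an incident bead moves again), so the
  // cost tracks the correction wavefront rather than the whole structure.
  // Returns 0 when fully converged, otherwise the worst violation seen in
  // the final round.
  double relax(const std::vector<int>& seed_beads, int max_rounds = 600,
               bool patient = false) {
    const double t0 = now();
    active.clear();
    for (size_t s = 0; s < seed_beads.size(); ++s) activate_bead(seed_beads[s]);
    const long long budget =
      n_corrections + 200LL * (long long)(ba.size() + nba.size()) + 10000;
    double maxv = 0.0, prev = std::numeric_limits<double>::max();
    for (int round = 0; round < max_rounds && !active.empty(); ++round) {
      maxv = 0.0;
      size_t write = 0;
      for (size_t idx = 0; idx < active.size(); ++idx) {  // grows during round
        const int c = active[idx];
        const double v = correct(c);
        if (v > maxv) maxv = v;
        if (v > act_tol) active[write++] = c;
        else inset[c] = 0;
      }
      active.resize(write);
      if (maxv < exit_tol) break;
      // conflicting constraints can ping-pong at a fixed small amplitude;
      // genuine transport across a long chain decays slowly but steadily,
      // so only a near-flat plateau counts as stalled
      if (!patient && round >= 30 && maxv > 0.99 * prev) break;
      prev = maxv;
      if (n_corrections > budget) break;
    }
    for (size_t k = 0; k < active.size(); ++k) inset[active[k]] = 0;
    const double out = active.empty() ? 0.0 : maxv;
    active.clear();
    t_relax += now() - t0;
    return out;
  }

  double relax_all(int max_rounds = 600, bool patient = false) {
    std::vector<int> all(N);
    for (int i = 0; i < N; ++i) all[i] = i;
    return relax(all, max_rounds, patient);
  }

  // push every overlapping non-bonded pair back to exact contact. The
  // displacements are at most the overlap depth, an order of magnitude
  // below the bond tolerance, so the perturbation of the bond network
  // needs no follow-up correction (the bond springs re-settle it).
  // Returns the worst relative overlap remaining after the sweeps.
  double t_sweep = 0;
  double overlap_sweeps(int max_passes = 10) {
    const double ts0 = now();
    double worst = 0.0;
    for (int pass = 0; pass < max_passes; ++pass) {
      worst = 0.0;
      for (size_t q = 0; q < nba.size(); ++q) {
        if (nbbond[q]) continue;
        const int a = nba[q], c = nbb[q];
        const double L = r[a] + r[c];
        double dx = X[3*c] - X[3*a], dy = X[3*c+1] - X[3*a+1], dz = X[3*c+2] - X[3*a+2];
        double d = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (d >= L) continue;
        if (d < 1e-12) { dx = L; dy = 0; dz = 0; d = 1e-12; }
        const double rel = (L - d) / L;
        if (rel > worst) worst = rel;
        const double cfac = 0.5 * (d - L) / d;  // split the push equally
        X[3*a]   += cfac * dx; X[3*a+1] += cfac * dy; X[3*a+2] += cfac * dz;
        X[3*c]   -= cfac * dx; X[3*c+1] -= cfac * dy; X[3*c+2] -= cfac * dz;
      }
      if (worst < 0.5 * p.tol_overlap) break;
    }
    t_sweep += now() - ts0;
    return worst;
  }

  // project outlier links (collision spikes) back to contact; the bulk of
  // the load-bearing strain sits well inside half the bond tolerance and
  // is left alone
  void bond_spike_repair(int passes = 3) {
    for (int pass = 0; pass < passes; ++pass)
      for (size_t b = 0; b < ba.size(); ++b) {
        const int a = ba[b], c = bb[b];
        const double L = blen[b];
        double dx = X[3*c] - X[3*a], dy = X[3*c+1] - X[3*a+1], dz = X[3*c+2] - X[3*a+2];
        const double d = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (std::fabs(d - L) <= 0.5 * p.tol_bond * L || d < 1e-12) continue;
        const double cf = 0.5 * (d - L) / d;
        X[3*a]   += cf * dx; X[3*a+1] += cf * dy; X[3*a+2] += cf * dz;
        X[3*c]   -= cf * dx; X[3*c+1] -= cf * dy; X[3*c+2] -= cf * dz;
      }
  }

  // one-sided settle: push every compressed pair (bonded or not) back to
  // contact, pull in only links stretched beyond half their tolerance
  void final_settle(int max_passes = 300) {
    for (int pass = 0; pass < max_passes; ++pass) {
      // links stretched beyond half their tolerance are pulled in first...
      for (size_t b = 0; b < ba.size(); ++b) {
        const int a = ba[b], c = bb[b];
        const double Lhi = blen[b] * (1.0 + 0.5 * p.tol_bond);
        double dx = X[3*c] - X[3*a], dy = X[3*c+1] - X[3*a+1], dz = X[3*c+2] - X[3*a+2];
        double d = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (d <= Lhi) continue;
        const double cfac = 0.5 * (d - Lhi) / d;
        X[3*a]   += cfac * dx; X[3*a+1] += cfac * dy; X[3*a+2] += cfac * dz;
        X[3*c]   -= cfac * dx; X[3*c+1] -= cfac * dy; X[3*c+2] -= cfac * dz;
      }
      // ...then every compressed pair (bonded or not) is pushed back to
      // contact; the pass order leaves the state exclusion-clean, so only
      // the compression needs to converge
      double worst = 0.0;
      for (size_t q = 0; q < nba.size(); ++q) {
        const int a = nba[q], c = nbb[q];
        const double L = r[a] + r[c];
        double dx = X[3*c] - X[3*a], dy = X[3*c+1] - X[3*a+1], dz = X[3*c+2] - X[3*a+2];
        double d = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (d >= L) continue;
        if (d < 1e-12) { dx = L; dy = 0; dz = 0; d = 1e-12; }
        const double rel = (L - d) / L;
        if (rel > worst) worst = rel;
        const double cfac = 0.5 * (d - L) / d;
        X[3*a]   += cfac * dx; X[3*a+1] += cfac * dy; X[3*a+2] += cfac * dz;
        X[3*c]   -= cfac * dx; X[3*c+1] -= cfac * dy; X[3*c+2] -= cfac * dz;
      }
      maybe_rebuild();
      if (worst < 0.25 * p.tol_overlap) break;
    }
  }

  int bv_site = 0;
  void record_violations(int site = 0) {
    double mb = 0, mo = 0;
    for (size_t b = 0; b < ba.size(); ++b) {
      const double rel = std::fabs(dist(ba[b], bb[b]) - blen[b]) / blen[b];
      if (rel > mb) mb = rel;
    }
    for (size_t q = 0; q < nba.size(); ++q) {
      // bonded pairs are held at contact by the (looser) bond tolerance;
      // the exclusion tolerance governs all other pairs
      if (nbbond[q]) continue;
      const int i = nba[q], j = nbb[q];
      const double L = r[i] + r[j], d = dist(i, j);
      if (d < L) { const double rel = (L - d) / L; if (rel > mo) mo = rel; }
    }
    if (mb > max_bond_viol) { max_bond_viol = mb; bv_site = site; }
    if (mo > max_overlap_viol) max_overlap_viol = mo;
  }

  // --- soft-sphere joining dynamics (FIRE) -------------------------------
  // An attempt pulls the selected pair together with a constant helper
  // force while stiff harmonic springs hold every formed link at its
  // contact length and a one-sided harmonic repulsion resolves overlaps.
  // The over-damped motion is integrated with FIRE (fast inertial
  // relaxation), whose inertia lets the pulled spheres roll around
  // obstacles instead of stopping at the first dead end. None of these
  // forces is meant to be physical; they only realize the joining attempt.
  // Every `chk_iters` integrator iterations the configuration is polished
  // back onto the constraint set (relax) and counts as one accepted
  // dynamics step for the invariants and the stall bookkeeping.

  static constexpr double k_bond = 600.0;   // bond spring stiffness
  static constexpr double k_rep  = 300.0;   // guidance repulsion
  static constexpr double f_pull = 1.0;     // helper pull per bead
  static constexpr double dt0 = 0.004, dt_max = 0.014, v_cap = 0.15;
  static constexpr int chk_iters = 24;

  std::vector<double> vel_, frc_;
  std::mt19937 vrng{12345u};  // per-attempt velocity seeds (re-seeded per run)
  long long pairkey(int a, int b) const {
    return (long long)std::min(a, b) * (long long)N + (long long)std::max(a, b);
  }
  std::unordered_set<long long> bondset;

  void compute_forces(int i, int j) {
    std::fill(frc_.begin(), frc_.end(), 0.0);
    const double d = (i >= 0) ? dist(i, j) : 0.0;
    if (i >= 0 && d > 1e-12) {
      const double ux = (X[3*j] - X[3*i]) / d, uy = (X[3*j+1] - X[3*i+1]) / d,
                   uz = (X[3*j+2] - X[3*i+2]) / d;
      frc_[3*i]   += f_pull * ux; frc_[3*i+1] += f_pull * uy; frc_[3*i+2] += f_pull * uz;
      frc_[3*j]   -= f_pull * ux; frc_[3*j+1] -= f_pull * uy; frc_[3*j+2] -= f_pull * uz;
    }
    for (size_t b = 0; b < ba.size(); ++b) {
      const int a = ba[b], c = bb[b];
      const double L = blen[b];
      const double dx = X[3*c] - X[3*a], dy = X[3*c+1] - X[3*a+1], dz = X[3*c+2] - X[3*a+2];
      const double dd = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (dd < 1e-12) continue;
      const double f = k_bond * (dd - L) / dd;  // toward rest length
      frc_[3*a]   += f * dx; frc_[3*a+1] += f * dy; frc_[3*a+2] += f * dz;
      frc_[3*c]   -= f * dx; frc_[3*c+1] -= f * dy; frc_[3*c+2] -= f * dz;
    }
    for (size_t q = 0; q < nba.size(); ++q) {
      if (nbbond[q]) continue;  // handled by its bond spring
      const int a = nba[q], c = nbb[q];
      const double L = r[a] + r[c];
      const double dx = X[3*c] - X[3*a], dy = X[3*c+1] - X[3*a+1], dz = X[3*c+2] - X[3*a+2];
      const double d2v = dx*dx + dy*dy + dz*dz;
      if (d2v >= L * L) continue;
      const double dd = std::sqrt(std::max(d2v, 1e-24));
      const double f = -k_rep * (L - dd) / dd;     // push apart
      frc_[3*a]   += f * dx; frc_[3*a+1] += f * dy; frc_[3*a+2] += f * dz;
      frc_[3*c]   -= f * dx; frc_[3*c+1] -= f * dy; frc_[3*c+2] -= f * dz;
    }
  }

  // let the springs settle with the helper pull switched off (used after a
  // successful join so the new state carries no elastic load)
  void quench(int iters = 80) {
    vel_.assign(3 * N, 0.0);
    frc_.resize(3 * N);
    double dt = dt0, alpha = 0.1;
    int n_pos = 0;
    for (int it = 0; it < iters; ++it) {
      compute_forces(-1, -1);
      double P = 0, v2 = 0, f2 = 0;
      for (int k = 0; k < 3 * N; ++k) {
        P += frc_[k] * vel_[k];
        v2 += vel_[k] * vel_[k];
        f2 += frc_[k] * frc_[k];
      }
      if (P > 0) {
        if (++n_pos > 5) { dt = std::min(dt * 1.1, dt_max); alpha *= 0.99; }
      } else {
        n_pos = 0; dt *= 0.5; alpha = 0.1;
        std::fill(vel_.begin(), vel_.end(), 0.0);
      }
      const double vnorm = std::sqrt(v2), fnorm = std::sqrt(std::max(f2, 1e-30));
      const double mix = alpha * vnorm / fnorm;
      for (int k = 0; k < 3 * N; ++k)
        vel_[k] = (1.0 - alpha) * vel_[k] + mix * frc_[k] + dt * frc_[k];
      for (int k = 0; k < 3 * N; ++k) X[k] += dt * vel_[k];
      if ((it & 15) == 15) maybe_rebuild();
    }
    maybe_rebuild();
  }

  // One joining attempt on pair (i, j). On success the bond is added; on
  // failure the configuration is rolled back (failure is side-effect-free).
  // steps_used reports the accepted dynamics steps (checkpoints) consumed.
  bool attempt(int i, int j, int* steps_used = 0, bool patient = false) {
    const std::vector<double> Xsave = X;
    const double L = r[i] + r[j];
    const double succ_d = L * (1.0 + p.tol_contact);
    const double d0 = dist(i, j);
    double best = d0;
    int since = 0, used = 0;
    int max_steps = p.max_steps > 0 ? p.max_steps : std::max(6 * N, 150);
    if (patient) max_steps *= 4;
    // while the chain is still nearly straight it folds through slowly
    // buckling hinges whose start-up time depends on the seeded jitter;
    // early attempts therefore get a generous horizon (the caller flags
    // them), later ones the standard one
    // saddle escape (a flat or collinear closing mode) amplifies the seeded
    // kick exponentially while the pair distance changes only quadratically
    // in the mode amplitude, so patient attempts need a long horizon
    const int stall_win = patient ? std::max(p.stall_window, 300) : p.stall_window;
    bool ok = false;
    // a tiny random positional kick on the pulled pair breaks flat or
    // collinear saddle configurations in which the helper pull has no
    // component along the closing mode (a velocity kick would not survive
    // the FIRE brake); failure rolls it back, and the per-run seeding
    // keeps it deterministic
    std::uniform_real_distribution<double> kick(-0.02, 0.02);
    for (int c = 0; c < 3; ++c) { X[3*i + c] += kick(vrng); X[3*j + c] += kick(vrng); }
    vel_.assign(3 * N, 0.0);
    frc_.resize(3 * N);
    double dt = dt0, alpha = 0.1;
    int n_pos = 0;
    for (int s = 0; s < max_steps && !ok; ++s) {
      const double tf0 = now();
      for (int it = 0; it < chk_iters; ++it) {
        if (dist(i, j) <= succ_d) { ok = true; break; }
        compute_forces(i, j);
        // FIRE: accelerate while the power is positive, brake otherwise
        double P = 0, v2 = 0, f2 = 0;
        for (int k = 0; k < 3 * N; ++k) {
          P += frc_[k] * vel_[k];
          v2 += vel_[k] * vel_[k];
          f2 += frc_[k] * frc_[k];
        }
        if (P > 0) {
          if (++n_pos > 5) { dt = std::min(dt * 1.1, dt_max); alpha *= 0.99; }
        } else {
          // partial brake: a residue of the velocity survives so that the
          // slowly accumulating motion along a weakly unstable (saddle)
          // mode is not erased by every in-plane force oscillation
          n_pos = 0; dt *= 0.5; alpha = 0.1;
          for (int k = 0; k < 3 * N; ++k) vel_[k] *= 0.25;
          v2 *= 0.0625;
        }
        const double vnorm = std::sqrt(v2), fnorm = std::sqrt(std::max(f2, 1e-30));
        const double mix = alpha * vnorm / fnorm;
        for (int k = 0; k < 3 * N; ++k)
          vel_[k] = (1.0 - alpha) * vel_[k] + mix * frc_[k] + dt * frc_[k];
        // cap per-bead speed (keeps collision transients shallow)
        double vmax2 = 0;
        for (int k = 0; k < N; ++k) {
          const double s2 = vel_[3*k]*vel_[3*k] + vel_[3*k+1]*vel_[3*k+1] +
                            vel_[3*k+2]*vel_[3*k+2];
          if (s2 > v_cap * v_cap) {
            const double sc = v_cap / std::sqrt(s2);
            vel_[3*k] *= sc; vel_[3*k+1] *= sc; vel_[3*k+2] *= sc;
          } else if (s2 > vmax2) vmax2 = s2;
        }
        // a collective drag moves at a speed inversely proportional to the
        // number of dragged beads; renormalizing the fastest bead to the
        // cap keeps the approach rate of long pulls independent of chain
        // length (without it, global folds stall on long chains and the
        // aggregates grow as sausages instead of globules)
        // boost only sustained coherent drags (power positive for many
        // consecutive iterations); contact rattling flips the power sign
        // and is never amplified
        if (n_pos > 10 && vmax2 > 1e-18) {
          const double vref = 0.5 * v_cap;
          if (vmax2 < vref * vref) {
            const double sc = std::min(3.0, vref / std::sqrt(vmax2));
            for (int k = 0; k < 3 * N; ++k) vel_[k] *= sc;
          }
        }
        for (int k = 0; k < 3 * N; ++k) X[k] += dt * vel_[k];
        // displacement per iteration is bounded by v_cap*dt, far below the
        // Verlet skin; checking the list once per checkpoint is safe
      }
      t_cg += now() - tf0;  // reuse the t_cg slot for the FIRE block
      maybe_rebuild();
      // checkpoint: overlap pushes restore volume exclusion exactly; the
      // bond springs keep the (10x looser) bond tolerance on their own,
      // except for occasional collision spikes, which are projected out
      // (outlier bonds only, so the load-bearing strain survives; the
      // final overlap pass keeps exclusion exact afterwards)
      overlap_sweeps();
      bond_spike_repair();
      const double worst_ov = overlap_sweeps();
      ++n_steps;
      ++used;
      if (!ok && worst_ov > p.tol_overlap) break;  // wedged: exclusion untenable
      if (check_every_step) record_violations(1);
      if (ok) break;
      const double dn = dist(i, j);
      if (dn < best - p.stall_eps) { best = dn; since = 0; }
      else if (++since >= stall_win) break;
      // blocked pairs do not move at all; give the drag wave of a long
      // pull time to develop before judging
      if (!patient && used == 6 && dn > d0 - 2e-3) break;
    }
    if (steps_used) *steps_used = used;
    if (ok) {
      add_bond(i, j);
      build_nb();  // constraint ids shift; rebuild incidence with the new bond
      quench();
      bond_spike_repair();
      overlap_sweeps();
      maybe_rebuild();
      if (check_every_step) record_violations(2);
      return true;
    }
    X = Xsave;  // pre-attempt state was exactly feasible; nothing to polish
    maybe_rebuild();
    return false;
  }

  // First-order (infinitesimal) rigidity of the bond framework. When rigid,
  // no continuous motion respecting the formed links can change any pair
  // distance, so pairs well away from contact are geometrically incapable
  // of connecting. Conservative: near-zero singular values count as flexes.
  bool first_order_rigid() {
    const double t0 = now();
    if (N < 3) { t_rank += now() - t0; return true; }
    const int E = (int)ba.size();
    const int dof = 3 * N - 6;
    if (E < dof) return false;
    ++n_rank_tests;
    arma::mat R(E, 3 * N, arma::fill::zeros);
    for (int b = 0; b < E; ++b) {
      const int i = ba[b], j = bb[b];
      for (int c = 0; c < 3; ++c) {
        const double v = X[3*i+c] - X[3*j+c];
        R(b, 3*i+c) = v;
        R(b, 3*j+c) = -v;
      }
    }
    arma::vec sv;
    if (!arma::svd(sv, R)) return false;
    const double thr = 1e-4 * sv.max();
    const int rank = (int)arma::sum(sv > thr);
    t_rank += now() - t0;
    return rank >= dof;
  }
};

static Params params_from_list(const List& par) {
  Params p;
  p.tol_contact  = as<double>(par["tol_contact"]);
  p.tol_overlap  = as<double>(par["tol_overlap"]);
  p.tol_bond     = as<double>(par["tol_bond"]);
  p.step_size    = as<double>(par["step_size"]);
  p.max_steps    = as<int>(par["max_steps_per_attempt"]);
  p.stall_window = as<int>(par["stall_window"]);
  p.stall_eps    = as<double>(par["stall_eps"]);
  return p;
}

static NumericMatrix positions_matrix(const Sim& s) {
  NumericMatrix out(s.N, 3);
  for (int i = 0; i < s.N; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = s.X[3*i + c];
  return out;
}

// [[Rcpp::export]]
List cpp_run_folding(int N, double a, int seed, List par,
                     IntegerVector snapshot_l,
                     bool check_every_step, bool record_attempts) {
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  Sim s;
  s.vrng.seed((uint32_t)seed ^ 0x9e3779b9u);
  s.N = N;
  s.p = params_from_list(par);
  s.check_every_step = check_every_step;

  // diameters uniform on [1 - a, 1 + a] (mean diameter 1); a = 0 => all unit
  s.r.resize(N);
  for (int i = 0; i < N; ++i) {
    const double diam = (a > 0) ? (1.0 - a + 2.0 * a * U(rng)) : 1.0;
    s.r[i] = 0.5 * diam;
  }
  s.rmax = *std::max_element(s.r.begin(), s.r.end());

  // straight chain along x, consecutive beads touching
  s.X.assign(3 * N, 0.0);
  double x = 0.0;
  for (int i = 1; i < N; ++i) { x += s.r[i-1] + s.r[i]; s.X[3*i] = x; }
  for (int i = 0; i + 1 < N; ++i) s.add_bond(i, i + 1);

  // tiny jitter breaks the collinear degeneracy (all helper forces would
  // otherwise stay on the chain axis); bonds re-projected to contact after
  const double jit = 5e-2;
  for (int k = 0; k < 3 * N; ++k) s.X[k] += jit * (2.0 * U(rng) - 1.0);
  s.build_nb();
  // the springs settle the jitter locally (no long-range transport is
  // needed), after which the exact projection converges immediately
  s.quench(300);
  s.relax_all();
  s.overlap_sweeps();

  // candidate pairs: all non-backbone, non-linked pairs
  std::vector<int> pi, pj;
  for (int i = 0; i < N; ++i)
    for (int j = i + 2; j < N; ++j) { pi.push_back(i); pj.push_back(j); }
  const int M = (int)pi.size();
  std::vector<int> status(M, 0);  // 0 open, 1 marked failed, 2 linked
  std::vector<int> open;
  open.reserve(M);
  for (int m = 0; m < M; ++m) open.push_back(m);

  std::vector<int> Ai, Aj, Aout, Al, Asteps;
  std::set<int> snapset(snapshot_l.begin(), snapshot_l.end());
  List snapshots;
  int l = 0;
  if (snapset.count(0)) {
    snapshots.push_back(List::create(_["l"] = 0, _["positions"] = positions_matrix(s)));
  }

  const int base_interval = 40;
  int fail_streak = 0, interval = base_interval;

  // clear failure marks (rebuild the open set) after any success
  #define RESET_MARKS() do { \
    open.clear(); \
    for (int m2 = 0; m2 < M; ++m2) { if (status[m2] == 1) status[m2] = 0; \
                                     if (status[m2] == 0) open.push_back(m2); } \
  } while (0)

  #define RECORD(ii, jj, ok, st) do { if (record_attempts) { \
    Ai.push_back(ii); Aj.push_back(jj); Aout.push_back((ok) ? 1 : 0); \
    Al.push_back(l); Asteps.push_back(st); } } while (0)

  bool done = open.empty();
  while (!done) {
    std::uniform_int_distribution<int> pick(0, (int)open.size() - 1);
    const int oi = pick(rng);
    const int m = open[oi];
    int used = 0;
    const bool ok = s.attempt(pi[m], pj[m], &used, l < 5);
    if (ok) {
      status[m] = 2;
      ++l;
      RECORD(pi[m], pj[m], true, used);
      if (snapset.count(l)) {
        snapshots.push_back(List::create(_["l"] = l, _["positions"] = positions_matrix(s)));
      }
      RESET_MARKS();
      fail_streak = 0;
      interval = base_interval;
    } else {
      status[m] = 1;
      RECORD(pi[m], pj[m], false, used);
      open[oi] = open.back();
      open.pop_back();
      ++fail_streak;
    }
    if (open.empty()) break;

    if (fail_streak >= interval) {
      fail_streak = 0;
      if (s.first_order_rigid()) {
        // rigid: sweep the remaining unlinked pairs, nearest gap first;
        // only near pairs (slack of the held links could still admit them)
        // get a dynamics attempt, the rest are provably incapable
        std::vector<std::pair<double, int> > rem;
        for (int m2 = 0; m2 < M; ++m2)
          if (status[m2] != 2)
            rem.push_back(std::make_pair(
              s.dist(pi[m2], pj[m2]) - (s.r[pi[m2]] + s.r[pj[m2]]), m2));
        std::sort(rem.begin(), rem.end());
        bool any_success = false;
        for (size_t q = 0; q < rem.size(); ++q) {
          const int m2 = rem[q].second;
          const int i = pi[m2], j = pj[m2];
          const double L = s.r[i] + s.r[j];
          const double gap = s.dist(i, j) - L;
          if (gap <= 0.1 * L) {
            int used2 = 0;
            const bool ok2 = s.attempt(i, j, &used2);
            if (ok2) {
              status[m2] = 2;
              ++l;
              RECORD(i, j, true, used2);
              if (snapset.count(l)) {
                snapshots.push_back(List::create(_["l"] = l, _["positions"] = positions_matrix(s)));
              }
              any_success = true;
            } else {
              status[m2] = 1;
              RECORD(i, j, false, used2);
            }
          } else {
            status[m2] = 1;
            RECORD(i, j, false, 0);
          }
        }
        if (!any_success) {
          done = true;  // every unlinked pair marked failed
        } else {
          RESET_MARKS();
          done = open.empty();
        }
      } else {
        interval = std::min(interval * 2, 5120);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  #undef RESET_MARKS
  #undef RECORD

  // settle the finished aggregate: drain elastic strain, then one-sided
  // projection onto the feasible set (no pair compressed; links may carry
  // a little stretch within their tolerance, which avoids fighting the
  // frustration of over-braced contact networks)
  s.quench(200);
  s.final_settle();
  s.build_nb();
  s.record_violations(3);

  const int E = (int)s.ba.size();
  IntegerMatrix edges(E, 2);
  for (int b = 0; b < E; ++b) { edges(b, 0) = s.ba[b] + 1; edges(b, 1) = s.bb[b] + 1; }

  DataFrame attempts = DataFrame::create(
    _["i"] = IntegerVector(Ai.begin(), Ai.end()),
    _["j"] = IntegerVector(Aj.begin(), Aj.end()),
    _["success"] = LogicalVector(Aout.begin(), Aout.end()),
    _["l"] = IntegerVector(Al.begin(), Al.end()),
    _["steps"] = IntegerVector(Asteps.begin(), Asteps.end()));
  // shift to 1-based node ids for R
  if (record_attempts && Ai.size() > 0) {
    IntegerVector ii = attempts["i"], jj = attempts["j"];
    for (R_xlen_t k = 0; k < ii.size(); ++k) { ii[k] += 1; jj[k] += 1; }
  }

  return List::create(
    _["positions"] = positions_matrix(s),
    _["radii"] = NumericVector(s.r.begin(), s.r.end()),
    _["edges"] = edges,
    _["l"] = l,
    _["attempts"] = attempts,
    _["snapshots"] = snapshots,
    _["diagnostics"] = List::create(
      _["max_bond_violation"] = s.max_bond_viol,
      _["max_overlap_violation"] = s.max_overlap_viol,
      _["n_steps"] = (double)s.n_steps,
      _["bv_site"] = s.bv_site,
      _["n_corrections"] = (double)s.n_corrections,
      _["n_rigidity_tests"] = s.n_rank_tests,
      _["t_cg"] = s.t_cg, _["t_relax"] = s.t_relax, _["t_rank"] = s.t_rank,
      _["t_sweep"] = s.t_sweep));
}

// [[Rcpp::export]]
List cpp_attempt_link(NumericMatrix positions, NumericVector radii,
                      IntegerMatrix edges, int i, int j, List par,
                      bool check_every_step) {
  const int N = positions.nrow();
  Sim s;
  s.N = N;
  s.p = params_from_list(par);
  s.check_every_step = check_every_step;
  s.X.resize(3 * N);
  for (int k = 0; k < N; ++k)
    for (int c = 0; c < 3; ++c) s.X[3*k + c] = positions(k, c);
  s.r.assign(radii.begin(), radii.end());
  s.rmax = *std::max_element(s.r.begin(), s.r.end());
  for (int b = 0; b < edges.nrow(); ++b) s.add_bond(edges(b, 0) - 1, edges(b, 1) - 1);
  s.build_nb();

  int used = 0;
  const bool ok = s.attempt(i - 1, j - 1, &used, true);
  return List::create(
    _["success"] = ok,
    _["positions"] = positions_matrix(s),
    _["diagnostics"] = List::create(
      _["max_bond_violation"] = s.max_bond_viol,
      _["max_overlap_violation"] = s.max_overlap_viol,
      _["n_steps"] = (double)s.n_steps,
      _["steps_used"] = used));
}
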