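#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rejection-free (n-fold way) KMC core for lattice self-assembly.
//
// Conventions (shared with the R reference implementation, see R/moves.R):
//  - particles are labelled 1..N; positions are 0-based (row, col) on an
//    L x L board with hard walls; internal states are 1..M.
//  - pair energy J(a,b,sa,sb) = Jw + (Js-Jw)/2 * (I[sa](a,b) + I[sb](a,b)),
//    energies in k_BT (k_BT == 1).
//  - move ordering: 4N translations first (particle-major, direction-minor,
//    directions up/down/left/right), then (M-1)N state switches
//    (particle-major, candidate state ascending, skipping the current one).
//  - rate laws: 0 = symmetric barrier r0*exp(-dE/2);
//               1 = Metropolis r0*min(1, exp(-dE)).
//    Switch moves carry the prefactor 4*r0/(M-1) instead of r0.
//  - RNG draw order per step: u (move selection), then u' (waiting time,
//    dt = -log(u')/Q).  Uses R's RNG stream so set.seed() governs runs.
//  - distance to target m: ordered-pair Hamming distance between the board
//    adjacency matrix and I[m], plus the count of particles with state != m.

static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

struct Sim {
  int N, L, M;
  double Js, Jw, r0, half;
  int rate_law;
  std::vector<int> prow, pcol, pstate;    // per particle
  std::vector<int> grid;                  // L*L, 0 empty else particle id 1..N
  std::vector<const int*> I;              // M pointers into targets (N*N, col-major)
  double E;
  std::vector<long long> Amis, Smis;      // per-target distance components

  inline int tg(int m, int a, int b) const { return I[m][a + b * N]; }

  inline double pairJ(int a, int b, int sa, int sb) const {
    return Jw + half * (tg(sa - 1, a, b) + tg(sb - 1, a, b));
  }

  inline double ratef(double dE) const {
    if (rate_law == 0) return std::exp(-0.5 * dE);
    return dE <= 0.0 ? 1.0 : std::exp(-dE);
  }

  // sum of pair energies between particle a (in state sa) and occupants of
  // tiles adjacent to (r, c), excluding particle `excl` (1-based, 0 = none)
  inline double bondSum(int a, int sa, int r, int c, int excl) const {
    double s = 0.0;
    for (int d = 0; d < 4; ++d) {
      int nr = r + DR[d], nc = c + DC[d];
      if (nr < 0 || nr >= L || nc < 0 || nc >= L) continue;
      int occ = grid[nr * L + nc];
      if (occ == 0 || occ == a + 1 || occ == excl) continue;
      s += pairJ(a, occ - 1, sa, pstate[occ - 1]);
    }
    return s;
  }

  double fullEnergy() const {
    double e = 0.0;
    for (int a = 0; a < N; ++a) {
      int r = prow[a], c = pcol[a];
      // count each pair once: look right and down
      if (r + 1 < L) {
        int occ = grid[(r + 1) * L + c];
        if (occ) e += pairJ(a, occ - 1, pstate[a], pstate[occ - 1]);
      }
      if (c + 1 < L) {
        int occ = grid[r * L + c + 1];
        if (occ) e += pairJ(a, occ - 1, pstate[a], pstate[occ - 1]);
      }
    }
    return e;
  }

  void fullDistance(std::vector<long long>& A, std::vector<long long>& S) const {
    A.assign(M, 0); S.assign(M, 0);
    for (int m = 0; m < M; ++m) {
      for (int a = 0; a < N; ++a) {
        if (pstate[a] != m + 1) S[m]++;
        for (int b = a + 1; b < N; ++b) {
          int adj = (std::abs(prow[a] - prow[b]) + std::abs(pcol[a] - pcol[b]) == 1);
          if (adj != tg(m, a, b)) A[m] += 2;  // ordered pairs
        }
      }
    }
  }

  inline long long dmin() const {
    long long dm = Amis[0] + Smis[0];
    for (int m = 1; m < M; ++m) {
      long long d = Amis[m] + Smis[m];
      if (d < dm) dm = d;
    }
    return dm;
  }
};

// [[Rcpp::export(name = ".kmc_run_cpp")]]
List kmc_run_cpp(IntegerVector row, IntegerVector col, IntegerVector state,
                 int L, IntegerVector targets_flat, int n_targets,
                 double Js, double Jw, double r0, int rate_law,
                 double t_init, double step_offset,
                 double t_stop, double max_steps, int stride,
                 bool stop_on_assembly, bool record_initial,
                 bool record_state_code,
                 int pending_move, double pending_residual) {
  Sim sim;
  sim.N = row.size(); sim.L = L; sim.M = n_targets;
  sim.Js = Js; sim.Jw = Jw; sim.r0 = r0; sim.half = 0.5 * (Js - Jw);
  sim.rate_law = rate_law;
  const int N = sim.N, M = sim.M;
  if ((int)targets_flat.size() != N * N * M)
    stop("targets_flat has wrong length");
  sim.prow.assign(row.begin(), row.end());
  sim.pcol.assign(col.begin(), col.end());
  sim.pstate.assign(state.begin(), state.end());
  sim.grid.assign(L * L, 0);
  for (int a = 0; a < N; ++a) {
    int idx = sim.prow[a] * L + sim.pcol[a];
    if (sim.prow[a] < 0 || sim.prow[a] >= L || sim.pcol[a] < 0 || sim.pcol[a] >= L)
      stop("particle position off board");
    if (sim.grid[idx]) stop("two particles share a tile");
    sim.grid[idx] = a + 1;
    if (sim.pstate[a] < 1 || sim.pstate[a] > M) stop("internal state out of range");
  }
  sim.I.resize(M);
  for (int m = 0; m < M; ++m) sim.I[m] = &targets_flat[0] + (size_t)m * N * N;

  sim.E = sim.fullEnergy();
  sim.fullDistance(sim.Amis, sim.Smis);

  const int n_tot = (3 + M) * N;
  std::vector<double> rate(n_tot), dE(n_tot);
  // move decoding tables filled on the fly: translations idx = a*4 + d;
  // switches idx = 4N + a*(M-1) + k, k-th admissible state in ascending order.

  std::vector<double> rec_step, rec_t, rec_E, rec_kind, rec_code;
  std::vector<std::vector<double> > rec_d(M);
  double t = t_init;
  double t_fas = NA_REAL;
  bool assembled = sim.dmin() == 0;
  if (assembled) t_fas = t;

  RNGScope rngs;

  auto record = [&](double stepno, int kind) {
    rec_step.push_back(stepno);
    rec_t.push_back(t);
    rec_E.push_back(sim.E);
    rec_kind.push_back(kind);
    for (int m = 0; m < M; ++m)
      rec_d[m].push_back((double)(sim.Amis[m] + sim.Smis[m]));
    if (record_state_code) {
      double code = 0.0, base = 1.0;
      for (int a = 0; a < N; ++a) {
        code += (sim.prow[a] * L + sim.pcol[a]) * base;
        base *= L * L;
      }
      rec_code.push_back(code);
    }
  };

  if (record_initial) record(step_offset, 0);

  double steps_done = 0.0;
  int reason = 0;  // 1 step budget, 2 time limit (possibly paused), 3 assembled
  // a dwell interrupted at a time boundary: the selected move and its
  // remaining waiting time survive the pause so an unperturbed resume is
  // bit-identical to an uninterrupted run
  int pend_out = -1;
  double resid_out = 0.0;
  if (assembled && stop_on_assembly) reason = 3;

  while (reason == 0) {
    if (steps_done >= max_steps) { reason = 1; break; }
    // --- enumerate rates ---
    double Q = 0.0;
    for (int a = 0; a < N; ++a) {
      int r = sim.prow[a], c = sim.pcol[a], sa = sim.pstate[a];
      for (int d = 0; d < 4; ++d) {
        int idx = a * 4 + d;
        int nr = r + DR[d], nc = c + DC[d];
        if (nr < 0 || nr >= L || nc < 0 || nc >= L || sim.grid[nr * L + nc]) {
          rate[idx] = 0.0; dE[idx] = 0.0;
        } else {
          double de = sim.bondSum(a, sa, nr, nc, 0) - sim.bondSum(a, sa, r, c, 0);
          dE[idx] = de;
          rate[idx] = r0 * sim.ratef(de);
          Q += rate[idx];
        }
      }
    }
    if (M > 1) {
      double pref = 4.0 * r0 / (M - 1);
      for (int a = 0; a < N; ++a) {
        int r = sim.prow[a], c = sim.pcol[a], sa = sim.pstate[a];
        int k = 0;
        for (int m = 1; m <= M; ++m) {
          if (m == sa) continue;
          int idx = 4 * N + a * (M - 1) + k; ++k;
          double de = 0.0;
          for (int d = 0; d < 4; ++d) {
            int nr = r + DR[d], nc = c + DC[d];
            if (nr < 0 || nr >= L || nc < 0 || nc >= L) continue;
            int occ = sim.grid[nr * L + nc];
            if (!occ) continue;
            int b = occ - 1;
            de += sim.pairJ(a, b, m, sim.pstate[b]) -
                  sim.pairJ(a, b, sa, sim.pstate[b]);
          }
          dE[idx] = de;
          rate[idx] = pref * sim.ratef(de);
          Q += rate[idx];
        }
      }
    }
    if (!(Q > 0.0)) stop("stalled state: total escape rate is zero");

    int sel;
    double dt;
    if (pending_move >= 0) {         // resume an interrupted dwell
      sel = pending_move;
      dt = pending_residual;
      pending_move = -1;
      if (rate[sel] <= 0.0) stop("pending move is no longer admissible");
    } else {
      // --- select move:  R_{I-1} < u*Q <= R_I ---
      double u = unif_rand();
      double targetR = u * Q, cum = 0.0;
      sel = -1;
      int last_pos = -1;
      for (int i = 0; i < n_tot; ++i) {
        if (rate[i] <= 0.0) continue;
        last_pos = i;
        cum += rate[i];
        if (cum >= targetR) { sel = i; break; }
      }
      if (sel < 0) sel = last_pos;  // guard against roundoff on the last move

      // --- waiting time (dwell in the current state) ---
      double u2 = unif_rand();
      dt = -std::log(u2) / Q;
    }

    if (t + dt > t_stop) {
      // the dwell crosses the time boundary: pause mid-dwell (exact by
      // memorylessness), keep the move and its residual waiting time
      pend_out = sel;
      resid_out = t + dt - t_stop;
      t = t_stop;
      reason = 2;
      record(step_offset + steps_done, -1);
      break;
    }
    t += dt;

    int kind;
    if (sel < 4 * N) {
      kind = 1;
      int a = sel / 4, d = sel % 4;
      int r = sim.prow[a], c = sim.pcol[a];
      int nr = r + DR[d], nc = c + DC[d];
      // distance bookkeeping: row-a adjacency contributions before/after
      int oldnb[4], nold = 0, newnb[4], nnew = 0;
      for (int dd = 0; dd < 4; ++dd) {
        int rr = r + DR[dd], cc = c + DC[dd];
        if (rr >= 0 && rr < L && cc >= 0 && cc < L && sim.grid[rr * L + cc])
          oldnb[nold++] = sim.grid[rr * L + cc] - 1;
      }
      sim.grid[r * L + c] = 0;
      for (int dd = 0; dd < 4; ++dd) {
        int rr = nr + DR[dd], cc = nc + DC[dd];
        if (rr >= 0 && rr < L && cc >= 0 && cc < L && sim.grid[rr * L + cc])
          newnb[nnew++] = sim.grid[rr * L + cc] - 1;
      }
      sim.grid[nr * L + nc] = a + 1;
      sim.prow[a] = nr; sim.pcol[a] = nc;
      for (int m = 0; m < M; ++m) {
        long long delta = 0;
        for (int i = 0; i < nnew; ++i) delta += 1 - 2 * sim.tg(m, a, newnb[i]);
        for (int i = 0; i < nold; ++i) delta -= 1 - 2 * sim.tg(m, a, oldnb[i]);
        sim.Amis[m] += 2 * delta;
      }
    } else {
      kind = 2;
      int off = sel - 4 * N;
      int a = off / (M - 1), k = off % (M - 1);
      int sa = sim.pstate[a];
      int m_new = 0, kk = 0;
      for (int m = 1; m <= M; ++m) {
        if (m == sa) continue;
        if (kk == k) { m_new = m; break; }
        ++kk;
      }
      sim.Smis[sa - 1] += 1;
      sim.Smis[m_new - 1] -= 1;
      sim.pstate[a] = m_new;
    }
    sim.E += dE[sel];
    steps_done += 1.0;

    // periodic consistency check of the incremental bookkeeping
    if (((long long)steps_done) % 100000 == 0) {
      double Efull = sim.fullEnergy();
      if (std::abs(Efull - sim.E) > 1e-6)
        stop("energy bookkeeping drifted beyond 1e-6 k_BT");
      sim.E = Efull;
      std::vector<long long> A, S;
      sim.fullDistance(A, S);
      for (int m = 0; m < M; ++m)
        if (A[m] != sim.Amis[m] || S[m] != sim.Smis[m])
          stop("distance bookkeeping drifted");
    }

    bool rec_now = ((long long)(step_offset + steps_done)) % stride == 0;
    bool asm_now = sim.dmin() == 0;
    if (asm_now && !assembled) { assembled = true; t_fas = t; }
    if (asm_now && stop_on_assembly) reason = 3;
    else if (t >= t_stop) reason = 2;
    else if (steps_done >= max_steps) reason = 1;
    if (rec_now || reason != 0) record(step_offset + steps_done, kind);
  }

  int nr = rec_t.size();
  NumericMatrix records(nr, 4 + M + (record_state_code ? 1 : 0));
  CharacterVector cn(records.ncol());
  for (int i = 0; i < nr; ++i) {
    records(i, 0) = rec_step[i];
    records(i, 1) = rec_t[i];
    records(i, 2) = rec_E[i];
    records(i, 3) = rec_kind[i];
    for (int m = 0; m < M; ++m) records(i, 4 + m) = rec_d[m][i];
    if (record_state_code) records(i, 4 + M) = rec_code[i];
  }
  cn[0] = "step"; cn[1] = "t"; cn[2] = "E"; cn[3] = "kind";
  for (int m = 0; m < M; ++m) cn[4 + m] = "d" + std::to_string(m + 1);
  if (record_state_code) cn[4 + M] = "state_code";
  colnames(records) = cn;

  NumericVector dists(M);
  for (int m = 0; m < M; ++m) dists[m] = (double)(sim.Amis[m] + sim.Smis[m]);

  return List::create(
    _["records"] = records,
    _["row"] = IntegerVector(sim.prow.begin(), sim.prow.end()),
    _["col"] = IntegerVector(sim.pcol.begin(), sim.pcol.end()),
    _["state"] = IntegerVector(sim.pstate.begin(), sim.pstate.end()),
    _["E"] = sim.E,
    _["t"] = t,
    _["d"] = dists,
    _["steps"] = steps_done,
    _["assembled"] = assembled,
    _["t_fas"] = t_fas,
    _["reason"] = reason,
    _["pending_move"] = pend_out,
    _["pending_residual"] = resid_out);
}
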