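// Core numerical routines: synchronous retrieval dynamics, per-row quadratic
// connectivity costs, simulated annealing over binary rows, greedy add/prune
// trials, and the online structural-plasticity loop.
//
// Conventions shared with the R layer:
//   * xi is a p x N integer matrix of +/-1 pattern entries, xi(nu, j).
//   * C is an N x N binary matrix; row i lists neuron i's presynaptic inputs.
//   * W is the integer Hebbian matrix, W_ij = sum_mu xi(mu,i) xi(mu,j).
//   * All cost arithmetic is on integer-valued quantities held in doubles,
//     exact below 2^53, so accept/reject comparisons never see rounding.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// seeding: splitmix64 hash so per-unit streams are decorrelated and
// independent of execution order
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
int cpp_mix_seed(int master, int index) {
  uint64_t h = splitmix64((static_cast<uint64_t>(static_cast<uint32_t>(master)) << 32) ^
                          static_cast<uint32_t>(index));
  return static_cast<int>(h & 0x7FFFFFFFULL);
}

// ---------------------------------------------------------------------------
// retrieval dynamics
// ---------------------------------------------------------------------------

// sgn with the fixed tie-break sgn(0) := +1
static inline int sgn_plus(long long x) { return x < 0 ? -1 : 1; }

struct Adjacency {
  std::vector<int> offset;  // length N + 1
  std::vector<int> col;     // neighbour indices, grouped by row
  std::vector<int> wgt;     // matching Hebbian weights
};

static Adjacency build_adjacency(const IntegerMatrix& W, const IntegerMatrix& C) {
  const int N = C.nrow();
  Adjacency a;
  a.offset.assign(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) if (C(i, j) != 0) ++cnt;
    a.offset[i + 1] = a.offset[i] + cnt;
  }
  a.col.resize(a.offset[N]);
  a.wgt.resize(a.offset[N]);
  for (int i = 0; i < N; ++i) {
    int k = a.offset[i];
    for (int j = 0; j < N; ++j) {
      if (C(i, j) != 0) {
        a.col[k] = j;
        a.wgt[k] = W(i, j);
        ++k;
      }
    }
  }
  return a;
}

// Run the synchronous dynamics from pattern nu with n_flips random sign flips,
// stopping when the overlap with the pattern is unchanged between consecutive
// iterations or after max_iter updates.  The overlap numerator is integer so
// the constancy test is exact.
static void run_one(const Adjacency& adj, const int* xi_nu, int N,
                    int n_flips, int max_iter, uint64_t rng_seed,
                    double& final_overlap, int& iters, bool& converged) {
  std::vector<int> s(xi_nu, xi_nu + N);
  if (n_flips > 0) {
    // partial Fisher-Yates for n_flips distinct positions
    std::mt19937 rng(static_cast<uint32_t>(rng_seed));
    std::vector<int> idx(N);
    for (int j = 0; j < N; ++j) idx[j] = j;
    for (int k = 0; k < n_flips; ++k) {
      std::uniform_int_distribution<int> d(k, N - 1);
      std::swap(idx[k], idx[d(rng)]);
      s[idx[k]] = -s[idx[k]];
    }
  }
  long long dot = 0;
  for (int j = 0; j < N; ++j) dot += static_cast<long long>(s[j]) * xi_nu[j];
  std::vector<int> snew(N);
  converged = false;
  iters = 0;
  for (int t = 1; t <= max_iter; ++t) {
    for (int i = 0; i < N; ++i) {
      long long h = 0;
      for (int k = adj.offset[i]; k < adj.offset[i + 1]; ++k)
        h += static_cast<long long>(adj.wgt[k]) * s[adj.col[k]];
      snew[i] = sgn_plus(h);
    }
    long long dot_new = 0;
    for (int j = 0; j < N; ++j) dot_new += static_cast<long long>(snew[j]) * xi_nu[j];
    s.swap(snew);
    iters = t;
    if (dot_new == dot) { converged = true; dot = dot_new; break; }
    dot = dot_new;
  }
  final_overlap = static_cast<double>(dot) / N;
}

// Retrieval sweep over all stored patterns; returns per-pattern final overlap,
// iteration count and the convergence flag.
// [[Rcpp::export]]
List cpp_retrieve_patterns(IntegerMatrix xi, IntegerMatrix W, IntegerMatrix C,
                           int n_flips, int max_iter, int seed) {
  const int p = xi.nrow(), N = xi.ncol();
  Adjacency adj = build_adjacency(W, C);
  NumericVector overlap(p);
  IntegerVector iters(p);
  LogicalVector conv(p);
  std::vector<int> xi_nu(N);
  for (int nu = 0; nu < p; ++nu) {
    for (int j = 0; j < N; ++j) xi_nu[j] = xi(nu, j);
    double m; int it; bool cv;
    run_one(adj, xi_nu.data(), N, n_flips, max_iter,
            static_cast<uint64_t>(cpp_mix_seed(seed, nu)), m, it, cv);
    overlap[nu] = m; iters[nu] = it; conv[nu] = cv;
    if ((nu & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["final_overlap"] = overlap,
                      _["iterations_used"] = iters,
                      _["converged"] = conv);
}

// Single trajectory from an arbitrary start state; returns the per-iteration
// overlap log as well.
// [[Rcpp::export]]
List cpp_run_dynamics(IntegerVector s0, IntegerMatrix W, IntegerMatrix C,
                      IntegerVector xi_nu, int max_iter) {
  const int N = s0.size();
  Adjacency adj = build_adjacency(W, C);
  std::vector<int> s(s0.begin(), s0.end());
  long long dot = 0;
  for (int j = 0; j < N; ++j) dot += static_cast<long long>(s[j]) * xi_nu[j];
  std::vector<double> traj;
  traj.push_back(static_cast<double>(dot) / N);
  std::vector<int> snew(N);
  bool converged = false;
  int iters = 0;
  for (int t = 1; t <= max_iter; ++t) {
    for (int i = 0; i < N; ++i) {
      long long h = 0;
      for (int k = adj.offset[i]; k < adj.offset[i + 1]; ++k)
        h += static_cast<long long>(adj.wgt[k]) * s[adj.col[k]];
      snew[i] = sgn_plus(h);
    }
    long long dot_new = 0;
    for (int j = 0; j < N; ++j) dot_new += static_cast<long long>(snew[j]) * xi_nu[j];
    s.swap(snew);
    iters = t;
    traj.push_back(static_cast<double>(dot_new) / N);
    if (dot_new == dot) { converged = true; break; }
    dot = dot_new;
  }
  return List::create(_["final_state"] = IntegerVector(s.begin(), s.end()),
                      _["final_overlap"] = traj.back(),
                      _["iterations_used"] = iters,
                      _["converged"] = converged,
                      _["overlap_trajectory"] = NumericVector(traj.begin(), traj.end()));
}

// ---------------------------------------------------------------------------
// per-row quadratic cost machinery
//
// For neuron i and pattern nu the unnormalized aligned noise is
//   A_nu = sum_{j in row} (W_ij - xi(nu,i) xi(nu,j)) xi(nu,i) xi(nu,j)
//        = sum_{j in row} (xi(nu,i) xi(nu,j) W_ij - 1)
// and the row cost is E = sum_nu (A_nu - eps)^2.
// ---------------------------------------------------------------------------

struct RowProblem {
  int N, p, i;
  double eps;
  const int* xi;          // p x N, column-major
  std::vector<int> w;     // Hebbian weights W_ij for this row
  std::vector<int> a;     // a_nu = xi(nu, i)

  void init(int i_, const IntegerMatrix& xim, double eps_) {
    N = xim.ncol(); p = xim.nrow(); i = i_; eps = eps_;
    xi = &xim(0, 0);
    a.resize(p);
    for (int nu = 0; nu < p; ++nu) a[nu] = xi[nu + static_cast<size_t>(i) * p];
    w.assign(N, 0);
    for (int j = 0; j < N; ++j) {
      const int* xj = xi + static_cast<size_t>(j) * p;
      int acc = 0;
      for (int nu = 0; nu < p; ++nu) acc += a[nu] * xj[nu];
      // note a_nu * xi(nu,j) has the same sum as xi(nu,i) * xi(nu,j)
      w[j] = acc;
    }
  }

  inline double term(int j, int nu) const {
    return static_cast<double>(a[nu]) * xi[nu + static_cast<size_t>(j) * p] * w[j] - 1.0;
  }

  void accumulate(const int* Crow, std::vector<double>& A) const {
    A.assign(p, 0.0);
    for (int j = 0; j < N; ++j) {
      if (Crow[j] != 0) {
        const int* xj = xi + static_cast<size_t>(j) * p;
        const int wj = w[j];
        for (int nu = 0; nu < p; ++nu)
          A[nu] += static_cast<double>(a[nu]) * xj[nu] * wj - 1.0;
      }
    }
  }

  double energy(const std::vector<double>& A) const {
    double E = 0.0;
    for (int nu = 0; nu < p; ++nu) {
      const double d = A[nu] - eps;
      E += d * d;
    }
    return E;
  }

  // cost change for replacing connection j_out by j_in (no state change)
  double delta_swap(const std::vector<double>& A, int j_out, int j_in) const {
    const int* xo = xi + static_cast<size_t>(j_out) * p;
    const int* xn = xi + static_cast<size_t>(j_in) * p;
    const int wo = w[j_out], wn = w[j_in];
    double dE = 0.0;
    for (int nu = 0; nu < p; ++nu) {
      const double d = static_cast<double>(a[nu]) * (xn[nu] * wn - xo[nu] * wo);
      dE += d * (2.0 * (A[nu] - eps) + d);
    }
    return dE;
  }

  void apply_swap(std::vector<double>& A, int j_out, int j_in) const {
    const int* xo = xi + static_cast<size_t>(j_out) * p;
    const int* xn = xi + static_cast<size_t>(j_in) * p;
    const int wo = w[j_out], wn = w[j_in];
    for (int nu = 0; nu < p; ++nu)
      A[nu] += static_cast<double>(a[nu]) * (xn[nu] * wn - xo[nu] * wo);
  }

  // cost change for toggling column j (add if absent, prune if present)
  double delta_toggle(const std::vector<double>& A, int j, bool present) const {
    const int* xj = xi + static_cast<size_t>(j) * p;
    const int wj = w[j];
    const double sgn = present ? -1.0 : 1.0;
    double dE = 0.0;
    for (int nu = 0; nu < p; ++nu) {
      const double d = sgn * (static_cast<double>(a[nu]) * xj[nu] * wj - 1.0);
      dE += d * (2.0 * (A[nu] - eps) + d);
    }
    return dE;
  }

  void apply_toggle(std::vector<double>& A, int j, bool present) const {
    const int* xj = xi + static_cast<size_t>(j) * p;
    const int wj = w[j];
    const double sgn = present ? -1.0 : 1.0;
    for (int nu = 0; nu < p; ++nu)
      A[nu] += sgn * (static_cast<double>(a[nu]) * xj[nu] * wj - 1.0);
  }
};

// [[Rcpp::export]]
double cpp_row_cost(int i, IntegerVector Crow, IntegerMatrix xi, double eps) {
  if (Crow[i] != 0) stop("self-connection present in row");
  RowProblem rp;
  rp.init(i, xi, eps);
  std::vector<double> A;
  rp.accumulate(&Crow[0], A);
  return rp.energy(A);
}

// [[Rcpp::export]]
NumericVector cpp_row_noise(int i, IntegerVector Crow, IntegerMatrix xi) {
  RowProblem rp;
  rp.init(i, xi, 0.0);
  std::vector<double> A;
  rp.accumulate(&Crow[0], A);
  return NumericVector(A.begin(), A.end());
}

// [[Rcpp::export]]
double cpp_delta_swap(int i, IntegerVector Crow, IntegerMatrix xi, double eps,
                      int j_out, int j_in) {
  if (Crow[j_out] == 0) stop("j_out is not a current connection");
  if (Crow[j_in] != 0) stop("j_in is already a connection");
  if (j_in == i) stop("j_in would create a self-connection");
  RowProblem rp;
  rp.init(i, xi, eps);
  std::vector<double> A;
  rp.accumulate(&Crow[0], A);
  return rp.delta_swap(A, j_out, j_in);
}

// ---------------------------------------------------------------------------
// simulated annealing over one row
// ---------------------------------------------------------------------------

struct AnnealResult {
  std::vector<int> row;
  double e_init, e_final, t0;
  int steps, accepted;
};

static double probe_t0(const RowProblem& rp, const std::vector<double>& A,
                       const std::vector<int>& conn, const std::vector<int>& free_cols,
                       int n_probe, double accept0, double t_final, std::mt19937& rng) {
  std::uniform_int_distribution<int> dc(0, static_cast<int>(conn.size()) - 1);
  std::uniform_int_distribution<int> df(0, static_cast<int>(free_cols.size()) - 1);
  double pos_sum = 0.0;
  int pos_n = 0;
  for (int k = 0; k < n_probe; ++k) {
    const double dE = rp.delta_swap(A, conn[dc(rng)], free_cols[df(rng)]);
    if (dE > 0) { pos_sum += dE; ++pos_n; }
  }
  if (pos_n == 0) return t_final;  // locally flat/downhill: skip the hot phase
  return -(pos_sum / pos_n) / std::log(accept0);
}

// [[Rcpp::export]]
double cpp_estimate_t0(int i, IntegerVector Crow, IntegerMatrix xi, double eps,
                       int n_probe, double accept0, double t_final, int seed) {
  RowProblem rp;
  rp.init(i, xi, eps);
  std::vector<int> conn, free_cols;
  for (int j = 0; j < rp.N; ++j) {
    if (j == i) continue;
    if (Crow[j] != 0) conn.push_back(j); else free_cols.push_back(j);
  }
  if (conn.empty() || free_cols.empty()) return t_final;
  std::vector<double> A;
  rp.accumulate(&Crow[0], A);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  return probe_t0(rp, A, conn, free_cols, n_probe, accept0, t_final, rng);
}

static AnnealResult anneal_row_core(int i, const int* Crow, const IntegerMatrix& xi,
                                    double eps, double decay, double t_final,
                                    double t_init, int moves_per_t, int n_probe,
                                    double accept0, uint32_t seed, int check_every) {
  RowProblem rp;
  rp.init(i, xi, eps);
  const int N = rp.N;
  const int p = rp.p;

  // precomputed per-(pattern, column) cost terms: B(nu, j) = a_nu xi(nu,j) w_j,
  // so a swap's crosstalk change is a plain column difference
  std::vector<int> B(static_cast<size_t>(p) * N);
  for (int j = 0; j < N; ++j) {
    const int* xj = rp.xi + static_cast<size_t>(j) * p;
    const int wj = rp.w[j];
    int* bj = &B[static_cast<size_t>(j) * p];
    for (int nu = 0; nu < p; ++nu) bj[nu] = rp.a[nu] * xj[nu] * wj;
  }

  std::vector<int> conn, free_cols;
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    if (Crow[j] != 0) conn.push_back(j); else free_cols.push_back(j);
  }

  AnnealResult res;
  res.row.assign(Crow, Crow + N);
  std::vector<double> A;
  rp.accumulate(Crow, A);
  res.e_init = rp.energy(A);
  res.e_final = res.e_init;
  res.steps = 0;
  res.accepted = 0;
  res.t0 = t_final;

  if (conn.empty() || free_cols.empty()) return res;  // no valid swap exists

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> dc(0, static_cast<int>(conn.size()) - 1);
  std::uniform_int_distribution<int> df(0, static_cast<int>(free_cols.size()) - 1);

  double T = (t_init > 0.0) ? t_init
                            : probe_t0(rp, A, conn, free_cols, n_probe, accept0, t_final, rng);
  res.t0 = T;

  double E = res.e_init;
  double best_E = E;
  std::vector<int> best_conn = conn;
  int since_check = 0;

  // When no uphill probe was found the row is already inside a descent
  // basin: anneal at T = 0 instead (greedy quench, strictly-decreasing moves
  // only) with the proposal budget of a unit-temperature schedule.
  int quench_steps = 0;
  if (T <= t_final) {
    quench_steps = static_cast<int>(
        std::ceil(std::log(1.0 / t_final) / std::log(1.0 / decay)));
  }

  while (T > t_final) {
    for (int m = 0; m < moves_per_t; ++m) {
      const int ci = dc(rng), fi = df(rng);
      const int j_out = conn[ci], j_in = free_cols[fi];
      const int* bo = &B[static_cast<size_t>(j_out) * p];
      const int* bn = &B[static_cast<size_t>(j_in) * p];
      double dE = 0.0;
      for (int nu = 0; nu < p; ++nu) {
        const double d = static_cast<double>(bn[nu] - bo[nu]);
        dE += d * (2.0 * (A[nu] - eps) + d);
      }
      if (dE < 0.0 || unif(rng) < std::exp(-dE / T)) {
        for (int nu = 0; nu < p; ++nu) A[nu] += bn[nu] - bo[nu];
        E += dE;
        std::swap(conn[ci], free_cols[fi]);
        ++res.accepted;
        if (E < best_E) { best_E = E; best_conn = conn; }
        if (check_every > 0 && ++since_check >= check_every) {
          since_check = 0;
          std::vector<int> rowchk(N, 0);
          for (int j : conn) rowchk[j] = 1;
          std::vector<double> Achk;
          rp.accumulate(rowchk.data(), Achk);
          for (int nu = 0; nu < rp.p; ++nu)
            if (Achk[nu] != A[nu]) stop("incremental noise cache diverged from recomputation");
          if (rp.energy(Achk) != E) stop("incremental energy diverged from recomputation");
        }
      }
    }
    T *= decay;
    ++res.steps;
  }

  for (int m = 0; m < quench_steps * moves_per_t; ++m) {
    const int ci = dc(rng), fi = df(rng);
    const int j_out = conn[ci], j_in = free_cols[fi];
    const int* bo = &B[static_cast<size_t>(j_out) * p];
    const int* bn = &B[static_cast<size_t>(j_in) * p];
    double dE = 0.0;
    for (int nu = 0; nu < p; ++nu) {
      const double d = static_cast<double>(bn[nu] - bo[nu]);
      dE += d * (2.0 * (A[nu] - eps) + d);
    }
    if (dE < 0.0) {
      for (int nu = 0; nu < p; ++nu) A[nu] += bn[nu] - bo[nu];
      E += dE;
      std::swap(conn[ci], free_cols[fi]);
      ++res.accepted;
      if (E < best_E) { best_E = E; best_conn = conn; }
    }
  }
  res.steps += quench_steps;

  // best-seen configuration, not the last visited one
  std::fill(res.row.begin(), res.row.end(), 0);
  for (int j : best_conn) res.row[j] = 1;
  res.e_final = best_E;
  return res;
}

// [[Rcpp::export]]
List cpp_anneal_row(int i, IntegerVector Crow, IntegerMatrix xi, double eps,
                    double decay, double t_final, double t_init, int moves_per_t,
                    int n_probe, double accept0, int seed, int check_every) {
  AnnealResult r = anneal_row_core(i, &Crow[0], xi, eps, decay, t_final, t_init,
                                   moves_per_t, n_probe, accept0,
                                   static_cast<uint32_t>(seed), check_every);
  return List::create(_["row"] = IntegerVector(r.row.begin(), r.row.end()),
                      _["e_init"] = r.e_init, _["e_final"] = r.e_final,
                      _["t0"] = r.t0, _["steps"] = r.steps,
                      _["accepted"] = r.accepted);
}

// [[Rcpp::export]]
List cpp_optimize_network(IntegerMatrix C, IntegerMatrix xi, double eps,
                          double decay, double t_final, double t_init,
                          int moves_per_t, int n_probe, double accept0,
                          int seed, int check_every) {
  const int N = C.nrow();
  IntegerMatrix Copt(N, N);
  NumericVector e_init(N), e_final(N), t0(N);
  std::vector<int> Crow(N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) Crow[j] = C(i, j);
    AnnealResult r = anneal_row_core(i, Crow.data(), xi, eps, decay, t_final, t_init,
                                     moves_per_t, n_probe, accept0,
                                     static_cast<uint32_t>(cpp_mix_seed(seed, i)),
                                     check_every);
    for (int j = 0; j < N; ++j) Copt(i, j) = r.row[j];
    e_init[i] = r.e_init; e_final[i] = r.e_final; t0[i] = r.t0;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["C"] = Copt, _["e_init"] = e_init,
                      _["e_final"] = e_final, _["t0"] = t0);
}

// ---------------------------------------------------------------------------
// greedy add/prune trials (the T = 0 online move)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_greedy_trials(int i, IntegerVector Crow, IntegerMatrix xi, double eps,
                       int trials, int seed) {
  RowProblem rp;
  rp.init(i, xi, eps);
  const int N = rp.N;
  std::vector<int> row(Crow.begin(), Crow.end());
  std::vector<double> A;
  rp.accumulate(row.data(), A);
  double E = rp.energy(A);
  NumericVector e_trace(trials + 1);
  e_trace[0] = E;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> dj(0, N - 2);
  int accepted = 0;
  for (int k = 0; k < trials; ++k) {
    int j = dj(rng);
    if (j >= i) ++j;  // uniform over the N-1 columns other than i
    const bool present = row[j] != 0;
    const double dE = rp.delta_toggle(A, j, present);
    if (dE < 0.0) {   // strictly decreasing moves only
      rp.apply_toggle(A, j, present);
      row[j] = present ? 0 : 1;
      E += dE;
      ++accepted;
    }
    e_trace[k + 1] = E;
  }
  return List::create(_["row"] = IntegerVector(row.begin(), row.end()),
                      _["e_trace"] = e_trace, _["accepted"] = accepted,
                      _["e_final"] = E);
}

// ---------------------------------------------------------------------------
// online algorithm: interleaved pattern loading and greedy add/prune sweeps
// ---------------------------------------------------------------------------

static int peff_from_state(const IntegerMatrix& xi, int p,
                           const std::vector<int>& Wflat,
                           const std::vector<unsigned char>& Cflat,
                           int N, int max_iter) {
  // CSR over the current connectivity
  Adjacency adj;
  adj.offset.assign(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) if (Cflat[i + static_cast<size_t>(j) * N]) ++cnt;
    adj.offset[i + 1] = adj.offset[i] + cnt;
  }
  adj.col.resize(adj.offset[N]);
  adj.wgt.resize(adj.offset[N]);
  for (int i = 0; i < N; ++i) {
    int k = adj.offset[i];
    for (int j = 0; j < N; ++j) {
      if (Cflat[i + static_cast<size_t>(j) * N]) {
        adj.col[k] = j;
        adj.wgt[k] = Wflat[i + static_cast<size_t>(j) * N];
        ++k;
      }
    }
  }
  int n_ok = 0;
  std::vector<int> xi_nu(N);
  for (int nu = 0; nu < p; ++nu) {
    for (int j = 0; j < N; ++j) xi_nu[j] = xi(nu, j);
    double m; int it; bool cv;
    run_one(adj, xi_nu.data(), N, 0, max_iter, 0, m, it, cv);
    if (m > 0.7) ++n_ok;
  }
  return n_ok;
}

// [[Rcpp::export]]
List cpp_online_run(IntegerMatrix xi, IntegerMatrix C0, int p0, double eps,
                    int batch, int trials, double thr_frac, int stop_after,
                    int max_sweeps, int max_iter_dyn, int seed) {
  const int N = C0.nrow();
  const int p_max = xi.nrow();
  std::vector<unsigned char> Cflat(static_cast<size_t>(N) * N, 0);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      Cflat[i + static_cast<size_t>(j) * N] = static_cast<unsigned char>(C0(i, j) != 0);

  // Hebbian matrix over the first p0 patterns, updated incrementally per batch
  std::vector<int> Wflat(static_cast<size_t>(N) * N, 0);
  std::vector<int> xrow(N);
  auto add_pattern = [&](int mu) {
    for (int j = 0; j < N; ++j) xrow[j] = xi(mu, j);
    for (int j = 0; j < N; ++j) {
      const int xj = xrow[j];
      int* wc = &Wflat[static_cast<size_t>(j) * N];
      for (int i = 0; i < N; ++i) wc[i] += xrow[i] * xj;
    }
  };
  int p = std::min(p0, p_max);
  for (int mu = 0; mu < p; ++mu) add_pattern(mu);

  std::vector<double> rec_mean_c, rec_sd_c, rec_peff, rec_p, rec_sweep, rec_E;
  std::vector<int> rec_event;  // 0 = sweep, 1 = batch load, 2 = initial
  int sweeps_done = 0;

  auto record = [&](int peff, int event, double totE) {
    int sum = 0; double sq = 0.0;
    std::vector<int> indeg(N, 0);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        indeg[i] += Cflat[i + static_cast<size_t>(j) * N];
    for (int i = 0; i < N; ++i) sum += indeg[i];
    const double mc = static_cast<double>(sum) / N;
    for (int i = 0; i < N; ++i) sq += (indeg[i] - mc) * (indeg[i] - mc);
    rec_mean_c.push_back(mc);
    rec_sd_c.push_back(N > 1 ? std::sqrt(sq / (N - 1)) : 0.0);
    rec_peff.push_back(peff);
    rec_p.push_back(p);
    rec_sweep.push_back(sweeps_done);
    rec_E.push_back(totE);
    rec_event.push_back(event);
  };

  int peff = peff_from_state(xi, p, Wflat, Cflat, N, max_iter_dyn);
  record(peff, 2, NA_REAL);

  bool stopped_unchanged = false, hit_sweep_cap = false, hit_pattern_cap = false;
  int unchanged = 0;
  RowProblem rp;
  std::vector<double> A;
  std::vector<int> rowbuf(N);

  bool done = false;
  for (;;) {
    // optimize until the retrieval criterion holds again (also covers runs
    // whose initial state already violates it), then load the next batch
    while (peff <= thr_frac * p) {
      if (sweeps_done >= max_sweeps) { hit_sweep_cap = true; done = true; break; }
      int accepted_sweep = 0;
      double totE = 0.0;
      for (int i = 0; i < N; ++i) {
        // row problem against the current W (rebuild w from the maintained matrix)
        rp.N = N; rp.p = p; rp.i = i; rp.eps = eps;
        rp.xi = &xi(0, 0);
        rp.a.resize(p);
        const int pfull = xi.nrow();
        for (int nu = 0; nu < p; ++nu) rp.a[nu] = rp.xi[nu + static_cast<size_t>(i) * pfull];
        // NOTE: rp.xi indexing assumes leading dimension p; xi has p_max rows,
        // so index through a local lambda instead of RowProblem helpers.
        rp.w.assign(N, 0);
        for (int j = 0; j < N; ++j) rp.w[j] = Wflat[i + static_cast<size_t>(j) * N];
        for (int j = 0; j < N; ++j) rowbuf[j] = Cflat[i + static_cast<size_t>(j) * N];

        A.assign(p, 0.0);
        for (int j = 0; j < N; ++j) {
          if (rowbuf[j]) {
            const int* xj = rp.xi + static_cast<size_t>(j) * pfull;
            const int wj = rp.w[j];
            for (int nu = 0; nu < p; ++nu)
              A[nu] += static_cast<double>(rp.a[nu]) * xj[nu] * wj - 1.0;
          }
        }
        double E = 0.0;
        for (int nu = 0; nu < p; ++nu) { const double d = A[nu] - eps; E += d * d; }

        std::mt19937 rng(static_cast<uint32_t>(
            cpp_mix_seed(seed, sweeps_done * N + i + 1)));
        std::uniform_int_distribution<int> dj(0, N - 2);
        for (int k = 0; k < trials; ++k) {
          int j = dj(rng);
          if (j >= i) ++j;
          const bool present = rowbuf[j] != 0;
          const int* xj = rp.xi + static_cast<size_t>(j) * pfull;
          const int wj = rp.w[j];
          const double sgn = present ? -1.0 : 1.0;
          double dE = 0.0;
          for (int nu = 0; nu < p; ++nu) {
            const double d = sgn * (static_cast<double>(rp.a[nu]) * xj[nu] * wj - 1.0);
            dE += d * (2.0 * (A[nu] - eps) + d);
          }
          if (dE < 0.0) {
            for (int nu = 0; nu < p; ++nu)
              A[nu] += sgn * (static_cast<double>(rp.a[nu]) * xj[nu] * wj - 1.0);
            rowbuf[j] = present ? 0 : 1;
            Cflat[i + static_cast<size_t>(j) * N] = static_cast<unsigned char>(rowbuf[j]);
            E += dE;
            ++accepted_sweep;
          }
        }
        totE += E;
      }
      ++sweeps_done;
      peff = peff_from_state(xi, p, Wflat, Cflat, N, max_iter_dyn);
      record(peff, 0, totE);
      if (accepted_sweep == 0) ++unchanged; else unchanged = 0;
      if (unchanged >= stop_after) { stopped_unchanged = true; done = true; break; }
      Rcpp::checkUserInterrupt();
    }
    if (done) break;
    if (p + batch > p_max) { hit_pattern_cap = true; break; }
    for (int mu = p; mu < p + batch; ++mu) add_pattern(mu);
    p += batch;
    peff = peff_from_state(xi, p, Wflat, Cflat, N, max_iter_dyn);
    record(peff, 1, NA_REAL);
  }

  IntegerMatrix Cfinal(N, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      Cfinal(i, j) = Cflat[i + static_cast<size_t>(j) * N];

  return List::create(
      _["trajectory"] = DataFrame::create(
          _["sweep"] = NumericVector(rec_sweep.begin(), rec_sweep.end()),
          _["event"] = IntegerVector(rec_event.begin(), rec_event.end()),
          _["p"] = NumericVector(rec_p.begin(), rec_p.end()),
          _["p_eff"] = NumericVector(rec_peff.begin(), rec_peff.end()),
          _["mean_c"] = NumericVector(rec_mean_c.begin(), rec_mean_c.end()),
          _["sd_c"] = NumericVector(rec_sd_c.begin(), rec_sd_c.end()),
          _["total_cost"] = NumericVector(rec_E.begin(), rec_E.end())),
      _["C"] = Cfinal,
      _["p"] = p,
      _["p_eff"] = peff,
      _["c_est"] = rec_mean_c.back(),
      _["stopped_unchanged"] = stopped_unchanged,
      _["hit_sweep_cap"] = hit_sweep_cap,
      _["hit_pattern_cap"] = hit_pattern_cap,
      _["sweeps"] = sweeps_done);
}
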