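#include <Rcpp.h>
using namespace Rcpp;

// Death-birth dynamics on an edge-typed regular graph.
//
// Strategies are 0 (B) / 1 (A). Payoff tensors are flat vectors in
// lexicographic configuration order (s1 slowest), matching config_grid():
//   idx = ((s1)*(g2+1) + s2)*(g3+1) + ... + sn.
// Each node's typed A-neighbour counts are kept incrementally so an
// elementary update touches only the k neighbours of the flipped node.

namespace {

struct Sim {
  int N, k, n;
  const int *nbr;   // N x k, 0-based node ids, column-major from R
  const int *typ;   // N x k, 0-based type ids
  std::vector<int> gplus1;
  const double *a, *b;
  double omega;
  std::vector<int> cnt;    // N x n typed A-neighbour counts
  std::vector<int> strat;  // 0/1 per node
  int nA;

  Sim(const IntegerMatrix &nbr_, const IntegerMatrix &typ_,
      const IntegerVector &g_, const NumericVector &a_,
      const NumericVector &b_, double omega_)
      : N(nbr_.nrow()), k(nbr_.ncol()), n(g_.size()), nbr(nbr_.begin()),
        typ(typ_.begin()), a(a_.begin()), b(b_.begin()), omega(omega_),
        cnt(N * n), strat(N), nA(0) {
    gplus1.resize(n);
    for (int j = 0; j < n; ++j) gplus1[j] = g_[j] + 1;
  }

  inline int nb(int i, int j) const { return nbr[i + (size_t)N * j]; }
  inline int ty(int i, int j) const { return typ[i + (size_t)N * j]; }

  void recount() {
    std::fill(cnt.begin(), cnt.end(), 0);
    nA = 0;
    for (int i = 0; i < N; ++i) nA += strat[i];
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < k; ++j)
        if (strat[nb(i, j)]) ++cnt[(size_t)i * n + ty(i, j)];
  }

  inline int cfg_index(int i) const {
    const int *c = &cnt[(size_t)i * n];
    int idx = 0;
    for (int j = 0; j < n; ++j) idx = idx * gplus1[j] + c[j];
    return idx;
  }

  inline double fitness(int i) const {
    double pay = strat[i] ? a[cfg_index(i)] : b[cfg_index(i)];
    return 1.0 - omega + omega * pay;
  }

  inline void set_strategy(int i, int s) {
    if (strat[i] == s) return;
    int d = s - strat[i];
    strat[i] = s;
    nA += d;
    for (int j = 0; j < k; ++j) cnt[(size_t)nb(i, j) * n + ty(i, j)] += d;
  }

  // one elementary death-birth event; returns false on non-positive fitness
  inline bool step() {
    int i = (int)(unif_rand() * N);
    if (i == N) i = N - 1;
    double tot = 0.0, F[64];
    for (int j = 0; j < k; ++j) {
      double f = fitness(nb(i, j));
      if (f <= 0.0) return false;
      F[j] = f;
      tot += f;
    }
    double u = unif_rand() * tot;
    int pick = k - 1;
    for (int j = 0; j < k; ++j) {
      u -= F[j];
      if (u <= 0.0) { pick = j; break; }
    }
    set_strategy(i, strat[nb(i, pick)]);
    return true;
  }
};

}  // namespace

// Fixation runs: each starts from a single mutant (strategy `mutant`) at a
// uniformly random node in a resident population, and iterates until
// absorption or max_steps. Returns c(n_fixed, n_capped).
// [[Rcpp::export(name = ".cpp_fixation")]]
IntegerVector cpp_fixation(IntegerMatrix nbr, IntegerMatrix typ,
                           IntegerVector g, NumericVector a, NumericVector b,
                           double omega, int runs, int mutant,
                           double max_steps) {
  Sim sim(nbr, typ, g, a, b, omega);
  if (sim.k > 64) stop("degree larger than 64 is not supported");
  int fixed = 0, capped = 0;
  int resident = 1 - mutant;
  for (int run = 0; run < runs; ++run) {
    std::fill(sim.strat.begin(), sim.strat.end(), resident);
    int start = (int)(unif_rand() * sim.N);
    if (start == sim.N) start = sim.N - 1;
    sim.strat[start] = mutant;
    sim.recount();
    double steps = 0.0;
    bool absorbed = false;
    while (steps < max_steps) {
      if (!sim.step()) stop("non-positive fitness encountered");
      steps += 1.0;
      if (sim.nA == 0 || sim.nA == sim.N) { absorbed = true; break; }
    }
    if (!absorbed) {
      ++capped;
    } else {
      int winner = (sim.nA == sim.N) ? 1 : 0;
      if (winner == mutant) ++fixed;
    }
    if ((run & 1023) == 0) checkUserInterrupt();
  }
  return IntegerVector::create(fixed, capped);
}

// Drift runs: independent Bernoulli(p) initialisations, one generation of
// N elementary events each, returning p_after - p_before per replicate.
// [[Rcpp::export(name = ".cpp_drift")]]
NumericVector cpp_drift(IntegerMatrix nbr, IntegerMatrix typ, IntegerVector g,
                        NumericVector a, NumericVector b, double omega,
                        double p, int reps, int steps_per_rep) {
  Sim sim(nbr, typ, g, a, b, omega);
  if (sim.k > 64) stop("degree larger than 64 is not supported");
  NumericVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    for (int i = 0; i < sim.N; ++i) sim.strat[i] = (unif_rand() < p) ? 1 : 0;
    sim.recount();
    double before = (double)sim.nA / sim.N;
    for (int s = 0; s < steps_per_rep; ++s)
      if (!sim.step()) stop("non-positive fitness encountered");
    out[rep] = (double)sim.nA / sim.N - before;
    if ((rep & 255) == 0) checkUserInterrupt();
  }
  return out;
}

// Advance an explicit strategy state by nsteps elementary events.
// [[Rcpp::export(name = ".cpp_advance")]]
IntegerVector cpp_advance(IntegerMatrix nbr, IntegerMatrix typ,
                          IntegerVector g, NumericVector a, NumericVector b,
                          double omega, IntegerVector strategies,
                          int nsteps) {
  Sim sim(nbr, typ, g, a, b, omega);
  if (sim.k > 64) stop("degree larger than 64 is not supported");
  for (int i = 0; i < sim.N; ++i) sim.strat[i] = strategies[i] ? 1 : 0;
  sim.recount();
  for (int s = 0; s < nsteps; ++s) {
    if (!sim.step()) stop("non-positive fitness encountered");
    if (sim.nA == 0 || sim.nA == sim.N) break;
  }
  return IntegerVector(sim.strat.begin(), sim.strat.end());
}
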