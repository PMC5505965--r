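#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Wright-Fisher core. Alleles are coded 0 = A (wild type, fixed phenotype)
// and 1 = a (plastic). All randomness comes from R's RNG (unif_rand), so
// set.seed() on the R side fully determines a trajectory.

namespace {

struct WfCfg {
  int N;
  int mode;       // 0 individual, 1 global, 2 switching
  double p;       // phenotypic memory (individual/global)
  double q;       // per-offspring switch probability (switching)
  int kind;       // 0 degenerate, 1 two_point, 2 uniform
  double mean;    // E(Phi_a)
  double sd;      // sd(Phi_a)
  double phiA;    // fixed phenotype of A
  int regime;     // 0 constant, 1 periodic
  int period_n;   // generations per environment (periodic)
  int env0;       // 0 = E1 first, 1 = E2 first (resolved per replicate)
  double m;       // reflection midpoint (periodic)
  int max_gen;    // discard cutoff (generations after entry)
};

WfCfg parse_cfg(const List& cfg) {
  WfCfg c;
  c.N        = as<int>(cfg["N"]);
  c.mode     = as<int>(cfg["mode"]);
  c.p        = as<double>(cfg["p"]);
  c.q        = as<double>(cfg["q"]);
  c.kind     = as<int>(cfg["kind"]);
  c.mean     = as<double>(cfg["mean"]);
  c.sd       = as<double>(cfg["sd"]);
  c.phiA     = as<double>(cfg["phiA"]);
  c.regime   = as<int>(cfg["regime"]);
  c.period_n = as<int>(cfg["period_n"]);
  c.env0     = as<int>(cfg["env0"]);
  c.m        = as<double>(cfg["m"]);
  c.max_gen  = as<int>(cfg["max_gen"]);
  return c;
}

// environment index (0 = E1, 1 = E2) in effect during generation t;
// blocks of period_n generations, starting from env0 at t = 0
inline int env_at(int t, const WfCfg& c) {
  if (c.regime == 0) return 0;
  return ((t / c.period_n) % 2 == 0) ? c.env0 : 1 - c.env0;
}

// f1 is the identity, f2 the reflection around m
inline double fitness_map(double x, int env, const WfCfg& c) {
  double w = (env == 1) ? 2.0 * c.m - x : x;
  if (w <= 0.0) stop("non-positive fitness");
  return w;
}

inline double draw_phen(const WfCfg& c) {
  switch (c.kind) {
  case 0:  return c.mean;
  case 1:  return (unif_rand() < 0.5) ? c.mean + c.sd : c.mean - c.sd;
  default: return c.mean + c.sd * std::sqrt(3.0) * (2.0 * unif_rand() - 1.0);
  }
}

struct WfState {
  std::vector<int> al;
  std::vector<double> ph;
  std::vector<int> al2;
  std::vector<double> ph2;
  std::vector<double> cum;
  int gen;

  WfState(const IntegerVector& alleles, const NumericVector& phen, int generation)
    : al(alleles.begin(), alleles.end()),
      ph(phen.begin(), phen.end()),
      al2(alleles.size()), ph2(alleles.size()), cum(alleles.size()),
      gen(generation) {}

  int count_a() const {
    int k = 0;
    for (size_t i = 0; i < al.size(); ++i) k += al[i];
    return k;
  }

  double mean_fitness(const WfCfg& c) const {
    double tot = 0.0;
    int env = env_at(gen, c);
    for (size_t i = 0; i < ph.size(); ++i) tot += fitness_map(ph[i], env, c);
    return tot / double(ph.size());
  }

  // selection + reproduction, then phenotype inheritance/resampling
  void step(const WfCfg& c) {
    const int N = c.N;
    const int env = env_at(gen, c);
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      tot += fitness_map(ph[i], env, c);
      cum[i] = tot;
    }
    if (!(tot > 0.0)) stop("zero total fitness");

    bool shared_redraw = false;
    double shared_val = 0.0;
    if (c.mode == 1 && unif_rand() >= c.p) {  // one Bernoulli(p) per generation
      shared_redraw = true;
      shared_val = draw_phen(c);
    }

    for (int j = 0; j < N; ++j) {
      double u = unif_rand() * tot;
      int k = int(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (k >= N) k = N - 1;
      al2[j] = al[k];
      if (al[k] == 0) {
        ph2[j] = c.phiA;                       // A breeds true
      } else if (c.mode == 0) {                // individual memory
        ph2[j] = (unif_rand() < c.p) ? ph[k] : draw_phen(c);
      } else if (c.mode == 1) {                // global memory
        ph2[j] = shared_redraw ? shared_val : ph[k];
      } else {                                 // two-phenotype switching
        double other = (ph[k] > c.mean) ? c.mean - c.sd : c.mean + c.sd;
        ph2[j] = (unif_rand() < c.q) ? other : ph[k];
      }
    }
    al.swap(al2);
    ph.swap(ph2);
    ++gen;
  }

  List as_list() const {
    return List::create(_["alleles"] = IntegerVector(al.begin(), al.end()),
                        _["phenotypes"] = NumericVector(ph.begin(), ph.end()),
                        _["generation"] = gen);
  }
};

}  // namespace

// Single generation update; errors if the state is already absorbed.
// [[Rcpp::export]]
List cpp_wf_step(IntegerVector alleles, NumericVector phenotypes, int generation,
                 List cfg) {
  WfCfg c = parse_cfg(cfg);
  WfState s(alleles, phenotypes, generation);
  int na = s.count_a();
  if (na == 0 || na == c.N) stop("population absorbed");
  s.step(c);
  return s.as_list();
}

// Run until absorption of either allele or the discard cutoff.
// outcome: 1 = fixation of a, 0 = loss of a, 2 = discard (cutoff reached)
// [[Rcpp::export]]
List cpp_wf_run(IntegerVector alleles, NumericVector phenotypes, int generation,
                List cfg) {
  WfCfg c = parse_cfg(cfg);
  WfState s(alleles, phenotypes, generation);
  int steps = 0;
  int na = s.count_a();
  while (na > 0 && na < c.N && steps < c.max_gen) {
    s.step(c);
    na = s.count_a();
    ++steps;
  }
  int outcome = (na == c.N) ? 1 : (na == 0 ? 0 : 2);
  return List::create(_["outcome"] = outcome,
                      _["generation"] = s.gen,
                      _["steps"] = steps,
                      _["n_a"] = na);
}

// Advance nsteps generations unconditionally (burn-in / stationary-state
// recording). If record_mean_fitness, returns the population mean fitness
// evaluated on the state in effect at each of the nsteps generations,
// before that generation's update.
// [[Rcpp::export]]
List cpp_wf_steps(IntegerVector alleles, NumericVector phenotypes, int generation,
                  List cfg, int nsteps, bool record_mean_fitness) {
  WfCfg c = parse_cfg(cfg);
  WfState s(alleles, phenotypes, generation);
  NumericVector wbar(record_mean_fitness ? nsteps : 0);
  for (int i = 0; i < nsteps; ++i) {
    if (record_mean_fitness) wbar[i] = s.mean_fitness(c);
    s.step(c);
  }
  List out = s.as_list();
  out["mean_fitness"] = wbar;
  return out;
}
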