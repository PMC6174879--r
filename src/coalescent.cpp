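#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured-coalescent kernel for two demes plus an ancestral population.
//
// Units follow the diffusion convention: time in 2*Nref generations, deme
// sizes nu1/nu2 as ratios to Nref, scaled migration m = 2*Nref * (per-
// generation migration fraction), so a lineage in deme 1 jumps to deme 2
// backward in time at rate m12/2.  At time T (backward) all lineages merge
// into the ancestral population of size 1.  Growth models shrink each deme
// exponentially backward from nu_i at the present to its split fraction
// (s1 or 1-s1) at T; time-inhomogeneous coalescence is handled by thinning
// against the interval maximum of the rate.

struct Lineage {
  int pop;  // 1 or 2 (ignored in the ancestral phase)
  int c1;   // descendant leaves in pop 1
  int c2;   // descendant leaves in pop 2
  int nid;  // node id in the recorded genealogy
};

// Simulate one genealogy.  If grid is non-null, add each lineage's duration
// to the cell indexed by its descendant-leaf counts (the branch-length
// contribution that expected-SFS computation needs).  If parent/times are
// non-null, record the tree (2n-1 nodes, leaves 0..n-1, root parent -1).
// `lin` is a caller-owned scratch buffer, reused across replicates.
//
// When accumulating the grid (and not recording a tree), the ancestral
// phase uses the conditional expectation of each holding time given the
// jump chain (2/(k(k-1)) instead of a sampled exponential): in that phase
// rates are constant and pair choices are independent of the holding
// times, so this is an unbiased Rao-Blackwellized estimator of expected
// branch lengths with strictly smaller variance.
static void sim_one(int n1, int n2,
                    double nu1, double nu2, double T,
                    double m12, double m21, double s1, bool growth,
                    double* grid,
                    std::vector<int>* parent, std::vector<double>* times,
                    std::vector<Lineage>& lin) {
  const bool rao_blackwell = (grid != nullptr) && (parent == nullptr);
  const int n = n1 + n2;
  const int g1 = n1 + 1;  // grid rows (index = leaves in pop 1)
  lin.clear();
  lin.reserve(n);
  for (int i = 0; i < n; ++i) {
    Lineage L;
    L.pop = (i < n1) ? 1 : 2;
    L.c1 = (i < n1) ? 1 : 0;
    L.c2 = (i < n1) ? 0 : 1;
    L.nid = i;
    lin.push_back(L);
  }
  int next_node = n;
  double t = 0.0;
  const double s2 = 1.0 - s1;
  const double r1 = (growth && T > 0) ? std::log(s1 / nu1) / T : 0.0;
  const double r2 = (growth && T > 0) ? std::log(s2 / nu2) / T : 0.0;

  auto accumulate = [&](double dt) {
    if (grid == nullptr || dt <= 0) return;
    for (size_t l = 0; l < lin.size(); ++l) {
      int i = lin[l].c1, j = lin[l].c2;
      if ((i == 0 && j == 0) || (i == n1 && j == n2)) continue;
      grid[i + j * g1] += dt;
    }
  };
  auto merge_pair = [&](int a, int b, double when) {
    // a != b indices into lin
    if (parent != nullptr) {
      (*parent)[lin[a].nid] = next_node;
      (*parent)[lin[b].nid] = next_node;
      (*times)[next_node] = when;
    }
    lin[a].c1 += lin[b].c1;
    lin[a].c2 += lin[b].c2;
    lin[a].nid = next_node++;
    lin[b] = lin.back();
    lin.pop_back();
  };
  // index into lin of the r-th (0-based) lineage currently in `pop`
  auto nth_in_pop = [&](int pop, int r) -> int {
    for (size_t l = 0; l < lin.size(); ++l)
      if (lin[l].pop == pop && r-- == 0) return (int)l;
    return (int)lin.size() - 1;  // unreachable for valid r
  };
  auto pick_pair_in_pop = [&](int pop, int& a, int& b) {
    int k = 0;
    for (size_t l = 0; l < lin.size(); ++l) if (lin[l].pop == pop) ++k;
    int i = (int)std::floor(R::runif(0.0, 1.0) * k);
    if (i >= k) i = k - 1;
    int j = (int)std::floor(R::runif(0.0, 1.0) * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    a = nth_in_pop(pop, std::min(i, j));
    b = nth_in_pop(pop, std::max(i, j));
  };

  // Phase 1: two structured demes, 0 <= t < T.
  while (t < T && lin.size() > 1) {
    int k1 = 0, k2 = 0;
    for (size_t l = 0; l < lin.size(); ++l) (lin[l].pop == 1) ? ++k1 : ++k2;
    double inv1_now = growth ? std::exp(-r1 * t) / nu1 : 1.0 / nu1;
    double inv2_now = growth ? std::exp(-r2 * t) / nu2 : 1.0 / nu2;
    double b1 = growth ? std::max(inv1_now, 1.0 / s1) : inv1_now;
    double b2 = growth ? std::max(inv2_now, 1.0 / s2) : inv2_now;
    double rc1 = 0.5 * k1 * (k1 - 1) * b1;
    double rc2 = 0.5 * k2 * (k2 - 1) * b2;
    double rm1 = k1 * m12 / 2.0;
    double rm2 = k2 * m21 / 2.0;
    double rtot = rc1 + rc2 + rm1 + rm2;
    if (rtot <= 0) { accumulate(T - t); t = T; break; }
    double dt = R::rexp(1.0 / rtot);
    if (t + dt >= T) { accumulate(T - t); t = T; break; }
    accumulate(dt);
    t += dt;
    double u = R::runif(0.0, rtot);
    if (u < rc1) {
      double inv1_t = growth ? std::exp(-r1 * t) / nu1 : 1.0 / nu1;
      if (!growth || R::runif(0.0, 1.0) < inv1_t / b1) {
        int a, b; pick_pair_in_pop(1, a, b); merge_pair(a, b, t);
      }
    } else if (u < rc1 + rc2) {
      double inv2_t = growth ? std::exp(-r2 * t) / nu2 : 1.0 / nu2;
      if (!growth || R::runif(0.0, 1.0) < inv2_t / b2) {
        int a, b; pick_pair_in_pop(2, a, b); merge_pair(a, b, t);
      }
    } else if (u < rc1 + rc2 + rm1) {
      int i = (int)std::floor(R::runif(0.0, 1.0) * k1);
      if (i >= k1) i = k1 - 1;
      lin[nth_in_pop(1, i)].pop = 2;
    } else {
      int i = (int)std::floor(R::runif(0.0, 1.0) * k2);
      if (i >= k2) i = k2 - 1;
      lin[nth_in_pop(2, i)].pop = 1;
    }
  }

  // Phase 2: ancestral panmictic population of size 1.
  for (size_t l = 0; l < lin.size(); ++l) lin[l].pop = 1;
  while (lin.size() > 1) {
    int k = (int)lin.size();
    double rate = 0.5 * k * (k - 1);
    double dt = rao_blackwell ? 1.0 / rate : R::rexp(1.0 / rate);
    accumulate(dt);
    t += dt;
    int a, b; pick_pair_in_pop(1, a, b); merge_pair(a, b, t);
  }
}

// [[Rcpp::export]]
NumericMatrix coal_branch_grid_cpp(int n_reps, int n1, int n2,
                                   double nu1, double nu2, double T,
                                   double m12, double m21,
                                   double s1, bool growth) {
  NumericMatrix grid(n1 + 1, n2 + 1);
  std::vector<Lineage> buf;
  for (int r = 0; r < n_reps; ++r) {
    sim_one(n1, n2, nu1, nu2, T, m12, m21, s1, growth,
            REAL(grid), nullptr, nullptr, buf);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < grid.size(); ++i) grid[i] /= n_reps;
  return grid;
}

// [[Rcpp::export]]
List coal_genealogy_cpp(int n1, int n2,
                        double nu1, double nu2, double T,
                        double m12, double m21,
                        double s1, bool growth) {
  int n = n1 + n2;
  std::vector<int> parent(2 * n - 1, -1);
  std::vector<double> times(2 * n - 1, 0.0);
  std::vector<Lineage> buf;
  sim_one(n1, n2, nu1, nu2, T, m12, m21, s1, growth,
          nullptr, &parent, &times, buf);
  IntegerVector pop(n);
  for (int i = 0; i < n; ++i) pop[i] = (i < n1) ? 1 : 2;
  return List::create(_["parent"] = wrap(parent),
                      _["time"] = wrap(times),
                      _["leaf_pop"] = pop);
}
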