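#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Energy of an assignment under H = -sum_{i<j, same} (W_ij - gamma*p).
static double full_energy(const NumericMatrix &w, double gp,
                          const std::vector<int> &sigma) {
  const int k = w.nrow();
  double e = 0.0;
  for (int i = 0; i < k - 1; ++i)
    for (int j = i + 1; j < k; ++j)
      if (sigma[i] == sigma[j]) e -= (w(i, j) - gp);
  return e;
}

// Single simulated-annealing trial for the Reichardt-Bornholdt spin glass.
// q = k spin states, single-spin Metropolis updates, geometric cooling,
// best-visited state returned. Deterministic given seed (std::mt19937,
// raw 32-bit draws mapped to [0,1) by ldexp, so no library-specific
// distribution code is involved).
// [[Rcpp::export]]
List anneal_cpp(NumericMatrix w, double p, double gamma,
                double initial_temperature, double cooling_factor,
                int sweeps_per_temperature, double min_temperature,
                int max_stale, int seed) {
  const int k = w.nrow();
  const double gp = gamma * p;
  std::mt19937 gen(static_cast<unsigned>(seed));
  auto runif01 = [&]() { return std::ldexp(static_cast<double>(gen()), -32); };
  auto rint = [&](int n) {   // uniform on 0..n-1
    return static_cast<int>(runif01() * n) % n;
  };

  std::vector<int> sigma(k);
  for (int i = 0; i < k; ++i) sigma[i] = rint(k);
  double energy = full_energy(w, gp, sigma);
  const double initial_energy = energy;
  std::vector<int> best_sigma = sigma;
  double best_energy = energy;

  // local field: cost change of moving node i from state a to state b is
  // sum_{j!=i, sigma_j=a}(w_ij - gp) - sum_{j!=i, sigma_j=b}(w_ij - gp)
  auto link_sum = [&](int i, int state) {
    double s = 0.0;
    for (int j = 0; j < k; ++j)
      if (j != i && sigma[j] == state) s += w(i, j) - gp;
    return s;
  };

  double temp = initial_temperature;
  if (temp <= 0) {
    // calibrate: mean uphill step from the initial state accepted w.p. ~0.9
    double up = 0.0; int nup = 0;
    for (int t = 0; t < 20 * k; ++t) {
      int i = rint(k);
      int b = rint(k);
      if (b == sigma[i]) continue;
      double d = link_sum(i, sigma[i]) - link_sum(i, b);
      if (d > 0) { up += d; ++nup; }
    }
    temp = (nup > 0) ? (up / nup) / std::log(1.0 / 0.9) : 1.0;
    if (temp < min_temperature) temp = 10.0 * min_temperature;
  }

  // a temperature block counts as stale only if it neither improved the
  // best energy nor moved at all (frozen); stopping on "no improvement"
  // alone would abort during the high-temperature random-walk phase
  int stale = 0;
  while (temp > min_temperature && stale < max_stale) {
    bool improved = false;
    int accepted = 0;
    for (int sweep = 0; sweep < sweeps_per_temperature; ++sweep) {
      for (int u = 0; u < k; ++u) {
        int i = rint(k);
        int b = rint(k);
        if (b == sigma[i]) continue;
        double d = link_sum(i, sigma[i]) - link_sum(i, b);
        if (d <= 0 || runif01() < std::exp(-d / temp)) {
          sigma[i] = b;
          energy += d;
          ++accepted;
          if (energy < best_energy - 1e-12) {
            best_energy = energy;
            best_sigma = sigma;
            improved = true;
          }
        }
      }
    }
    bool frozen = accepted * 100 < sweeps_per_temperature * k;
    stale = (improved || !frozen) ? 0 : stale + 1;
    temp *= cooling_factor;
  }

  // zero-temperature polish: greedy single-spin descent on the best state.
  // Exact ties are broken toward splitting: an energy-neutral move of a
  // node out of a multi-member group into an empty spin state is taken, so
  // degenerate groupings (isolated nodes, empty networks with p = 0)
  // resolve to singletons. Never increases the energy.
  sigma = best_sigma;
  energy = full_energy(w, gp, sigma);
  std::vector<int> count(k, 0);
  for (int i = 0; i < k; ++i) ++count[sigma[i]];
  bool moved = true;
  while (moved) {
    moved = false;
    for (int i = 0; i < k; ++i) {
      double cur = link_sum(i, sigma[i]);
      int arg = sigma[i];
      double best_gain = 0.0;
      for (int b = 0; b < k; ++b) {
        if (b == sigma[i]) continue;
        double d = cur - link_sum(i, b);
        if (d < best_gain - 1e-12) { best_gain = d; arg = b; }
      }
      if (arg == sigma[i] && count[sigma[i]] > 1 &&
          std::fabs(cur) <= 1e-12) {
        for (int b = 0; b < k; ++b)
          if (count[b] == 0) { arg = b; best_gain = cur; break; }
      }
      if (arg != sigma[i]) {
        --count[sigma[i]];
        ++count[arg];
        sigma[i] = arg;
        energy += best_gain;
        moved = true;
      }
    }
  }
  best_sigma = sigma;
  // recompute exactly (guards against float drift in the incremental sum)
  best_energy = full_energy(w, gp, best_sigma);
  IntegerVector assignment(k);
  for (int i = 0; i < k; ++i) assignment[i] = best_sigma[i] + 1;
  return List::create(_["assignment"] = assignment,
                      _["energy"] = best_energy,
                      _["initial_energy"] = initial_energy);
}
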