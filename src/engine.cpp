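#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the awareness/adoption agent-based model.
//
// States: 0 unaware, 1 aware, 2 adopted (absorbing, monotone ladder).
// Each step runs two phases: awareness first, then adoption conditional on
// awareness, each over a fresh uniform random permutation of agents.
// Neighbor counts over the union of the offline and online layers are kept
// incrementally, so one step costs O(n + transitions * degree).
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R makes
// runs exactly reproducible.

static inline double link_prob(double L, int link, double g0, double g1) {
  if (link == 0) {                      // clipped linear
    if (L < 0.0) return 0.0;
    if (L > 1.0) return 1.0;
    return L;
  }
  return 1.0 / (1.0 + std::exp(-(g0 + g1 * L)));  // logistic
}

static void fisher_yates(std::vector<int>& perm) {
  const int n = (int)perm.size();
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int n,
                IntegerVector adj_ptr,   // length n+1, 0-based CSR offsets
                IntegerVector adj_nbr,   // 0-based neighbor ids
                NumericVector exposure,  // per-agent media exposure term
                NumericVector b_step,    // per-agent baseline step hazard
                double alpha, double w_bg, double omega_a,
                double beta_m, double beta_s, int tau,
                int link, double gamma0, double gamma1,
                int n_steps, int t_start,
                bool sequential,
                IntegerVector init_state,
                IntegerVector init_t_aware,
                IntegerVector init_t_adopt) {
  std::vector<int> state(n), t_aware(n), t_adopt(n);
  std::vector<int> n_aware(n, 0), n_adopt(n, 0), deg(n, 0);
  for (int i = 0; i < n; ++i) {
    state[i] = init_state[i];
    t_aware[i] = init_t_aware[i];
    t_adopt[i] = init_t_adopt[i];
    deg[i] = adj_ptr[i + 1] - adj_ptr[i];
  }
  // aware = state >= 1 (adopters count as aware in the spillover term)
  for (int i = 0; i < n; ++i) {
    if (state[i] >= 1) {
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) n_aware[adj_nbr[e]]++;
    }
    if (state[i] == 2) {
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) n_adopt[adj_nbr[e]]++;
    }
  }

  std::vector<int> perm(n), pending;
  pending.reserve(n);

  for (int s = 0; s < n_steps; ++s) {
    const int t = t_start + s;

    // Phase 1: awareness
    fisher_yates(perm);
    pending.clear();
    for (int idx = 0; idx < n; ++idx) {
      const int i = perm[idx];
      if (state[i] != 0) continue;
      double frac = deg[i] > 0 ? (double)n_aware[i] / deg[i] : 0.0;
      double L = w_bg + exposure[i] + omega_a * frac;
      double p = link_prob(L, link, gamma0, gamma1);
      if (unif_rand() < p) {
        state[i] = 1;
        t_aware[i] = t;
        if (sequential) {
          for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) n_aware[adj_nbr[e]]++;
        } else {
          pending.push_back(i);
        }
      }
    }
    if (!sequential) {
      for (int i : pending)
        for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) n_aware[adj_nbr[e]]++;
    }

    // Phase 2: adoption, conditional on awareness
    fisher_yates(perm);
    pending.clear();
    for (int idx = 0; idx < n; ++idx) {
      const int i = perm[idx];
      if (state[i] != 1) continue;
      double reinf = 0.0;
      if (n_adopt[i] >= tau && deg[i] > 0)
        reinf = (double)n_adopt[i] / deg[i];
      double L = alpha * b_step[i] + beta_m * exposure[i] + beta_s * reinf;
      double p = link_prob(L, link, gamma0, gamma1);
      if (unif_rand() < p) {
        state[i] = 2;
        t_adopt[i] = t;
        if (sequential) {
          for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) n_adopt[adj_nbr[e]]++;
        } else {
          pending.push_back(i);
        }
      }
    }
    if (!sequential) {
      for (int i : pending)
        for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) n_adopt[adj_nbr[e]]++;
    }
  }

  return List::create(_["state"] = IntegerVector(state.begin(), state.end()),
                      _["t_aware"] = IntegerVector(t_aware.begin(), t_aware.end()),
                      _["t_adopt"] = IntegerVector(t_adopt.begin(), t_adopt.end()));
}
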