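#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis simulated annealing on a Potts energy landscape with an
// optional low-complexity penalty E_new = E_potts - a * log Omega(S).
// Single-site uniform proposals; incremental O(degree) energy deltas;
// best-seen bookkeeping. Uses R's RNG (deterministic under set.seed).
//
// pair_mats is the np x 20 x 20 array flattened column-major.
// Adjacency CSR: for position i (0-based), entries adj_start[i]..adj_start[i+1]-1
// give (pair index p, partner position u, orient==1 if rows of table p are
// letters at i).
// [[Rcpp::export(name = ".anneal_potts_cpp")]]
List anneal_potts_cpp(NumericMatrix self, NumericVector pair_mats, int np,
                      IntegerVector pair_i, IntegerVector pair_j,
                      IntegerVector adj_start, IntegerVector adj_pair,
                      IntegerVector adj_other, IntegerVector adj_orient,
                      IntegerVector start_seq, double n_cycles_d,
                      double kT_start, double kT_end, bool geometric,
                      double comp_weight) {
  const int L = self.nrow();
  const long long n_cycles = (long long) n_cycles_d;
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = start_seq[i] - 1;  // 0-based letters

  // counts for the complexity penalty
  std::vector<int> cnt(20, 0);
  for (int i = 0; i < L; ++i) cnt[s[i]]++;
  double logOmega = std::lgamma(L + 1.0);
  for (int m = 0; m < 20; ++m) logOmega -= std::lgamma(cnt[m] + 1.0);

  // current Potts energy
  double e = 0.0;
  for (int i = 0; i < L; ++i) e += self(i, s[i]);
  for (int p = 0; p < np; ++p) {
    int a = pair_i[p] - 1, b = pair_j[p] - 1;
    e += pair_mats[p + np * s[a] + np * 20 * s[b]];
  }
  double obj = e - comp_weight * logOmega;

  std::vector<int> best(s);
  double best_e = e, best_obj = obj, best_logOmega = logOmega;

  GetRNGstate();
  const double lratio = (n_cycles > 1) ? std::log(kT_end / kT_start) / (double)(n_cycles - 1) : 0.0;
  const double lstep = (n_cycles > 1) ? (kT_end - kT_start) / (double)(n_cycles - 1) : 0.0;
  for (long long t = 0; t < n_cycles; ++t) {
    double kT = geometric ? kT_start * std::exp(lratio * (double) t)
                          : kT_start + lstep * (double) t;
    int pos = (int)(unif_rand() * L);
    if (pos >= L) pos = L - 1;
    int cur = s[pos];
    int prop = (int)(unif_rand() * 19.0);
    if (prop >= 19) prop = 18;
    if (prop >= cur) prop += 1;  // uniform over the 19 other letters
    // Potts delta
    double de = self(pos, prop) - self(pos, cur);
    for (int a = adj_start[pos]; a < adj_start[pos + 1]; ++a) {
      int p = adj_pair[a];
      int u = s[adj_other[a]];
      if (adj_orient[a] == 1) {
        de += pair_mats[p + np * prop + np * 20 * u] -
              pair_mats[p + np * cur + np * 20 * u];
      } else {
        de += pair_mats[p + np * u + np * 20 * prop] -
              pair_mats[p + np * u + np * 20 * cur];
      }
    }
    double dobj = de;
    double dlo = 0.0;
    if (comp_weight != 0.0) {
      // counts change: cnt[cur]--, cnt[prop]++
      dlo = std::log((double) cnt[cur]) - std::log((double) cnt[prop] + 1.0);
      dobj = de - comp_weight * dlo;
    }
    if (dobj <= 0.0 || unif_rand() < std::exp(-dobj / kT)) {
      s[pos] = prop;
      cnt[cur]--; cnt[prop]++;
      e += de;
      logOmega += dlo;
      obj += dobj;
      if (obj < best_obj) {
        best_obj = obj; best_e = e; best = s; best_logOmega = logOmega;
      }
    }
  }
  PutRNGstate();

  IntegerVector out(L), fin(L);
  for (int i = 0; i < L; ++i) { out[i] = best[i] + 1; fin[i] = s[i] + 1; }
  return List::create(_["sequence"] = out, _["energy"] = best_e,
                      _["objective"] = best_obj,
                      _["log_omega"] = best_logOmega,
                      _["final_sequence"] = fin, _["final_energy"] = e);
}
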