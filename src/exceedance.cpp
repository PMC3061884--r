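#include <Rcpp.h>
#include <cstdint>

// Monte-Carlo exceedance count for one category pair.
//
// Per iteration both columns are redrawn independently: F carriers are
// sampled sequentially without replacement, each draw proportional to the
// remaining (renormalized) weights. The Jaccard index of the simulated
// pair is compared with the observed one; >= counts toward C.
//
// The comparison J* >= J_obs is done in integer arithmetic:
//   N11* / (Fj + Fk - N11*)  >=  N11 / (Fj + Fk - N11)
// <=> N11* * (Fj + Fk - N11) >= N11 * (Fj + Fk - N11*),
// exact because both denominators are non-negative integers (a zero
// denominator only occurs when the corresponding N11 equals Fj + Fk,
// i.e. J = 1, handled correctly by the cross product).
//
// A private xorshift-free mt19937 stream seeded per pair keeps results
// independent of pair-processing order and of R's global RNG.

namespace {

struct Mt {
  // minimal mt19937 (32-bit), self-contained for bitwise reproducibility
  uint32_t mt[624];
  int idx;
  explicit Mt(uint32_t seed) {
    mt[0] = seed;
    for (int i = 1; i < 624; ++i)
      mt[i] = 1812433253u * (mt[i - 1] ^ (mt[i - 1] >> 30)) + (uint32_t)i;
    idx = 624;
  }
  uint32_t next() {
    if (idx >= 624) {
      for (int i = 0; i < 624; ++i) {
        uint32_t y = (mt[i] & 0x80000000u) | (mt[(i + 1) % 624] & 0x7fffffffu);
        mt[i] = mt[(i + 397) % 624] ^ (y >> 1);
        if (y & 1u) mt[i] ^= 2567483615u;
      }
      idx = 0;
    }
    uint32_t y = mt[idx++];
    y ^= y >> 11;
    y ^= (y << 7) & 2636928640u;
    y ^= (y << 15) & 4022730752u;
    y ^= y >> 18;
    return y;
  }
  double unif() { return (next() + 0.5) / 4294967296.0; }
};

// draw `f` distinct indices into sel[], weighted without replacement
inline void draw_column(std::vector<double>& w, double total, int f,
                        std::vector<int>& sel, Mt& rng) {
  const int n = (int)w.size();
  for (int d = 0; d < f; ++d) {
    double u = rng.unif() * total;
    double acc = 0.0;
    int pick = -1;
    for (int i = 0; i < n; ++i) {
      acc += w[i];
      if (u <= acc && w[i] > 0.0) { pick = i; break; }
    }
    if (pick < 0) { // numeric guard: fall back to last positive weight
      for (int i = n - 1; i >= 0; --i)
        if (w[i] > 0.0) { pick = i; break; }
    }
    sel[d] = pick;
    total -= w[pick];
    w[pick] = 0.0;
  }
}

} // namespace

// [[Rcpp::export]]
int cpp_pair_exceedance(Rcpp::NumericVector weights, int fj, int fk,
                        int n11_obs, int S, double seed) {
  const int n = weights.size();
  if (fj < 0 || fk < 0 || fj > n || fk > n)
    Rcpp::stop("carrier count outside [0, n]");
  int npos = 0;
  for (int i = 0; i < n; ++i) if (weights[i] > 0.0) ++npos;
  if (fj > npos || fk > npos)
    Rcpp::stop("carrier count exceeds number of positively weighted samples");

  const long long dobs = (long long)fj + fk - n11_obs;
  Mt rng((uint32_t)((int64_t)seed & 0xffffffffLL));
  std::vector<double> base(weights.begin(), weights.end());
  double base_total = 0.0;
  for (int i = 0; i < n; ++i) base_total += base[i];

  std::vector<double> w(n);
  std::vector<int> selj(fj > 0 ? fj : 1), selk(fk > 0 ? fk : 1);
  std::vector<char> mark(n, 0);
  int C = 0;
  for (int s = 0; s < S; ++s) {
    w = base;
    draw_column(w, base_total, fj, selj, rng);
    w = base;
    draw_column(w, base_total, fk, selk, rng);
    for (int d = 0; d < fj; ++d) mark[selj[d]] = 1;
    int n11 = 0;
    for (int d = 0; d < fk; ++d) n11 += mark[selk[d]];
    for (int d = 0; d < fj; ++d) mark[selj[d]] = 0;
    long long dstar = (long long)fj + fk - n11;
    if ((long long)n11 * dobs >= (long long)n11_obs * dstar) ++C;
  }
  return C;
}
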