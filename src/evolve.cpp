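// Gillespie simulation of GY94 codon substitution along coalescent
// genealogies.  Two modes:
//
//  * cpp_evolve_arg: forward replay of the full ARG event list with every
//    lineage carrying a complete codon sequence.  Recombination joins
//    splice the two parental sequences at the nucleotide breakpoint, so
//    codons split by an intracodon breakpoint evolve at nucleotide
//    resolution with substitution rates conditional on the current states
//    of the partner nucleotides.
//  * cpp_evolve_marginal: each codon site independently follows the
//    marginal tree of its first nucleotide (diagnostic fallback).
//
// Branch lengths are coalescent units (2N generations); the per-codon-site
// event rate is theta/(2L) * site_rate * |q_ii|, Q normalised to one
// expected substitution per codon per unit branch length.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct CodonCTMC {
  int K;
  std::vector<double> qexit;                      // -q_ii
  std::vector<std::vector<int>> nbr;              // reachable codons
  std::vector<std::vector<double>> nbr_rate;      // q_ij for those
  explicit CodonCTMC(const NumericMatrix& Q) : K(Q.nrow()) {
    qexit.resize(K);
    nbr.resize(K);
    nbr_rate.resize(K);
    for (int i = 0; i < K; ++i) {
      qexit[i] = -Q(i, i);
      for (int j = 0; j < K; ++j) {
        if (j != i && Q(i, j) > 0.0) {
          nbr[i].push_back(j);
          nbr_rate[i].push_back(Q(i, j));
        }
      }
    }
  }
  template <class RNG>
  int jump(int i, RNG& rng, std::uniform_real_distribution<double>& U) const {
    double v = U(rng) * qexit[i];
    const std::vector<double>& r = nbr_rate[i];
    for (size_t m = 0; m < r.size(); ++m) {
      if (v < r[m]) return nbr[i][m];
      v -= r[m];
    }
    return nbr[i].back();
  }
};

template <class RNG>
int draw_categorical(const std::vector<double>& cum, RNG& rng,
                     std::uniform_real_distribution<double>& U) {
  const double u = U(rng) * cum.back();
  int lo = 0, hi = static_cast<int>(cum.size()) - 1;
  while (lo < hi) {
    const int mid = (lo + hi) / 2;
    if (u < cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// evolve one single site for duration dt at total rate base*qexit
template <class RNG>
int evolve_site(int state, double dt, double base, const CodonCTMC& ctmc,
                RNG& rng, std::uniform_real_distribution<double>& U) {
  if (base <= 0.0) return state;
  double t = 0.0;
  while (true) {
    const double rate = base * ctmc.qexit[state];
    if (rate <= 0.0) return state;
    t += -std::log(1.0 - U(rng)) / rate;
    if (t >= dt) return state;
    state = ctmc.jump(state, rng, U);
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_evolve_arg(int n, int L, int n_lineages,
                             NumericVector ev_time, IntegerVector ev_type,
                             IntegerVector ev_a, IntegerVector ev_b,
                             IntegerVector ev_c, IntegerVector ev_bp,
                             NumericMatrix Q, NumericVector freqs,
                             NumericVector site_rates, double theta,
                             IntegerMatrix codon_nt, IntegerVector nt_to_codon,
                             int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                      0xA0761D6478BD642FULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const CodonCTMC ctmc(Q);
  const int nev = ev_time.size();

  std::vector<double> base(L);
  for (int s = 0; s < L; ++s) base[s] = theta / (2.0 * L) * site_rates[s];

  std::vector<double> cumfreq(freqs.size());
  double acc = 0.0;
  for (int i = 0; i < freqs.size(); ++i) { acc += freqs[i]; cumfreq[i] = acc; }

  std::vector<std::vector<uint8_t>> seq_of(n_lineages);
  std::vector<int> alive;

  // root sequence: stationary draw at the grand MRCA
  if (nev == 0) stop("event list is empty");
  const int root = ev_a[nev - 1];
  seq_of[root].resize(L);
  for (int s = 0; s < L; ++s)
    seq_of[root][s] = static_cast<uint8_t>(draw_categorical(cumfreq, rng, U));
  alive.push_back(root);
  double cur_t = ev_time[nev - 1];

  std::vector<double> r(L);
  auto evolve_branch = [&](std::vector<uint8_t>& s, double dt) {
    if (dt <= 0.0) return;
    double tot = 0.0;
    for (int i = 0; i < L; ++i) {
      r[i] = base[i] * ctmc.qexit[s[i]];
      tot += r[i];
    }
    double tt = 0.0;
    while (tot > 1e-14) {
      tt += -std::log(1.0 - U(rng)) / tot;
      if (tt >= dt) break;
      double u = U(rng) * tot;
      int site = 0;
      for (; site < L - 1; ++site) {
        if (u < r[site]) break;
        u -= r[site];
      }
      const int i = s[site];
      const int j = ctmc.jump(i, rng, U);
      s[site] = static_cast<uint8_t>(j);
      tot -= r[site];
      r[site] = base[site] * ctmc.qexit[j];
      tot += r[site];
    }
  };

  auto drop_alive = [&alive](int id) {
    for (size_t i = 0; i < alive.size(); ++i)
      if (alive[i] == id) { alive.erase(alive.begin() + i); return; }
    stop("internal error: lineage not alive");
  };

  for (int e = nev - 1; e >= 0; --e) {
    const double dt = cur_t - ev_time[e];
    if (dt > 0.0)
      for (size_t i = 0; i < alive.size(); ++i) evolve_branch(seq_of[alive[i]], dt);
    cur_t = ev_time[e];

    if (ev_type[e] == 0) {
      // backward coalescence -> forward split: children copy the parent
      const int parent = ev_a[e], c1 = ev_b[e], c2 = ev_c[e];
      seq_of[c1] = seq_of[parent];
      seq_of[c2] = seq_of[parent];
      drop_alive(parent);
      std::vector<uint8_t>().swap(seq_of[parent]);
      alive.push_back(c1);
      alive.push_back(c2);
    } else {
      // backward recombination -> forward join: splice left/right parents
      const int child = ev_a[e], pl = ev_b[e], pr = ev_c[e];
      const int bp = ev_bp[e];
      const int csplit = bp / 3, off = bp % 3;
      std::vector<uint8_t> s = seq_of[pl];
      for (int c = csplit; c < L; ++c) s[c] = seq_of[pr][c];
      if (off != 0) {
        int nt[3];
        for (int p = 0; p < 3; ++p)
          nt[p] = codon_nt(p < off ? seq_of[pl][csplit] : seq_of[pr][csplit], p);
        const int comp = nt_to_codon[nt[0] * 16 + nt[1] * 4 + nt[2]];
        // a chimeric stop codon cannot exist: keep the left parent's codon
        s[csplit] = comp >= 0 ? static_cast<uint8_t>(comp) : seq_of[pl][csplit];
      }
      seq_of[child] = s;
      drop_alive(pl);
      drop_alive(pr);
      std::vector<uint8_t>().swap(seq_of[pl]);
      std::vector<uint8_t>().swap(seq_of[pr]);
      alive.push_back(child);
    }
  }

  if (cur_t > 0.0)
    for (size_t i = 0; i < alive.size(); ++i)
      evolve_branch(seq_of[alive[i]], cur_t);

  if (static_cast<int>(alive.size()) != n)
    stop("internal error: tips alive at time 0 != n");

  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    if (seq_of[i].empty()) stop("internal error: tip without sequence");
    for (int s = 0; s < L; ++s) out(i, s) = seq_of[i][s] + 1;  // 1-based
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_evolve_marginal(int n, int L,
                                  NumericVector tn_time, IntegerVector tn_left,
                                  IntegerVector tn_right, IntegerVector seg_a,
                                  IntegerVector seg_root, NumericMatrix Q,
                                  NumericVector freqs, NumericVector site_rates,
                                  double theta, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                      0xE7037ED1A0B428DBULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const CodonCTMC ctmc(Q);

  std::vector<double> cumfreq(freqs.size());
  double acc = 0.0;
  for (int i = 0; i < freqs.size(); ++i) { acc += freqs[i]; cumfreq[i] = acc; }

  IntegerMatrix out(n, L);
  const int nseg = seg_a.size();

  for (int s = 0; s < L; ++s) {
    const int nt0 = 3 * s;
    int seg = nseg - 1;
    for (int g = 0; g < nseg - 1; ++g)
      if (nt0 < seg_a[g + 1]) { seg = g; break; }
    const int root = seg_root[seg];
    const double base = theta / (2.0 * L) * site_rates[s];

    // preorder walk with explicit stack
    std::vector<std::pair<int, int>> stack;  // (node, state)
    const int rstate = draw_categorical(cumfreq, rng, U);
    stack.push_back(std::make_pair(root, rstate));
    while (!stack.empty()) {
      const int node = stack.back().first;
      const int state = stack.back().second;
      stack.pop_back();
      if (tn_left[node] < 0) {
        out(node, s) = state + 1;
        continue;
      }
      for (int which = 0; which < 2; ++which) {
        const int ch = which == 0 ? tn_left[node] : tn_right[node];
        const double dt = tn_time[node] - tn_time[ch];
        stack.push_back(
            std::make_pair(ch, evolve_site(state, dt, base, ctmc, rng, U)));
      }
    }
  }
  return out;
}

// Endpoint sampler for a single codon site on one branch: independent
// Gillespie runs used to cross-check against the matrix exponential.
// [[Rcpp::export]]
IntegerVector cpp_branch_endpoints(NumericMatrix Q, int start, double t,
                                   double rate, int nreps, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                      0x8EBC6AF09C88C6E3ULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const CodonCTMC ctmc(Q);
  IntegerVector out(nreps);
  for (int r = 0; r < nreps; ++r)
    out[r] = evolve_site(start - 1, t, rate, ctmc, rng, U) + 1;
  return out;
}
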