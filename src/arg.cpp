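// Backward-time simulation of the neutral constant-size coalescent with
// recombination (Hudson scaling: time in units of 2N generations, pairwise
// coalescence rate 1, per-lineage recombination rate rho/2 for a lineage
// whose active ancestral span covers the whole alignment).
//
// Lineages carry interval sets of ancestral material with per-segment
// descendant counts; a segment whose descendant count reaches n has found
// its MRCA, is recorded as a fixed segment with its marginal tree root,
// and stops contributing recombination rate.  The process keeps running
// until a single lineage remains so that the recorded event list forms a
// connected graph usable for forward sequence simulation.
#include <Rcpp.h>
#include <random>
#include <map>
#include <utility>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Seg {
  int a, b;     // half-open nucleotide interval [a, b)
  int node;     // marginal tree node carried for this interval
  int ndesc;    // number of sampled tips below `node` for this interval
};

struct TreeStore {
  std::vector<double> time;
  std::vector<int> left, right;
  int add(double t, int l, int r) {
    time.push_back(t);
    left.push_back(l);
    right.push_back(r);
    return static_cast<int>(time.size()) - 1;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_arg(int n, int l_nt, double rho, int seed) {
  if (n < 2) stop("need at least 2 samples");
  if (l_nt < 1) stop("alignment length must be positive");
  if (rho < 0) stop("rho must be non-negative");

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                      0xD1B54A32D192ED03ULL);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  TreeStore ts;
  for (int i = 0; i < n; ++i) ts.add(0.0, -1, -1);  // tips

  std::vector<std::vector<Seg>> segs_of(n);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) {
    segs_of[i].push_back(Seg{0, l_nt, i, 1});
    active[i] = i;
  }

  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_a, ev_b, ev_c, ev_bp;  // type 0 coal, 1 recomb
  std::vector<int> fs_a, fs_b, fs_root;
  std::vector<double> fs_time;

  double t = 0.0;
  int n_recomb = 0;

  while (active.size() > 1) {
    const int k = static_cast<int>(active.size());

    double tot_links = 0.0;
    std::vector<double> links;
    if (rho > 0.0 && l_nt > 1) {
      links.resize(k, 0.0);
      for (int i = 0; i < k; ++i) {
        const std::vector<Seg>& sg = segs_of[active[i]];
        if (!sg.empty()) {
          int nl = sg.back().b - sg.front().a - 1;
          if (nl > 0) {
            links[i] = nl;
            tot_links += nl;
          }
        }
      }
    }
    const double rate_c = 0.5 * k * (k - 1);
    const double rate_r =
        (tot_links > 0.0) ? rho / (2.0 * (l_nt - 1)) * tot_links : 0.0;
    const double tot = rate_c + rate_r;

    t += -std::log(1.0 - U(rng)) / tot;

    if (U(rng) * tot < rate_c) {
      // ---- coalescence of a uniform unordered pair ----
      int i1 = static_cast<int>(U(rng) * k);
      if (i1 >= k) i1 = k - 1;
      int i2 = static_cast<int>(U(rng) * (k - 1));
      if (i2 >= k - 1) i2 = k - 2;
      if (i2 >= i1) ++i2;
      const int la = active[i1], lb = active[i2];

      std::vector<Seg> A = segs_of[la], B = segs_of[lb];
      std::vector<Seg> merged;
      std::map<std::pair<int, int>, int> memo;  // child pair -> new node

      auto push = [&merged](int a, int b, int node, int nd) {
        if (!merged.empty() && merged.back().b == a &&
            merged.back().node == node && merged.back().ndesc == nd) {
          merged.back().b = b;
        } else {
          merged.push_back(Seg{a, b, node, nd});
        }
      };

      size_t i = 0, j = 0;
      while (i < A.size() && j < B.size()) {
        Seg& x = A[i];
        Seg& y = B[j];
        if (x.b <= y.a) { push(x.a, x.b, x.node, x.ndesc); ++i; continue; }
        if (y.b <= x.a) { push(y.a, y.b, y.node, y.ndesc); ++j; continue; }
        const int oa = std::max(x.a, y.a);
        if (x.a < oa) push(x.a, oa, x.node, x.ndesc);
        if (y.a < oa) push(y.a, oa, y.node, y.ndesc);
        const int ob = std::min(x.b, y.b);
        // overlapped [oa, ob): both lineages ancestral -> coalesce here
        std::pair<int, int> key(std::min(x.node, y.node),
                                std::max(x.node, y.node));
        int w;
        std::map<std::pair<int, int>, int>::iterator it = memo.find(key);
        if (it != memo.end()) {
          w = it->second;
        } else {
          w = ts.add(t, x.node, y.node);
          memo[key] = w;
        }
        const int nd = x.ndesc + y.ndesc;
        if (nd == n) {
          fs_a.push_back(oa);
          fs_b.push_back(ob);
          fs_root.push_back(w);
          fs_time.push_back(t);
        } else {
          push(oa, ob, w, nd);
        }
        if (x.b == ob) ++i; else x.a = ob;
        if (y.b == ob) ++j; else y.a = ob;
      }
      for (; i < A.size(); ++i) push(A[i].a, A[i].b, A[i].node, A[i].ndesc);
      for (; j < B.size(); ++j) push(B[j].a, B[j].b, B[j].node, B[j].ndesc);

      const int lz = static_cast<int>(segs_of.size());
      segs_of.push_back(merged);
      ev_time.push_back(t);
      ev_type.push_back(0);
      ev_a.push_back(lz);
      ev_b.push_back(la);
      ev_c.push_back(lb);
      ev_bp.push_back(-1);

      // replace the two coalescing lineages by the merged one
      if (i1 > i2) std::swap(i1, i2);
      active[i1] = lz;
      active.erase(active.begin() + i2);
    } else {
      // ---- recombination: lineage weighted by active links ----
      double u = U(rng) * tot_links;
      int pick = -1;
      for (int i = 0; i < k; ++i) {
        if (links[i] > 0.0) {
          if (u < links[i]) { pick = i; break; }
          u -= links[i];
        }
      }
      if (pick < 0) {
        for (int i = k - 1; i >= 0; --i)
          if (links[i] > 0.0) { pick = i; break; }
      }
      const int lu = active[pick];
      const std::vector<Seg>& sg = segs_of[lu];
      const int lo = sg.front().a, hi = sg.back().b;
      // integer breakpoint uniform on the active span's interior boundaries
      int bp = lo + 1 + static_cast<int>(U(rng) * (hi - lo - 1));
      if (bp > hi - 1) bp = hi - 1;

      std::vector<Seg> L, R;
      for (size_t s = 0; s < sg.size(); ++s) {
        const Seg& x = sg[s];
        if (x.b <= bp) L.push_back(x);
        else if (x.a >= bp) R.push_back(x);
        else {
          L.push_back(Seg{x.a, bp, x.node, x.ndesc});
          R.push_back(Seg{bp, x.b, x.node, x.ndesc});
        }
      }

      const int lleft = static_cast<int>(segs_of.size());
      segs_of.push_back(L);
      const int lright = static_cast<int>(segs_of.size());
      segs_of.push_back(R);
      ev_time.push_back(t);
      ev_type.push_back(1);
      ev_a.push_back(lu);
      ev_b.push_back(lleft);
      ev_c.push_back(lright);
      ev_bp.push_back(bp);
      ++n_recomb;

      active[pick] = lleft;
      active.push_back(lright);
    }
  }

  // assemble fixed segments into a tiling of [0, l_nt)
  std::vector<size_t> ord(fs_a.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&fs_a](size_t i, size_t j) { return fs_a[i] < fs_a[j]; });
  std::vector<int> seg_a, seg_b, seg_root;
  for (size_t i = 0; i < ord.size(); ++i) {
    const int a = fs_a[ord[i]], b = fs_b[ord[i]], r = fs_root[ord[i]];
    if (!seg_a.empty() && seg_root.back() == r && seg_b.back() == a) {
      seg_b.back() = b;  // same marginal tree continues across the boundary
    } else {
      seg_a.push_back(a);
      seg_b.push_back(b);
      seg_root.push_back(r);
    }
  }
  if (seg_a.empty() || seg_a.front() != 0 || seg_b.back() != l_nt)
    stop("internal error: fixed segments do not tile the alignment");
  for (size_t i = 1; i < seg_a.size(); ++i)
    if (seg_a[i] != seg_b[i - 1])
      stop("internal error: fixed segments do not tile the alignment");

  return List::create(
      _["n"] = n, _["l_nt"] = l_nt, _["rho"] = rho,
      _["ev_time"] = wrap(ev_time), _["ev_type"] = wrap(ev_type),
      _["ev_a"] = wrap(ev_a), _["ev_b"] = wrap(ev_b),
      _["ev_c"] = wrap(ev_c), _["ev_bp"] = wrap(ev_bp),
      _["tn_time"] = wrap(ts.time), _["tn_left"] = wrap(ts.left),
      _["tn_right"] = wrap(ts.right),
      _["seg_a"] = wrap(seg_a), _["seg_b"] = wrap(seg_b),
      _["seg_root"] = wrap(seg_root),
      _["n_recomb"] = n_recomb,
      _["n_lineages"] = static_cast<int>(segs_of.size()),
      _["root_lineage"] = ev_a.empty() ? -1 : ev_a.back());
}
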