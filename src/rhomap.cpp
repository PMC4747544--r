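// Coalescent machinery: Hudson-style ancestral recombination graph simulator
// under a piecewise-constant recombination map, a two-locus structured
// coalescent sampler used to build composite-likelihood lookup tables, and a
// fast evaluator for the pairwise composite log-likelihood.
//
// Time is in units of 2N generations: pairwise coalescence rate 1,
// per-lineage recombination rate rho/2 (rho = 4Nc spanned), mutation rate
// theta/2 per site. Sample sizes are limited to 64 haplotypes so descendant
// sets fit in one 64-bit mask.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// ---------------------------------------------------------------------------
// Piecewise-constant genetic map: breaks[0]=0 < ... < breaks[m] = L (bp),
// rates[i] = rho per bp on [breaks[i], breaks[i+1]).
struct GeneticMap {
  std::vector<double> breaks;  // m+1 physical breakpoints
  std::vector<double> rates;   // m piece rates (rho per bp)
  std::vector<double> cum;     // cumulative genetic position at breaks

  void init(const NumericVector& b, const NumericVector& r) {
    breaks.assign(b.begin(), b.end());
    rates.assign(r.begin(), r.end());
    cum.resize(breaks.size());
    cum[0] = 0.0;
    for (size_t i = 1; i < breaks.size(); ++i)
      cum[i] = cum[i - 1] + rates[i - 1] * (breaks[i] - breaks[i - 1]);
  }
  double gpos(double x) const {  // physical -> genetic
    size_t i = std::upper_bound(breaks.begin(), breaks.end(), x) - breaks.begin();
    if (i == 0) return 0.0;
    if (i >= breaks.size()) return cum.back();
    return cum[i - 1] + rates[i - 1] * (x - breaks[i - 1]);
  }
  double ppos(double g) const {  // genetic -> physical (first crossing)
    size_t i = std::upper_bound(cum.begin(), cum.end(), g) - cum.begin();
    if (i == 0) return breaks[0];
    if (i >= cum.size()) return breaks.back();
    double r = rates[i - 1];
    if (r <= 0.0) return breaks[i - 1];
    return breaks[i - 1] + (g - cum[i - 1]) / r;
  }
};

struct Seg { double a, b; uint64_t desc; };

struct Lineage {
  std::vector<Seg> segs;  // sorted, non-overlapping
  double phys_len() const {
    double s = 0; for (const Seg& sg : segs) s += sg.b - sg.a; return s;
  }
};

// merge two sorted segment lists; union descendant masks on overlaps; drop
// pieces whose mask equals `full` (marginal MRCA reached there)
static std::vector<Seg> merge_segs(const std::vector<Seg>& u,
                                   const std::vector<Seg>& v,
                                   uint64_t full) {
  std::vector<double> pts;
  for (const Seg& s : u) { pts.push_back(s.a); pts.push_back(s.b); }
  for (const Seg& s : v) { pts.push_back(s.a); pts.push_back(s.b); }
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  std::vector<Seg> out;
  size_t iu = 0, iv = 0;
  for (size_t i = 0; i + 1 < pts.size(); ++i) {
    double a = pts[i], b = pts[i + 1];
    double mid = 0.5 * (a + b);
    while (iu < u.size() && u[iu].b <= a) ++iu;
    while (iv < v.size() && v[iv].b <= a) ++iv;
    uint64_t d = 0;
    if (iu < u.size() && u[iu].a <= mid && mid < u[iu].b) d |= u[iu].desc;
    if (iv < v.size() && v[iv].a <= mid && mid < v[iv].b) d |= v[iv].desc;
    if (d != 0 && d != full) {
      if (!out.empty() && out.back().b == a && out.back().desc == d)
        out.back().b = b;
      else
        out.push_back({a, b, d});
    }
  }
  return out;
}

struct Mut { double pos; uint64_t desc; };

// [[Rcpp::export(name = ".cpp_sim_arg")]]
List cpp_sim_arg(int n, double L, NumericVector map_breaks,
                 NumericVector map_rates, double theta_site,
                 double max_events = 5e6) {
  if (n < 2 || n > 64) stop("n must be in [2, 64]");
  if (L <= 0) stop("zero-length region");
  GeneticMap gm; gm.init(map_breaks, map_rates);
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);

  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i)
    lin[i].segs.push_back({0.0, L, 1ULL << i});

  std::vector<Mut> muts;
  double ev = 0;
  while (!lin.empty()) {
    if (++ev > max_events) stop("event budget exceeded in ARG simulation");
    int k = (int)lin.size();
    double coal_rate = 0.5 * k * (k - 1);
    double rec_rate = 0.0, mut_wt = 0.0;
    std::vector<double> spans(k), plens(k);
    for (int i = 0; i < k; ++i) {
      double a = lin[i].segs.front().a, b = lin[i].segs.back().b;
      spans[i] = 0.5 * (gm.gpos(b) - gm.gpos(a));
      rec_rate += spans[i];
      plens[i] = lin[i].phys_len();
      mut_wt += plens[i];
    }
    double tot = coal_rate + rec_rate;
    if (tot <= 0) break;  // single lineage, no recombination possible
    double dt = R::exp_rand() / tot;

    // mutations during dt (infinite sites, placed on ancestral material)
    if (theta_site > 0) {
      int nm = (int)R::rpois(dt * 0.5 * theta_site * mut_wt);
      for (int m = 0; m < nm; ++m) {
        double u = unif_rand() * mut_wt, acc = 0; int li = k - 1;
        for (int i = 0; i < k; ++i) { acc += plens[i]; if (u <= acc) { li = i; break; } }
        double v = unif_rand() * plens[li], a2 = 0;
        for (const Seg& s : lin[li].segs) {
          double len = s.b - s.a;
          if (v <= a2 + len) { muts.push_back({s.a + (v - a2), s.desc}); break; }
          a2 += len;
        }
      }
    }

    if (unif_rand() * tot < coal_rate) {  // coalescence
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      std::vector<Seg> merged = merge_segs(lin[i].segs, lin[j].segs, full);
      if (i < j) std::swap(i, j);
      lin.erase(lin.begin() + i);
      lin.erase(lin.begin() + j);
      if (!merged.empty()) { Lineage nl; nl.segs = std::move(merged); lin.push_back(nl); }
    } else {  // recombination
      double u = unif_rand() * rec_rate, acc = 0; int li = k - 1;
      for (int i = 0; i < k; ++i) { acc += spans[i]; if (u <= acc) { li = i; break; } }
      double ga = gm.gpos(lin[li].segs.front().a), gb = gm.gpos(lin[li].segs.back().b);
      double x = gm.ppos(ga + unif_rand() * (gb - ga));
      Lineage left, right;
      for (const Seg& s : lin[li].segs) {
        if (s.b <= x) left.segs.push_back(s);
        else if (s.a >= x) right.segs.push_back(s);
        else { left.segs.push_back({s.a, x, s.desc}); right.segs.push_back({x, s.b, s.desc}); }
      }
      if (left.segs.empty() || right.segs.empty()) continue;  // break outside span
      lin[li] = left;
      lin.push_back(right);
    }
  }

  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  // discretize to integer bp (1-based), dropping collisions
  std::vector<int> pos; std::vector<uint64_t> desc;
  for (const Mut& m : muts) {
    int bp = (int)std::floor(m.pos) + 1;
    if (!pos.empty() && pos.back() == bp) continue;
    pos.push_back(bp); desc.push_back(m.desc);
  }
  int S = (int)pos.size();
  IntegerMatrix H(n, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i)
      H(i, s) = (desc[s] >> i) & 1ULL;
  return List::create(_["positions"] = wrap(pos), _["haplotypes"] = H);
}

// ---------------------------------------------------------------------------
// Two-locus structured coalescent: sample haplotype-count configurations
// (n00, n01, n10, n11; allele 1 = mutant) for n haplotypes at two loci
// separated by recombination rate rho, conditional on one mutation per locus
// placed proportionally to marginal-tree branch length.

struct TLLin { uint64_t dA, dB; };

// [[Rcpp::export(name = ".cpp_two_locus_configs")]]
IntegerMatrix cpp_two_locus_configs(int n, double rho, int reps, int placements) {
  if (n < 2 || n > 64) stop("n must be in [2, 64]");
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  IntegerMatrix out(reps * placements, 4);
  std::unordered_map<uint64_t, double> expA, expB;
  std::vector<uint64_t> keyA, keyB; std::vector<double> wA, wB;

  for (int r = 0; r < reps; ++r) {
    std::vector<TLLin> lin(n);
    for (int i = 0; i < n; ++i) lin[i] = {1ULL << i, 1ULL << i};
    expA.clear(); expB.clear();
    while (true) {
      int k = (int)lin.size();
      if (k == 0) break;
      int nboth = 0;
      for (const TLLin& l : lin) if (l.dA && l.dB) ++nboth;
      double coal = 0.5 * k * (k - 1), rec = 0.5 * rho * nboth;
      double tot = coal + rec;
      if (tot <= 0) break;
      double dt = R::exp_rand() / tot;
      for (const TLLin& l : lin) {
        if (l.dA) expA[l.dA] += dt;
        if (l.dB) expB[l.dB] += dt;
      }
      if (unif_rand() * tot < coal) {
        int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        TLLin m = {lin[i].dA | lin[j].dA, lin[i].dB | lin[j].dB};
        if (m.dA == full) m.dA = 0;
        if (m.dB == full) m.dB = 0;
        if (i < j) std::swap(i, j);
        lin.erase(lin.begin() + i);
        lin.erase(lin.begin() + j);
        if (m.dA || m.dB) lin.push_back(m);
      } else {
        int pick = (int)(unif_rand() * nboth); if (pick >= nboth) pick = nboth - 1;
        int li = -1;
        for (int i = 0; i < k; ++i)
          if (lin[i].dA && lin[i].dB && ++li == pick) { li = i; break; }
        TLLin right = {0, lin[li].dB};
        lin[li].dB = 0;
        lin.push_back(right);
      }
    }
    keyA.clear(); wA.clear(); double WA = 0;
    for (auto& kv : expA) { keyA.push_back(kv.first); wA.push_back(kv.second); WA += kv.second; }
    keyB.clear(); wB.clear(); double WB = 0;
    for (auto& kv : expB) { keyB.push_back(kv.first); wB.push_back(kv.second); WB += kv.second; }
    for (int p = 0; p < placements; ++p) {
      double u = unif_rand() * WA, acc = 0; uint64_t SA = keyA.back();
      for (size_t i = 0; i < keyA.size(); ++i) { acc += wA[i]; if (u <= acc) { SA = keyA[i]; break; } }
      u = unif_rand() * WB; acc = 0; uint64_t SB = keyB.back();
      for (size_t i = 0; i < keyB.size(); ++i) { acc += wB[i]; if (u <= acc) { SB = keyB[i]; break; } }
      int n11 = popcount64(SA & SB);
      int n10 = popcount64(SA & ~SB);
      int n01 = popcount64(SB & ~SA);
      int row = r * placements + p;
      out(row, 0) = n - n11 - n10 - n01;
      out(row, 1) = n01;
      out(row, 2) = n10;
      out(row, 3) = n11;
    }
  }
  return out;
}

// canonical fold of a configuration: minimum encoding over the 8-element
// group generated by allele swaps at either locus and locus exchange
static inline uint32_t fold_key(int c0, int c1, int c2, int c3) {
  int v[8][4] = {
    {c0, c1, c2, c3}, {c2, c3, c0, c1}, {c1, c0, c3, c2}, {c3, c2, c1, c0},
    {c0, c2, c1, c3}, {c1, c3, c0, c2}, {c2, c0, c3, c1}, {c3, c1, c2, c0}};
  uint32_t best = UINT32_MAX;
  for (int i = 0; i < 8; ++i) {
    uint32_t k = ((uint32_t)v[i][0] * 65u + v[i][1]) * 65u * 65u +
                 (uint32_t)v[i][2] * 65u + v[i][3];
    if (k < best) best = k;
  }
  return best;
}

// Rao-Blackwellized lookup-table accumulation: for each replicate ARG the
// exact conditional configuration distribution (mutation at each locus on a
// branch with probability proportional to branch length) is added to the
// counts, giving real-valued expected counts per canonical configuration.
// `configs` enumerates the canonical configuration space (M x 4).
// [[Rcpp::export(name = ".cpp_two_locus_table")]]
NumericMatrix cpp_two_locus_table(int n, NumericVector grid, int reps,
                                  IntegerMatrix configs) {
  if (n < 2 || n > 64) stop("n must be in [2, 64]");
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  int M = configs.nrow(), G = grid.size();
  std::unordered_map<uint32_t, int> row_of;
  row_of.reserve(M * 2);
  for (int m = 0; m < M; ++m)
    row_of[fold_key(configs(m, 0), configs(m, 1), configs(m, 2), configs(m, 3))] = m;
  NumericMatrix counts(M, G);
  std::unordered_map<uint64_t, double> expA, expB;

  for (int gi = 0; gi < G; ++gi) {
    double rho = grid[gi];
    for (int r = 0; r < reps; ++r) {
      std::vector<TLLin> lin(n);
      for (int i = 0; i < n; ++i) lin[i] = {1ULL << i, 1ULL << i};
      expA.clear(); expB.clear();
      while (true) {
        int k = (int)lin.size();
        if (k == 0) break;
        int nboth = 0;
        for (const TLLin& l : lin) if (l.dA && l.dB) ++nboth;
        double coal = 0.5 * k * (k - 1), rec = 0.5 * rho * nboth;
        double tot = coal + rec;
        if (tot <= 0) break;
        double dt = R::exp_rand() / tot;
        for (const TLLin& l : lin) {
          if (l.dA) expA[l.dA] += dt;
          if (l.dB) expB[l.dB] += dt;
        }
        if (unif_rand() * tot < coal) {
          int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
          int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
          if (j >= i) ++j;
          TLLin m = {lin[i].dA | lin[j].dA, lin[i].dB | lin[j].dB};
          if (m.dA == full) m.dA = 0;
          if (m.dB == full) m.dB = 0;
          if (i < j) std::swap(i, j);
          lin.erase(lin.begin() + i);
          lin.erase(lin.begin() + j);
          if (m.dA || m.dB) lin.push_back(m);
        } else {
          int pick = (int)(unif_rand() * nboth); if (pick >= nboth) pick = nboth - 1;
          int li = -1;
          for (int i = 0; i < k; ++i)
            if (lin[i].dA && lin[i].dB && ++li == pick) { li = i; break; }
          TLLin right = {0, lin[li].dB};
          lin[li].dB = 0;
          lin.push_back(right);
        }
      }
      double WA = 0, WB = 0;
      for (auto& kv : expA) WA += kv.second;
      for (auto& kv : expB) WB += kv.second;
      if (WA <= 0 || WB <= 0) continue;
      for (auto& ka : expA) {
        double pa = ka.second / WA;
        for (auto& kb : expB) {
          double w = pa * kb.second / WB;
          int n11 = popcount64(ka.first & kb.first);
          int n10 = popcount64(ka.first & ~kb.first);
          int n01 = popcount64(kb.first & ~ka.first);
          auto it = row_of.find(fold_key(n - n11 - n10 - n01, n01, n10, n11));
          if (it != row_of.end()) counts(it->second, gi) += w;
        }
      }
    }
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Composite log-likelihood for one model state. logP is n_pairs x G: per-pair
// smoothed log configuration probability across the rho grid. Pairwise rho is
// the rate-map integral between the two marker positions; values above the
// last grid node are clamped (count returned).

// [[Rcpp::export(name = ".cpp_pair_loglik")]]
NumericVector cpp_pair_loglik(NumericMatrix logP, NumericVector grid,
                              NumericVector x1, NumericVector x2,
                              double background_per_bp,
                              NumericVector hs_start, NumericVector hs_end,
                              NumericVector hs_mult) {
  int P = logP.nrow(), G = grid.size(), H = hs_start.size();
  double ll = 0; int nclamp = 0;
  for (int p = 0; p < P; ++p) {
    double rho = background_per_bp * (x2[p] - x1[p]);
    for (int h = 0; h < H; ++h) {
      double ov = std::min(hs_end[h], x2[p]) - std::max(hs_start[h], x1[p]);
      if (ov > 0) rho += background_per_bp * (hs_mult[h] - 1.0) * ov;
    }
    if (rho >= grid[G - 1]) { ll += logP(p, G - 1); ++nclamp; continue; }
    int lo = std::upper_bound(grid.begin(), grid.end(), rho) - grid.begin() - 1;
    if (lo < 0) lo = 0;
    if (lo >= G - 1) { ll += logP(p, G - 1); continue; }
    double w = (rho - grid[lo]) / (grid[lo + 1] - grid[lo]);
    ll += (1 - w) * logP(p, lo) + w * logP(p, lo + 1);
  }
  return NumericVector::create(ll, (double)nclamp);
}
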