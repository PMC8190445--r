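// Forward Wright-Fisher simulator of a single linear chromosome with
// recurrent deleterious and neutral mutation, uniform recombination,
// multiplicative selection with partial dominance, and an arbitrary
// per-generation population-size trace. Haplotypes are sorted vectors of
// mutation ids (sorted by genomic position, which is unique per mutation
// under the infinite-sites convention: position collisions are re-drawn).
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Registry {
  std::vector<int> pos;       // 1-based bp
  std::vector<double> s;      // selection coefficient, 0 for neutral
  std::vector<double> h;      // dominance
  std::vector<int> origin;    // generation of origin (1-based)
  std::vector<char> neutral;  // 1 = neutral
  std::unordered_set<int> used_pos;
  size_t size() const { return pos.size(); }
};

typedef std::vector<int> Hap;

inline double hapFitness(const Hap &a, const Hap &b, const Registry &reg) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    if (i < a.size() && j < b.size() && a[i] == b[j]) {
      if (!reg.neutral[a[i]]) w *= 1.0 + reg.s[a[i]];
      ++i; ++j;
    } else if (j >= b.size() ||
               (i < a.size() && reg.pos[a[i]] < reg.pos[b[j]])) {
      if (!reg.neutral[a[i]]) w *= 1.0 + reg.h[a[i]] * reg.s[a[i]];
      ++i;
    } else {
      if (!reg.neutral[b[j]]) w *= 1.0 + reg.h[b[j]] * reg.s[b[j]];
      ++j;
    }
    if (w <= 0.0) return 0.0;
  }
  return w;
}

// copy mutations of h with position in [lo, hi) into out
inline void copyRange(const Hap &h, const Registry &reg, double lo, double hi,
                      Hap &out) {
  // linear scan with binary-searched start
  size_t i = std::lower_bound(h.begin(), h.end(), lo,
    [&](int id, double v) { return reg.pos[id] < v; }) - h.begin();
  while (i < h.size() && reg.pos[h[i]] < hi) out.push_back(h[i++]);
}

inline Hap makeGamete(const Hap &a, const Hap &b, const Registry &reg,
                      double rec, double L) {
  int k = (int) R::rpois(rec * L);
  bool startA = unif_rand() < 0.5;
  if (k == 0) return startA ? a : b;
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L + 1.0;
  std::sort(bp.begin(), bp.end());
  Hap out;
  out.reserve(std::max(a.size(), b.size()));
  double lo = 0.0;
  bool cur = startA;
  for (int i = 0; i <= k; ++i) {
    double hi = (i == k) ? L + 2.0 : bp[i];
    copyRange(cur ? a : b, reg, lo, hi, out);
    lo = hi;
    cur = !cur;
  }
  return out;
}

inline void addMutations(Hap &g, Registry &reg, double mu, double L,
                         double p_del, double mean_s_abs, double shape,
                         double h_del, int gen) {
  int k = (int) R::rpois(mu * L);
  for (int i = 0; i < k; ++i) {
    int p;
    do { p = (int)(unif_rand() * L) + 1; } while (reg.used_pos.count(p));
    reg.used_pos.insert(p);
    int id = (int) reg.size();
    bool del = unif_rand() < p_del;
    reg.pos.push_back(p);
    if (del) {
      double sc = -R::rgamma(shape, mean_s_abs / shape);
      reg.s.push_back(sc);
      reg.h.push_back(h_del);
      reg.neutral.push_back(0);
    } else {
      reg.s.push_back(0.0);
      reg.h.push_back(0.5);
      reg.neutral.push_back(1);
    }
    reg.origin.push_back(gen);
    g.insert(std::lower_bound(g.begin(), g.end(), id,
      [&](int a, int b2) { return reg.pos[a] < reg.pos[b2]; }), id);
  }
}

// remove fixed mutations (count == 2N) from every haplotype
void purgeFixed(std::vector<Hap> &haps, const Registry &reg,
                std::vector<int> &cnt) {
  std::fill(cnt.begin(), cnt.end(), 0);
  cnt.resize(reg.size(), 0);
  for (const Hap &h : haps)
    for (int id : h) ++cnt[id];
  int tot = (int) haps.size();
  bool any = false;
  for (size_t id = 0; id < cnt.size() && !any; ++id)
    if (cnt[id] == tot) any = true;
  if (!any) return;
  for (Hap &h : haps) {
    Hap keep;
    keep.reserve(h.size());
    for (int id : h) if (cnt[id] != tot) keep.push_back(id);
    h.swap(keep);
  }
}

} // namespace

// mu, rec, mean_s_abs are per-generation vectors (length G): entry g is
// the rate used when producing generation g+1 (entry 0 seeds founders).
// At generation seam_gen (1-based, 0 = never) every stored selection
// coefficient is multiplied by s_seam_factor: staged rescaling hands the
// standing variation of a Q-rescaled burn-in (which preserves N*s) to an
// unrescaled phase by mapping s -> s/Q while keeping frequencies.
// [[Rcpp::export]]
List wf_simulate_cpp(IntegerVector trace, double length_bp, NumericVector mu,
                     NumericVector rec, double p_del, NumericVector mean_s_abs,
                     double shape, double h_del, int purge_every = 32,
                     int seam_gen = 0, double s_seam_factor = 1.0) {
  int G = trace.size();
  if (G < 1) stop("empty demography trace");
  if (mu.size() != G || rec.size() != G || mean_s_abs.size() != G)
    stop("mu, rec and mean_s_abs must have one entry per generation");
  for (int g = 0; g < G; ++g)
    if (trace[g] < 1) stop("population size must be positive");

  Registry reg;
  int N = trace[0];
  std::vector<Hap> haps(2 * N);
  std::vector<int> cnt;
  IntegerVector new_muts(G);

  // generation 1: mutation on founder haplotypes
  for (Hap &h : haps) {
    size_t before = reg.size();
    addMutations(h, reg, mu[0], length_bp, p_del, mean_s_abs[0], shape,
                 h_del, 1);
    new_muts[0] += (int)(reg.size() - before);
  }

  std::vector<double> w, cw;
  for (int g = 1; g < G; ++g) {
    if (seam_gen > 0 && g + 1 == seam_gen)
      for (size_t id = 0; id < reg.size(); ++id)
        reg.s[id] *= s_seam_factor;
    int Nnext = trace[g];
    w.resize(N);
    cw.resize(N);
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      w[i] = hapFitness(haps[2 * i], haps[2 * i + 1], reg);
      tot += w[i];
      cw[i] = tot;
    }
    std::vector<Hap> next(2 * Nnext);
    for (int off = 0; off < Nnext; ++off) {
      for (int side = 0; side < 2; ++side) {
        int par;
        if (tot > 0.0) {
          double u = unif_rand() * tot;
          par = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
          if (par >= N) par = N - 1;
        } else {
          par = (int)(unif_rand() * N);
          if (par >= N) par = N - 1;
        }
        Hap gam = makeGamete(haps[2 * par], haps[2 * par + 1], reg,
                             rec[g], length_bp);
        size_t before = reg.size();
        addMutations(gam, reg, mu[g], length_bp, p_del, mean_s_abs[g], shape,
                     h_del, g + 1);
        new_muts[g] += (int)(reg.size() - before);
        next[2 * off + side] = std::move(gam);
      }
    }
    haps.swap(next);
    N = Nnext;
    if ((g % purge_every) == 0) purgeFixed(haps, reg, cnt);
    if ((g % 64) == 0) Rcpp::checkUserInterrupt();
  }
  purgeFixed(haps, reg, cnt);

  // final frequencies over 2N haplotypes
  cnt.assign(reg.size(), 0);
  for (const Hap &h : haps)
    for (int id : h) ++cnt[id];
  int tot2N = 2 * N;
  std::vector<int> seg;
  for (size_t id = 0; id < reg.size(); ++id)
    if (cnt[id] > 0 && cnt[id] < tot2N) seg.push_back((int) id);
  std::sort(seg.begin(), seg.end(),
            [&](int a, int b) { return reg.pos[a] < reg.pos[b]; });

  int S = (int) seg.size();
  std::vector<int> col(reg.size(), -1);
  for (int j = 0; j < S; ++j) col[seg[j]] = j;

  IntegerMatrix geno(N, S);
  for (int i = 0; i < N; ++i)
    for (int side = 0; side < 2; ++side)
      for (int id : haps[2 * i + side])
        if (col[id] >= 0) geno(i, col[id]) += 1;

  IntegerVector m_pos(S), m_origin(S);
  NumericVector m_s(S), m_h(S), m_freq(S);
  LogicalVector m_neutral(S);
  for (int j = 0; j < S; ++j) {
    int id = seg[j];
    m_pos[j] = reg.pos[id];
    m_s[j] = reg.s[id];
    m_h[j] = reg.h[id];
    m_origin[j] = reg.origin[id];
    m_neutral[j] = reg.neutral[id] != 0;
    m_freq[j] = (double) cnt[id] / tot2N;
  }

  return List::create(_["genotypes"] = geno, _["position_bp"] = m_pos,
                      _["s"] = m_s, _["h"] = m_h, _["neutral"] = m_neutral,
                      _["origin_generation"] = m_origin,
                      _["frequency"] = m_freq,
                      _["new_mutations_per_generation"] = new_muts);
}
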