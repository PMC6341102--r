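// Rescaled forward Wright-Fisher simulator with recombination and
// infinite-sites mutation on a continuous segment, three-population
// out-of-Africa demography, and additive selection (1, 1+s/2, 1+s) on a
// central variant in the EAS population.
//
// Haplotypes are stored in a copy-on-write pool: an offspring without a
// crossover or new mutation reuses its parent's haplotype id, so the cost
// per generation is close to the population size, not the sequence length.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ --- fast internal RNG, seeded from R's RNG at entry so that
// set.seed() still controls the simulation
struct XRng {
  uint64_t s[4];
  explicit XRng() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (uint64_t)0x9E3779B97F4A7C15ULL;
    }
    for (int i = 0; i < 16; ++i) next();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double runif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline int below(int n) { return (int)(runif() * n); }
  inline int rpois(double lambda) {  // Knuth; fine for small means
    double limit = std::exp(-lambda), prod = runif();
    int k = 0;
    while (prod > limit) { prod *= runif(); ++k; }
    return k;
  }
};

struct Sim {
  std::vector<std::vector<int>> haps;  // site-id lists, sorted by position
  std::vector<char> carrier;           // carries the selected site
  std::vector<double> pos;             // site id -> position (bp)
  int selected_id = -1;
  double sel_pos = 0.0;

  bool before(int a, int b) const { return pos[a] < pos[b]; }

  int new_hap(std::vector<int> sites, char car) {
    haps.push_back(std::move(sites));
    carrier.push_back(car);
    return (int)haps.size() - 1;
  }

  // mosaic of parents a and b with crossover positions bps (sorted);
  // start_with_a: source for the leftmost segment
  // carrier flag is inherited from whichever parent contributes the
  // segment containing sel_pos (meaningful only once selected_id >= 0)
  int recombine(int a, int b, const std::vector<double>& bps,
                bool start_with_a) {
    const std::vector<int>& A = haps[a];
    const std::vector<int>& B = haps[b];
    std::vector<int> child;
    child.reserve(std::max(A.size(), B.size()));
    bool useA = start_with_a;
    double lo = -1.0;
    size_t ia = 0, ib = 0;
    char car = 0;
    for (size_t k = 0; k <= bps.size(); ++k) {
      double hi = (k < bps.size()) ? bps[k] : 1e300;
      const std::vector<int>& src = useA ? A : B;
      size_t& ptr = useA ? ia : ib;
      // advance the other pointer past this segment too
      size_t& other = useA ? ib : ia;
      const std::vector<int>& osrc = useA ? B : A;
      while (ptr < src.size() && pos[src[ptr]] < hi) {
        if (pos[src[ptr]] >= lo) child.push_back(src[ptr]);
        ++ptr;
      }
      while (other < osrc.size() && pos[osrc[other]] < hi) ++other;
      if (selected_id >= 0 && sel_pos >= lo && sel_pos < hi)
        car = carrier[useA ? a : b];
      lo = hi;
      useA = !useA;
    }
    return new_hap(std::move(child), car);
  }

  int mutate(int h, int nmut, double L, XRng& rng) {
    std::vector<int> child = haps[h];
    for (int k = 0; k < nmut; ++k) {
      double p = rng.runif() * L;
      int id = (int)pos.size();
      pos.push_back(p);
      auto it = std::lower_bound(child.begin(), child.end(), id,
        [this](int site, int val) { return pos[site] < pos[val]; });
      child.insert(it, id);
    }
    return new_hap(std::move(child), carrier[h]);
  }
};

// draw one offspring haplotype from a diploid parent pool
int make_child(Sim& sim, const std::vector<int>& parents, double s,
               double mu_hap, double rec_hap, double L, double p_quiet,
               XRng& rng) {
  int nd = (int)parents.size() / 2;
  int j;
  if (s > 0.0) {
    double wmax = 1.0 + s;
    for (;;) {
      j = rng.below(nd); if (j == nd) j = nd - 1;
      int nc = sim.carrier[parents[2 * j]] + sim.carrier[parents[2 * j + 1]];
      double w = 1.0 + 0.5 * s * nc;
      if (rng.runif() * wmax <= w) break;
    }
  } else {
    j = rng.below(nd); if (j == nd) j = nd - 1;
  }
  int a = parents[2 * j], b = parents[2 * j + 1];
  // fast path: with prob exp(-(mu+rec) per haplotype) the offspring is an
  // exact copy of one parental haplotype and shares its id
  double u = rng.runif();
  if (u < p_quiet) return (u < 0.5 * p_quiet) ? a : b;
  int nrec, nmut;
  do {
    nrec = rng.rpois(rec_hap);
    nmut = rng.rpois(mu_hap);
  } while (nrec == 0 && nmut == 0);
  int child;
  if (nrec == 0) {
    child = (rng.runif() < 0.5) ? a : b;
    if (nmut > 0) child = sim.mutate(child, nmut, L, rng);
  } else {
    std::vector<double> bps(nrec);
    for (int k = 0; k < nrec; ++k) bps[k] = rng.runif() * L;
    std::sort(bps.begin(), bps.end());
    child = sim.recombine(a, b, bps, rng.runif() < 0.5);
    if (nmut > 0) child = sim.mutate(child, nmut, L, rng);
  }
  return child;
}

} // namespace

// [[Rcpp::export]]
List wf_sweep_cpp(IntegerMatrix init, NumericVector init_pos, double L,
                  double mu_bp, double rec_bp,
                  int t_split2, int t_sel, double s, double init_freq,
                  IntegerVector n_afr, IntegerVector n_ooa,
                  IntegerVector n_eur, IntegerVector n_eas,
                  double mig, int n_sample) {
  // schedules are indexed by generations-before-present g = t_start-1 .. 0
  // (element [g]); n_eur/n_eas are used for g < t_split2, n_ooa for
  // g >= t_split2.
  int t_start = n_afr.size();
  XRng rng;
  double p_quiet = std::exp(-((mu_bp + rec_bp) * L));
  Sim sim;
  sim.pos.assign(init_pos.begin(), init_pos.end());
  int n0 = init.nrow();
  for (int i = 0; i < n0; ++i) {
    std::vector<int> sites;
    for (int j = 0; j < init.ncol(); ++j)
      if (init(i, j) == 1) sites.push_back(j);
    // init_pos is sorted, so site ids are already in position order
    sim.new_hap(std::move(sites), 0);
  }
  std::vector<int> anc(n0);
  for (int i = 0; i < n0; ++i) anc[i] = i;

  std::vector<int> afr, eurasia, eur, eas;
  double mu_hap = mu_bp * L, rec_hap = rec_bp * L;

  for (int g = t_start - 1; g >= 0; --g) {
    bool post2 = g < t_split2;
    // parent pools for this generation's offspring
    std::vector<int>* pool_afr = afr.empty() ? &anc : &afr;
    std::vector<int>* pool_b = eurasia.empty() ? &anc : &eurasia;
    std::vector<int>* pool_eur = eur.empty() ? pool_b : &eur;
    std::vector<int>* pool_eas = eas.empty() ? pool_b : &eas;

    auto reproduce = [&](std::vector<int>* self, std::vector<int>* other1,
                         std::vector<int>* other2, int n_child,
                         double sel) {
      std::vector<int> kids((size_t)2 * n_child);
      for (int c = 0; c < 2 * n_child; ++c) {
        std::vector<int>* src = self;
        if (mig > 0.0 && rng.runif() < mig) {
          if (other2 && rng.runif() < 0.5) src = other2;
          else if (other1) src = other1;
        }
        kids[c] = make_child(sim, *src, src == self ? sel : 0.0,
                             mu_hap, rec_hap, L, p_quiet, rng);
      }
      return kids;
    };

    std::vector<int> new_afr, new_b, new_eur, new_eas;
    if (!post2) {
      new_afr = reproduce(pool_afr, pool_b, nullptr, n_afr[g], 0.0);
      new_b = reproduce(pool_b, pool_afr, nullptr, n_ooa[g], 0.0);
      eurasia.swap(new_b);
    } else {
      double sel_eas = (sim.selected_id >= 0 && g < t_sel) ? s : 0.0;
      new_afr = reproduce(pool_afr, pool_eur, pool_eas, n_afr[g], 0.0);
      new_eur = reproduce(pool_eur, pool_afr, pool_eas, n_eur[g], 0.0);
      new_eas = reproduce(pool_eas, pool_afr, pool_eur, n_eas[g], sel_eas);
      eur.swap(new_eur);
      eas.swap(new_eas);
      eurasia.clear();
    }
    afr.swap(new_afr);

    // inject the selected allele at frequency init_freq in EUR and EAS
    if (g == t_sel && t_sel >= 0) {
      sim.sel_pos = L / 2.0;
      sim.selected_id = (int)sim.pos.size();
      sim.pos.push_back(sim.sel_pos);
      for (std::vector<int>* pl : {&eur, &eas}) {
        int n = (int)pl->size();
        int k = std::max(1, (int)std::lround(init_freq * n));
        // choose k distinct haplotype slots
        std::vector<int> idx(n);
        for (int i = 0; i < n; ++i) idx[i] = i;
        for (int i = 0; i < k; ++i) {
          int r = i + rng.below(n - i);
          if (r >= n) r = n - 1;
          std::swap(idx[i], idx[r]);
        }
        for (int i = 0; i < k; ++i) {
          int h = (*pl)[idx[i]];
          std::vector<int> sites = sim.haps[h];
          auto it = std::lower_bound(sites.begin(), sites.end(),
                                     sim.selected_id,
            [&sim](int site, int val) {
              return sim.pos[site] < sim.pos[val]; });
          sites.insert(it, sim.selected_id);
          (*pl)[idx[i]] = sim.new_hap(std::move(sites), 1);
        }
      }
    }
  }

  // sample without replacement from each terminal pool
  auto take = [&](std::vector<int>& pool) {
    int n = (int)pool.size();
    int k = std::min(n_sample, n);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::vector<int> out(k);
    for (int i = 0; i < k; ++i) {
      int r = i + rng.below(n - i);
      if (r >= n) r = n - 1;
      std::swap(idx[i], idx[r]);
      out[i] = pool[idx[i]];
    }
    return out;
  };
  std::vector<int> s_afr = take(afr), s_eur = take(eur), s_eas = take(eas);

  // collect segregating sites among the sampled haplotypes
  std::vector<int> all;
  for (auto* sv : {&s_afr, &s_eur, &s_eas})
    for (int h : *sv)
      for (int site : sim.haps[h]) all.push_back(site);
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  if (sim.selected_id >= 0 &&
      !std::binary_search(all.begin(), all.end(), sim.selected_id))
    all.push_back(sim.selected_id);
  std::sort(all.begin(), all.end(), [&sim](int a, int b) {
    return sim.pos[a] < sim.pos[b]; });

  int S = (int)all.size();
  std::vector<int> col(sim.pos.size(), -1);
  for (int j = 0; j < S; ++j) col[all[j]] = j;

  auto to_matrix = [&](const std::vector<int>& sv) {
    IntegerMatrix M((int)sv.size(), S);
    for (size_t i = 0; i < sv.size(); ++i)
      for (int site : sim.haps[sv[i]])
        M((int)i, col[site]) = 1;
    return M;
  };
  NumericVector positions(S);
  for (int j = 0; j < S; ++j) positions[j] = sim.pos[all[j]];

  int sel_col = (sim.selected_id >= 0) ? col[sim.selected_id] : -1;
  IntegerMatrix Meas = to_matrix(s_eas);
  double daf = 0.0;
  if (sel_col >= 0) {
    for (int i = 0; i < Meas.nrow(); ++i) daf += Meas(i, sel_col);
    daf /= Meas.nrow();
  }
  bool lost = true;
  if (sim.selected_id >= 0)
    for (auto* pl : {&afr, &eur, &eas}) {
      for (int h : *pl) if (sim.carrier[h]) { lost = false; break; }
      if (!lost) break;
    }

  return List::create(_["afr"] = to_matrix(s_afr),
                      _["eur"] = to_matrix(s_eur),
                      _["eas"] = Meas,
                      _["positions"] = positions,
                      _["selected_col"] = sel_col + 1,  // 1-based, 0 if none
                      _["daf_eas"] = daf,
                      _["lost"] = lost);
}
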