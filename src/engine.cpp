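// Forward-time engine for haplodiploid / diploid populations.
//
// Genomes are bitsets over "slots"; each slot holds one segregating mutation.
// Slots [0, backbone_n) are sorted by (position, id) so crossover segments map
// to contiguous bit ranges (word-level copies); slots [backbone_n, nslots) are
// a small unsorted tail of recently arisen mutations handled per bit.  Fixed
// and lost mutations are detected each generation with AND / OR masks over all
// non-null genomes; their slots are reclaimed by periodic compaction.  Purging
// a fixed mutation multiplies every individual's fitness within a sex by the
// same factor, so relative parent-sampling weights are unchanged.
//
// All randomness comes from R's RNG (seed with set.seed() before calling).

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline int popcnt64(uint64_t x) { return __builtin_popcountll(x); }

// copy bits [lo, hi) (slot indices) from src into dst, leaving other bits
static void copy_bits(uint64_t *dst, const uint64_t *src, int lo, int hi) {
  if (lo >= hi) return;
  int w0 = lo >> 6, w1 = (hi - 1) >> 6;
  uint64_t m0 = ~0ULL << (lo & 63);
  uint64_t m1 = ~0ULL >> (63 - ((hi - 1) & 63));
  if (w0 == w1) {
    uint64_t m = m0 & m1;
    dst[w0] = (dst[w0] & ~m) | (src[w0] & m);
    return;
  }
  dst[w0] = (dst[w0] & ~m0) | (src[w0] & m0);
  for (int w = w0 + 1; w < w1; ++w) dst[w] = src[w];
  dst[w1] = (dst[w1] & ~m1) | (src[w1] & m1);
}

struct HDEngine {
  // configuration
  bool hap;                 // haplodiploid (true) or diploid
  int Nm, Nf;
  long long L;
  double mu, r, s, h, h_hap;
  double l_hom, l_het, l_hemi;  // log fitness factors per zygosity
  int Gm;                   // male genome rows: Nm (hap) or 2*Nm (dip)
  int nG;                   // total genome rows = 2*Nf + Gm

  // mutation registry (index = id)
  std::vector<int32_t> mpos, morigin;
  std::vector<int8_t> mstate;             // 0 segregating, 1 fixed, 2 lost
  std::vector<int> fix_id, fix_gen;       // substitution log
  long long n_lost = 0;

  // slot layout
  std::vector<int32_t> slot_id;           // slot -> mutation id
  std::vector<int32_t> bpos;              // backbone slot -> position
  int backbone_n = 0, nslots = 0;
  int W = 0;                              // words per genome row

  std::vector<uint64_t> bufA, bufB;       // genome buffers (nG rows, stride W)
  bool curIsA = true;
  std::vector<uint64_t> active;           // mask of segregating slots
  std::vector<uint64_t> andm, orm, scratch;
  int Fpend = 0;                          // fixed-but-not-yet-purged count
  int generation = 0;
  long long cum_fix = 0;
  int seg_now = 0;

  std::vector<double> lwF, lwM, cumF, cumM;
  std::vector<int32_t> bps;               // crossover scratch

  // per-generation output
  std::vector<int> o_gen, o_sub, o_seg;
  std::vector<double> o_cum, o_wf, o_wm;

  uint64_t *rowCur(int g) { return (curIsA ? bufA : bufB).data() + (size_t)g * W; }
  uint64_t *rowNxt(int g) { return (curIsA ? bufB : bufA).data() + (size_t)g * W; }
  int usedW() const { return (nslots + 63) >> 6; }

  void init(bool hap_, int Nm_, int Nf_, double L_, double mu_, double r_,
            double s_, double h_, double h_hap_,
            int init_place /*0 none, 1 female, 2 male*/, int init_pos) {
    hap = hap_; Nm = Nm_; Nf = Nf_;
    L = (long long)L_; mu = mu_; r = r_; s = s_; h = h_; h_hap = h_hap_;
    if (Nm < 1 || Nf < 1) stop("Nm and Nf must be >= 1");
    if (L < 1) stop("L must be >= 1");
    if (mu < 0 || r < 0) stop("mu and r must be >= 0");
    if (s <= -1.0) stop("the simulation engine requires s > -1");
    l_hom = std::log1p(s);
    l_het = std::log1p(s * h);
    l_hemi = std::log1p(s * h_hap);
    if (!R_finite(l_het) || !R_finite(l_hemi))
      stop("fitness factors must be positive (check h, h_haploid)");
    Gm = hap ? Nm : 2 * Nm;
    nG = 2 * Nf + Gm;
    W = 8;
    bufA.assign((size_t)nG * W, 0);
    bufB.assign((size_t)nG * W, 0);
    active.assign(W, 0);
    andm.assign(W, 0);
    orm.assign(W, 0);
    scratch.assign(W, 0);
    lwF.resize(Nf); lwM.resize(Nm); cumF.resize(Nf); cumM.resize(Nm);
    if (init_place != 0) {
      if (init_pos < 0 || init_pos >= L) stop("initial mutation position out of [0, L)");
      mpos.push_back(init_pos); morigin.push_back(0); mstate.push_back(0);
      slot_id.push_back(0); bpos.push_back(init_pos);
      backbone_n = 1; nslots = 1;
      active[0] = 1ULL;
      int row = (init_place == 1) ? 0 : 2 * Nf;  // female 1 genome a, or male 1
      rowCur(row)[0] |= 1ULL;
      seg_now = 1;
    }
  }

  void restride(int newW) {
    int cw = std::min(usedW(), W);
    std::vector<uint64_t> na((size_t)nG * newW, 0), nb((size_t)nG * newW, 0);
    for (int g = 0; g < nG; ++g) {
      std::memcpy(na.data() + (size_t)g * newW,
                  bufA.data() + (size_t)g * W, (size_t)cw * 8);
      std::memcpy(nb.data() + (size_t)g * newW,
                  bufB.data() + (size_t)g * W, (size_t)cw * 8);
    }
    bufA.swap(na); bufB.swap(nb);
    active.resize(newW, 0); andm.resize(newW, 0);
    orm.resize(newW, 0); scratch.resize(newW, 0);
    W = newW;
  }

  void compact() {
    int uw = usedW();
    // surviving (segregating) slots, sorted by (position, id)
    std::vector<std::pair<int64_t, int32_t>> surv;  // (pos<<32 | id, oldslot)
    surv.reserve(seg_now);
    for (int w = 0; w < uw; ++w) {
      uint64_t m = active[w];
      while (m) {
        int b = __builtin_ctzll(m); m &= m - 1;
        int sl = (w << 6) | b;
        int32_t id = slot_id[sl];
        surv.push_back({((int64_t)mpos[id] << 32) | (uint32_t)id, sl});
      }
    }
    std::sort(surv.begin(), surv.end());
    int K = (int)surv.size();
    std::vector<int32_t> old2new(nslots, -1);
    std::vector<int32_t> nid(K);
    std::vector<int32_t> nbpos(K);
    for (int k = 0; k < K; ++k) {
      int sl = surv[k].second;
      old2new[sl] = k;
      nid[k] = slot_id[sl];
      nbpos[k] = mpos[slot_id[sl]];
    }
    for (int g = 0; g < nG; ++g) {
      uint64_t *row = rowCur(g);
      std::fill(scratch.begin(), scratch.begin() + uw, 0ULL);
      for (int w = 0; w < uw; ++w) {
        uint64_t m = row[w];
        while (m) {
          int b = __builtin_ctzll(m); m &= m - 1;
          int ns = old2new[(w << 6) | b];
          if (ns >= 0) scratch[ns >> 6] |= 1ULL << (ns & 63);
        }
      }
      std::memcpy(row, scratch.data(), (size_t)uw * 8);
    }
    slot_id.assign(nid.begin(), nid.end());
    bpos.assign(nbpos.begin(), nbpos.end());
    backbone_n = K; nslots = K;
    std::fill(active.begin(), active.end(), 0ULL);
    for (int k = 0; k < K; ++k) active[k >> 6] |= 1ULL << (k & 63);
    Fpend = 0;
    // shrink stride if grossly oversized
    int needW = std::max(8, ((K + 2048) >> 6) + 2);
    if (W > 2 * needW) restride(needW);
  }

  // fitness of the current population; fills parent-sampling weights and the
  // mean-fitness columns of the row belonging to the current generation
  void fitness_pass() {
    int uw = usedW();
    double maxF = R_NegInf, maxM = R_NegInf;
    for (int i = 0; i < Nf; ++i) {
      const uint64_t *a = rowCur(2 * i), *b = rowCur(2 * i + 1);
      int hom = 0, any = 0;
      for (int w = 0; w < uw; ++w) {
        hom += popcnt64(a[w] & b[w]);
        any += popcnt64(a[w] | b[w]);
      }
      double lw = (double)(hom - Fpend) * l_hom + (double)(any - hom) * l_het;
      lwF[i] = lw; if (lw > maxF) maxF = lw;
    }
    for (int j = 0; j < Nm; ++j) {
      double lw;
      if (hap) {
        const uint64_t *a = rowCur(2 * Nf + j);
        int n = 0;
        for (int w = 0; w < uw; ++w) n += popcnt64(a[w]);
        lw = (double)(n - Fpend) * l_hemi;
      } else {
        const uint64_t *a = rowCur(2 * Nf + 2 * j), *b = rowCur(2 * Nf + 2 * j + 1);
        int hom = 0, any = 0;
        for (int w = 0; w < uw; ++w) {
          hom += popcnt64(a[w] & b[w]);
          any += popcnt64(a[w] | b[w]);
        }
        lw = (double)(hom - Fpend) * l_hom + (double)(any - hom) * l_het;
      }
      lwM[j] = lw; if (lw > maxM) maxM = lw;
    }
    double accF = 0, accM = 0, mF = 0, mM = 0;
    for (int i = 0; i < Nf; ++i) {
      accF += std::exp(lwF[i] - maxF); cumF[i] = accF;
      mF += std::exp(lwF[i]);
    }
    for (int j = 0; j < Nm; ++j) {
      accM += std::exp(lwM[j] - maxM); cumM[j] = accM;
      mM += std::exp(lwM[j]);
    }
    if (accF <= 0 || accM <= 0)
      stop("population extinction: all fitnesses are zero within a sex");
    if (generation >= 1 && (int)o_wf.size() >= generation) {
      o_wf[generation - 1] = mF / Nf;
      o_wm[generation - 1] = mM / Nm;
    }
  }

  int pick(const std::vector<double> &cum, int n) {
    double u = unif_rand() * cum[n - 1];
    return (int)(std::upper_bound(cum.begin(), cum.begin() + n, u) - cum.begin());
  }

  void add_mutation(int32_t p, uint64_t *D) {
    if (nslots >= 64 * W) stop("internal error: mutation slot capacity exceeded");
    int sl = nslots++;
    int32_t id = (int32_t)mpos.size();
    mpos.push_back(p); morigin.push_back(generation + 1); mstate.push_back(0);
    slot_id.push_back(id);
    active[sl >> 6] |= 1ULL << (sl & 63);
    D[sl >> 6] |= 1ULL << (sl & 63);
  }

  void denovo(uint64_t *D) {
    if (mu <= 0) return;
    int k = (int)R::rpois(mu * (double)L);
    for (int i = 0; i < k; ++i) {
      long long p = (long long)(unif_rand() * (double)L);
      if (p >= L) p = L - 1;
      add_mutation((int32_t)p, D);
    }
  }

  // recombined gamete from genome rows A and B into D
  void gamete_recomb(const uint64_t *A, const uint64_t *B, uint64_t *D) {
    int nbp = (r > 0 && L > 1) ? (int)R::rpois(r * (double)(L - 1)) : 0;
    bool startA;
    if (nbp == 0) {
      startA = unif_rand() < 0.5;
      std::memcpy(D, startA ? A : B, (size_t)usedW() * 8);
      return;
    }
    bps.clear();
    for (int i = 0; i < nbp; ++i) {
      int32_t p;
      do {
        p = 1 + (int32_t)(unif_rand() * (double)(L - 1));
        if (p >= L) p = (int32_t)(L - 1);
      } while (std::find(bps.begin(), bps.end(), p) != bps.end());
      bps.push_back(p);
    }
    std::sort(bps.begin(), bps.end());
    startA = unif_rand() < 0.5;
    const uint64_t *S = startA ? A : B;
    const uint64_t *O = startA ? B : A;
    int uw = usedW();
    std::memcpy(D, S, (size_t)uw * 8);
    // backbone: overwrite alternating segments with the other strand
    int prev = 0;
    bool other = false;
    for (int k = 0; k <= nbp; ++k) {
      int idx = (k < nbp)
        ? (int)(std::lower_bound(bpos.begin(), bpos.begin() + backbone_n, bps[k]) - bpos.begin())
        : backbone_n;
      if (other) copy_bits(D, O, prev, idx);
      prev = idx;
      other = !other;
    }
    // tail: per-bit strand choice where parents differ
    if (nslots > backbone_n) {
      int t0 = backbone_n, t1 = nslots;
      int w0 = t0 >> 6, w1 = (t1 - 1) >> 6;
      for (int w = w0; w <= w1; ++w) {
        uint64_t tm = ~0ULL;
        if (w == w0) tm &= ~0ULL << (t0 & 63);
        if (w == w1) tm &= ~0ULL >> (63 - ((t1 - 1) & 63));
        uint64_t diff = (A[w] ^ B[w]) & tm;
        while (diff) {
          int b = __builtin_ctzll(diff); diff &= diff - 1;
          int sl = (w << 6) | b;
          int32_t p = mpos[slot_id[sl]];
          int cnt = 0;
          for (size_t q = 0; q < bps.size(); ++q) if (bps[q] <= p) ++cnt;
          const uint64_t *Ssel = (cnt & 1) ? O : S;
          uint64_t bit = 1ULL << b;
          D[w] = (D[w] & ~bit) | (Ssel[w] & bit);
        }
      }
    }
  }

  void step() {
    // compaction / capacity management
    int wasted = nslots - seg_now;
    if (wasted > std::max(1024, seg_now / 2)) compact();
    double n_gam = hap ? (2.0 * Nf + Nm) : 2.0 * (Nf + Nm);
    int need = (int)(4.0 * n_gam * mu * (double)L) + 256;
    if (nslots + need > 64 * W) {
      compact();
      if (nslots + need > 64 * W) restride(((nslots + need) >> 6) + 4);
    }

    fitness_pass();

    std::memset((curIsA ? bufB : bufA).data(), 0, (size_t)nG * W * 8);

    // daughters
    for (int d = 0; d < Nf; ++d) {
      int mo = pick(cumF, Nf);
      int fa = pick(cumM, Nm);
      uint64_t *g1 = rowNxt(2 * d), *g2 = rowNxt(2 * d + 1);
      gamete_recomb(rowCur(2 * mo), rowCur(2 * mo + 1), g1);
      denovo(g1);
      if (hap) {
        std::memcpy(g2, rowCur(2 * Nf + fa), (size_t)usedW() * 8);
      } else {
        gamete_recomb(rowCur(2 * Nf + 2 * fa), rowCur(2 * Nf + 2 * fa + 1), g2);
      }
      denovo(g2);
    }
    // sons
    for (int j = 0; j < Nm; ++j) {
      int mo = pick(cumF, Nf);
      if (hap) {
        uint64_t *g1 = rowNxt(2 * Nf + j);
        gamete_recomb(rowCur(2 * mo), rowCur(2 * mo + 1), g1);
        denovo(g1);
      } else {
        int fa = pick(cumM, Nm);
        uint64_t *g1 = rowNxt(2 * Nf + 2 * j), *g2 = rowNxt(2 * Nf + 2 * j + 1);
        gamete_recomb(rowCur(2 * mo), rowCur(2 * mo + 1), g1);
        denovo(g1);
        gamete_recomb(rowCur(2 * Nf + 2 * fa), rowCur(2 * Nf + 2 * fa + 1), g2);
        denovo(g2);
      }
    }

    // fixation / loss detection on the offspring generation
    int uw = usedW();
    for (int w = 0; w < uw; ++w) { andm[w] = ~0ULL; orm[w] = 0ULL; }
    for (int g = 0; g < nG; ++g) {
      const uint64_t *row = rowNxt(g);
      for (int w = 0; w < uw; ++w) { andm[w] &= row[w]; orm[w] |= row[w]; }
    }
    int subs = 0;
    for (int w = 0; w < uw; ++w) {
      uint64_t f = andm[w] & active[w];
      while (f) {
        int b = __builtin_ctzll(f); f &= f - 1;
        int sl = (w << 6) | b;
        int32_t id = slot_id[sl];
        mstate[id] = 1;
        fix_id.push_back(id); fix_gen.push_back(generation + 1);
        active[w] &= ~(1ULL << b);
        ++Fpend; ++subs;
      }
      uint64_t lo = active[w] & ~orm[w];
      while (lo) {
        int b = __builtin_ctzll(lo); lo &= lo - 1;
        int sl = (w << 6) | b;
        mstate[slot_id[sl]] = 2;
        active[w] &= ~(1ULL << b);
        ++n_lost;
      }
    }
    seg_now = 0;
    for (int w = 0; w < uw; ++w) seg_now += popcnt64(active[w]);
    cum_fix += subs;
    o_gen.push_back(generation + 1);
    o_sub.push_back(subs);
    o_cum.push_back((double)cum_fix);
    o_seg.push_back(seg_now);
    o_wf.push_back(NA_REAL);
    o_wm.push_back(NA_REAL);

    curIsA = !curIsA;
    ++generation;
  }

  // returns true if the run ended by absorption (mu == 0, nothing segregating)
  bool run(int total_generations, bool stop_on_absorption, bool fill) {
    o_gen.reserve(total_generations); o_sub.reserve(total_generations);
    o_seg.reserve(total_generations); o_cum.reserve(total_generations);
    o_wf.reserve(total_generations); o_wm.reserve(total_generations);
    for (int g = 0; g < total_generations; ++g) {
      step();
      if (mu <= 0 && seg_now == 0) {
        if (stop_on_absorption) return true;
        if (fill) {
          // the population is monomorphic: all later rows are deterministic
          if ((int)o_wf.size() >= generation) {
            o_wf[generation - 1] = 1.0;
            o_wm[generation - 1] = 1.0;
          }
          for (int g2 = g + 1; g2 < total_generations; ++g2) {
            o_gen.push_back(g2 + 1); o_sub.push_back(0);
            o_cum.push_back((double)cum_fix); o_seg.push_back(0);
            o_wf.push_back(1.0); o_wm.push_back(1.0);
          }
          return true;
        }
      }
    }
    fitness_pass();  // fill the final row's mean-fitness columns
    return false;
  }

  List export_population() {
    compact();  // purge pending fixed/lost; slot order = (position, id)
    int uw = usedW();
    std::vector<int> cnt(nslots, 0);
    List genomes(nG);
    for (int g = 0; g < nG; ++g) {
      const uint64_t *row = rowCur(g);
      std::vector<int> ids;
      for (int w = 0; w < uw; ++w) {
        uint64_t m = row[w];
        while (m) {
          int b = __builtin_ctzll(m); m &= m - 1;
          int sl = (w << 6) | b;
          ids.push_back(slot_id[sl] + 1);
          cnt[sl]++;
        }
      }
      genomes[g] = IntegerVector(ids.begin(), ids.end());
    }
    IntegerVector rid(nslots), rposn(nslots), rorig(nslots), rcnt(nslots);
    for (int k = 0; k < nslots; ++k) {
      rid[k] = slot_id[k] + 1;
      rposn[k] = mpos[slot_id[k]];
      rorig[k] = morigin[slot_id[k]];
      rcnt[k] = cnt[k];
    }
    return List::create(
      _["genomes"] = genomes,
      _["registry"] = DataFrame::create(
        _["id"] = rid, _["position"] = rposn,
        _["s"] = NumericVector(nslots, s), _["h"] = NumericVector(nslots, h),
        _["origin"] = rorig, _["count"] = rcnt));
  }
};

// [[Rcpp::export]]
List cpp_run_simulation(bool haplodiploid, int Nm, int Nf, double L,
                        double mu, double r, double s, double h, double h_hap,
                        int total_generations, int init_place, int init_position,
                        bool stop_on_absorption, bool export_population) {
  HDEngine e;
  e.init(haplodiploid, Nm, Nf, L, mu, r, s, h, h_hap, init_place, init_position);
  bool absorbed = e.run(total_generations, stop_on_absorption, true);
  int nfix = (int)e.fix_id.size();
  IntegerVector fid(nfix), fposn(nfix), forig(nfix), fgen(nfix);
  for (int k = 0; k < nfix; ++k) {
    fid[k] = e.fix_id[k] + 1;
    fposn[k] = e.mpos[e.fix_id[k]];
    forig[k] = e.morigin[e.fix_id[k]];
    fgen[k] = e.fix_gen[k];
  }
  List out = List::create(
    _["per_generation"] = DataFrame::create(
      _["generation"] = IntegerVector(e.o_gen.begin(), e.o_gen.end()),
      _["substitutions"] = IntegerVector(e.o_sub.begin(), e.o_sub.end()),
      _["cumulative_substitutions"] = NumericVector(e.o_cum.begin(), e.o_cum.end()),
      _["segregating"] = IntegerVector(e.o_seg.begin(), e.o_seg.end()),
      _["mean_fitness_females"] = NumericVector(e.o_wf.begin(), e.o_wf.end()),
      _["mean_fitness_males"] = NumericVector(e.o_wm.begin(), e.o_wm.end())),
    _["substitution_log"] = DataFrame::create(
      _["id"] = fid, _["position"] = fposn,
      _["s"] = NumericVector(nfix, s), _["h"] = NumericVector(nfix, h),
      _["origin_generation"] = forig, _["fixation_generation"] = fgen),
    _["n_created"] = (double)e.mpos.size(),
    _["n_lost"] = (double)e.n_lost,
    _["n_segregating_final"] = e.seg_now,
    _["generations_simulated"] = e.generation,
    _["absorbed"] = absorbed);
  if (export_population) out["final_population"] = e.export_population();
  return out;
}

// Repeated absorption runs of the full engine at a single locus (mu = 0),
// starting from one mutant copy; returns c(n_fixed, n_unresolved).
// [[Rcpp::export]]
IntegerVector cpp_fixation_replicates(bool haplodiploid, int Nm, int Nf,
                                      double s, double h, double h_hap,
                                      int n_rep, int init_place,
                                      int max_generations) {
  int n_fixed = 0, n_unres = 0;
  for (int rep = 0; rep < n_rep; ++rep) {
    HDEngine e;
    e.init(haplodiploid, Nm, Nf, 1.0, 0.0, 0.0, s, h, h_hap, init_place, 0);
    bool absorbed = e.run(max_generations, true, false);
    if (!absorbed && e.seg_now > 0) { ++n_unres; continue; }
    if (!e.fix_id.empty()) ++n_fixed;
  }
  return IntegerVector::create(n_fixed, n_unres);
}
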