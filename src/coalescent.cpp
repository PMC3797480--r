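// Hudson-style ancestral-recombination-graph simulator with piecewise-constant
// demography (size changes, population joins, symmetric migration), an
// infinite-sites mutation model mapped onto L discrete positions, and fast
// summary-statistic evaluation for ABC reference tables.
//
// Conventions (documented in the methods vignette):
//   * time is measured in units of 4N generations, N = reference size;
//   * a pair of lineages in a deme of relative size x coalesces at rate 2/x;
//   * mutations arise at rate theta (=4N*mu) per bp per unit branch length;
//   * a lineage recombines at rate rho (=4N*r per bp) * (ancestral span in bp);
//   * a lineage migrates at rate M/2 (M = 4N*m), ms's convention.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
#include <string>
using namespace Rcpp;

// ------------------------------------------------------------------ RNG ----
static inline uint64_t splitmix64_step(uint64_t& x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) s[i] = splitmix64_step(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0,1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double rexp(double rate) { return -std::log(unif()) / rate; }
  int rpois(double lam) {
    if (lam <= 0.0) return 0;
    if (lam > 60.0) { int a = rpois(lam * 0.5); return a + rpois(lam - lam * 0.5); }
    double L = std::exp(-lam), p = 1.0;
    int k = 0;
    do { k++; p *= unif(); } while (p > L);
    return k - 1;
  }
  int rint(int n) { int k = (int)(unif() * n); return k >= n ? n - 1 : k; }
};

static inline uint64_t fnv1a(const char* s) {
  uint64_t h = 1469598103934665603ULL;
  for (; *s; ++s) { h ^= (uint64_t)(unsigned char)*s; h *= 1099511628211ULL; }
  return h;
}

static inline uint64_t mix2(uint64_t a, uint64_t b) {
  uint64_t x = a ^ (b * 0x9E3779B97f4A7C15ULL + 0x632BE59BD9B4E019ULL);
  splitmix64_step(x);
  return splitmix64_step(x);
}

// --------------------------------------------------------------- segments ---
struct Seg { double l, r; uint64_t m; };

struct Lin {
  int deme;
  std::vector<Seg> s;
  double lo, hi, len;
  void update() {
    lo = s.front().l; hi = s.back().r; len = 0.0;
    for (size_t i = 0; i < s.size(); i++) len += s[i].r - s[i].l;
  }
};

struct Mut { double pos, l, r; uint64_t m; };

static inline void push_seg(std::vector<Seg>& out, double l, double r, uint64_t m,
                            uint64_t full) {
  if (r <= l || m == full) return;
  if (!out.empty() && out.back().r == l && out.back().m == m) { out.back().r = r; return; }
  out.push_back(Seg{l, r, m});
}

// merge two ancestral-segment lists; material where every sample has
// coalesced (mask == full) is dropped (local MRCA reached)
static void merge_segs(const std::vector<Seg>& av, const std::vector<Seg>& bv,
                       uint64_t full, std::vector<Seg>& out) {
  out.clear();
  size_t i = 0, j = 0;
  Seg A, B;
  bool haveA = i < av.size(), haveB = j < bv.size();
  if (haveA) { A = av[i++]; }
  if (haveB) { B = bv[j++]; }
  while (haveA && haveB) {
    if (A.r <= B.l) {
      push_seg(out, A.l, A.r, A.m, full);
      haveA = i < av.size(); if (haveA) A = av[i++];
      continue;
    }
    if (B.r <= A.l) {
      push_seg(out, B.l, B.r, B.m, full);
      haveB = j < bv.size(); if (haveB) B = bv[j++];
      continue;
    }
    double olo = std::max(A.l, B.l), ohi = std::min(A.r, B.r);
    if (A.l < olo) push_seg(out, A.l, olo, A.m, full);
    if (B.l < olo) push_seg(out, B.l, olo, B.m, full);
    push_seg(out, olo, ohi, A.m | B.m, full);
    if (A.r > ohi) A.l = ohi; else { haveA = i < av.size(); if (haveA) A = av[i++]; }
    if (B.r > ohi) B.l = ohi; else { haveB = j < bv.size(); if (haveB) B = bv[j++]; }
  }
  while (haveA) { push_seg(out, A.l, A.r, A.m, full); haveA = i < av.size(); if (haveA) A = av[i++]; }
  while (haveB) { push_seg(out, B.l, B.r, B.m, full); haveB = j < bv.size(); if (haveB) B = bv[j++]; }
}

// ------------------------------------------------------------- simulator ---
// events: rows (time, code, a, x) sorted by time
//   code 1: deme a gets relative size x
//   code 2: all lineages of deme a move to deme (int)x  (backwards join)
//   code 3: symmetric migration rate set to x
struct SimOut {
  std::vector<Mut> muts;
  double tree_len_bp;   // sum over lineages of (ancestral bp) x (time), so
                        // E[#mutations] = theta * tree_len_bp
};

static void sim_one_locus(int n1, int n2, double L, double theta, double rho,
                          std::vector<double> size, double mig,
                          const NumericMatrix& ev, Xoshiro& rng, SimOut& out) {
  const int n = n1 + n2;
  if (n < 2 || n > 63) stop("sample size must be in [2, 63]");
  const uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1);
  const int nd = (int)size.size();

  std::vector<Lin> lin;
  lin.reserve(2 * n);
  for (int i = 0; i < n; i++) {
    Lin l;
    l.deme = (i < n1) ? 0 : 1;
    if (nd == 1) l.deme = 0;
    l.s.push_back(Seg{0.0, L, 1ULL << i});
    l.update();
    lin.push_back(l);
  }

  out.muts.clear();
  out.tree_len_bp = 0.0;
  double t = 0.0;
  int evi = 0;
  const int nev = ev.nrow();
  long long guard = 0;
  std::vector<Seg> scratch;
  std::vector<int> didx;

  while (!lin.empty()) {
    if (++guard > 20000000LL) stop("simulation did not coalesce (event cap reached)");
    const int k = (int)lin.size();
    // per-deme counts and rates
    double crate[2] = {0.0, 0.0};
    int kd[2] = {0, 0};
    double span_tot = 0.0, len_tot = 0.0;
    for (int i = 0; i < k; i++) {
      kd[lin[i].deme]++;
      span_tot += lin[i].hi - lin[i].lo;
      len_tot += lin[i].len;
    }
    double ctot = 0.0;
    for (int d = 0; d < nd; d++) {
      crate[d] = (double)kd[d] * (kd[d] - 1) / size[d];
      ctot += crate[d];
    }
    const double rrate = (rho > 0.0) ? rho * span_tot : 0.0;
    const double mrate = (nd > 1 && mig > 0.0) ? 0.5 * mig * k : 0.0;
    const double R = ctot + rrate + mrate;

    double dt;
    bool do_event = false;
    if (R <= 0.0) {
      if (evi >= nev) stop("demography never brings remaining lineages together (no common ancestor)");
      dt = ev(evi, 0) - t;
      do_event = true;
    } else {
      dt = rng.rexp(R);
      if (evi < nev && t + dt >= ev(evi, 0)) { dt = ev(evi, 0) - t; do_event = true; }
    }
    if (dt < 0) dt = 0;

    // mutations dropped over the elapsed interval
    if (theta > 0.0 && len_tot > 0.0 && dt > 0.0) {
      for (int i = 0; i < k; i++) {
        int nm = rng.rpois(theta * lin[i].len * dt);
        for (int q = 0; q < nm; q++) {
          double u = rng.unif() * lin[i].len, acc = 0.0;
          for (size_t g = 0; g < lin[i].s.size(); g++) {
            double w = lin[i].s[g].r - lin[i].s[g].l;
            if (u <= acc + w || g + 1 == lin[i].s.size()) {
              double pos = lin[i].s[g].l + (u - acc);
              if (pos >= lin[i].s[g].r) pos = std::nextafter(lin[i].s[g].r, lin[i].s[g].l);
              out.muts.push_back(Mut{pos, lin[i].s[g].l, lin[i].s[g].r, lin[i].s[g].m});
              break;
            }
            acc += w;
          }
        }
      }
    }
    out.tree_len_bp += len_tot * dt;
    t += dt;

    if (do_event) {
      int code = (int)ev(evi, 1);
      int a = (int)ev(evi, 2);
      double x = ev(evi, 3);
      if (code == 1) {
        if (a < 0 || a >= nd) stop("size-change event for unknown deme");
        if (x <= 0) stop("relative deme size must be > 0");
        size[a] = x;
      } else if (code == 2) {
        int b = (int)x;
        if (a < 0 || a >= nd || b < 0 || b >= nd) stop("join event for unknown deme");
        for (int i = 0; i < k; i++) if (lin[i].deme == a) lin[i].deme = b;
      } else if (code == 3) {
        mig = x;
      } else stop("unknown demographic event code");
      evi++;
      continue;
    }

    double u = rng.unif() * R;
    if (u < ctot) {
      int d = 0;
      if (nd > 1 && u >= crate[0]) d = 1;
      didx.clear();
      for (int i = 0; i < k; i++) if (lin[i].deme == d) didx.push_back(i);
      int ia = rng.rint((int)didx.size());
      int ib = rng.rint((int)didx.size() - 1);
      if (ib >= ia) ib++;
      int i1 = didx[ia], i2 = didx[ib];
      merge_segs(lin[i1].s, lin[i2].s, full, scratch);
      if (i1 > i2) std::swap(i1, i2);
      if (scratch.empty()) {
        lin.erase(lin.begin() + i2);
        lin.erase(lin.begin() + i1);
      } else {
        lin[i1].s = scratch;
        lin[i1].update();
        lin.erase(lin.begin() + i2);
      }
    } else if (u < ctot + rrate) {
      double v = rng.unif() * span_tot, acc = 0.0;
      int pick = k - 1;
      for (int i = 0; i < k; i++) {
        double w = lin[i].hi - lin[i].lo;
        if (v <= acc + w) { pick = i; break; }
        acc += w;
      }
      Lin& P = lin[pick];
      if (P.hi - P.lo <= 0) continue;
      double bp = P.lo + rng.unif() * (P.hi - P.lo);
      if (bp <= P.lo || bp >= P.hi) continue;
      Lin right;
      right.deme = P.deme;
      std::vector<Seg> left;
      for (size_t g = 0; g < P.s.size(); g++) {
        const Seg& sg = P.s[g];
        if (sg.r <= bp) left.push_back(sg);
        else if (sg.l >= bp) right.s.push_back(sg);
        else {
          left.push_back(Seg{sg.l, bp, sg.m});
          right.s.push_back(Seg{bp, sg.r, sg.m});
        }
      }
      if (left.empty() || right.s.empty()) continue;  // breakpoint outside material
      P.s = left;
      P.update();
      right.update();
      lin.push_back(right);
    } else {
      int pick = rng.rint(k);
      lin[pick].deme = 1 - lin[pick].deme;
    }
  }
}

// place mutations on discrete positions 0..L-1, redrawing collisions within
// the originating ancestral segment
static void discretize(const std::vector<Mut>& muts, double L, Xoshiro& rng,
                       std::vector<int>& pos, std::vector<uint64_t>& mask) {
  pos.clear(); mask.clear();
  std::vector<char> used((size_t)L, 0);
  for (size_t i = 0; i < muts.size(); i++) {
    int p = (int)muts[i].pos;
    if (p >= (int)L) p = (int)L - 1;
    int tries = 0;
    while (used[p] && tries < 64) {
      double q = muts[i].l + rng.unif() * (muts[i].r - muts[i].l);
      p = (int)q;
      if (p >= (int)L) p = (int)L - 1;
      tries++;
    }
    if (used[p]) continue;  // saturated segment; drop (rare)
    used[p] = 1;
    pos.push_back(p);
    mask.push_back(muts[i].m);
  }
  // sort by position
  std::vector<size_t> ord(pos.size());
  for (size_t i = 0; i < ord.size(); i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return pos[a] < pos[b]; });
  std::vector<int> p2(pos.size());
  std::vector<uint64_t> m2(pos.size());
  for (size_t i = 0; i < ord.size(); i++) { p2[i] = pos[ord[i]]; m2[i] = mask[ord[i]]; }
  pos.swap(p2); mask.swap(m2);
}

// ------------------------------------------------------------ statistics ---
static void tajima_consts(int n, double& a1, double& e1, double& e2) {
  double a2 = 0.0;
  a1 = 0.0;
  for (int i = 1; i < n; i++) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  e1 = c1 / a1;
  e2 = c2 / (a1 * a1 + a2);
}

static double tajimas_d_cpp(int n, int S, double pitot) {
  if (S < 1) return NA_REAL;
  double a1, e1, e2;
  tajima_consts(n, a1, e1, e2);
  double denom = std::sqrt(e1 * S + e2 * (double)S * (S - 1));
  if (denom <= 0) return NA_REAL;
  return (pitot - S / a1) / denom;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; c++; } return c;
#endif
}

// haplotype counts from site masks: group the n samples by their joint
// pattern across sites; returns He with the n/(n-1) correction
static double hap_diversity_cpp(const std::vector<uint64_t>& mask, int n) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; i++) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    for (size_t s = 0; s < mask.size(); s++) {
      int ba = (int)((mask[s] >> a) & 1), bb = (int)((mask[s] >> b) & 1);
      if (ba != bb) return ba < bb;
    }
    return false;
  });
  double sum2 = 0.0;
  int run = 1;
  for (int i = 1; i <= n; i++) {
    bool same = false;
    if (i < n) {
      same = true;
      for (size_t s = 0; s < mask.size() && same; s++)
        if (((mask[s] >> idx[i - 1]) & 1) != ((mask[s] >> idx[i]) & 1)) same = false;
    }
    if (same) run++;
    else { double f = (double)run / n; sum2 += f * f; run = 1; }
  }
  return (double)n / (n - 1.0) * (1.0 - sum2);
}

struct LocusWithin { double thw, pi, he, d; bool mono; };

static LocusWithin within_locus_stats(const std::vector<uint64_t>& mask, int n, double L) {
  LocusWithin o;
  int S = (int)mask.size();
  double a1 = 0.0;
  for (int i = 1; i < n; i++) a1 += 1.0 / i;
  double pitot = 0.0;
  for (int s = 0; s < S; s++) {
    int d = popcount64(mask[s]);
    pitot += 2.0 * d * (n - d) / ((double)n * (n - 1));
  }
  o.thw = S / (a1 * L);
  o.pi = pitot / L;
  o.he = (S == 0) ? 0.0 : hap_diversity_cpp(mask, n);
  o.mono = (S == 0);
  double D = tajimas_d_cpp(n, S, pitot);
  o.d = ISNAN(D) ? 0.0 : D;  // 0-convention for the ABC stat vector
  return o;
}

static void mean_sd(const std::vector<double>& v, double& m, double& s) {
  int n = (int)v.size();
  m = 0.0;
  for (int i = 0; i < n; i++) m += v[i];
  m /= n;
  s = 0.0;
  if (n > 1) {
    for (int i = 0; i < n; i++) s += (v[i] - m) * (v[i] - m);
    s = std::sqrt(s / (n - 1));
  }
}

// ------------------------------------------------------------ R interface --
static std::vector<double> as_sizes(NumericVector sizes) {
  std::vector<double> s(sizes.begin(), sizes.end());
  if (s.empty() || s.size() > 2) stop("1 or 2 demes supported");
  for (size_t i = 0; i < s.size(); i++) if (s[i] <= 0) stop("deme sizes must be > 0");
  return s;
}

// Simulate every locus of a study design under one demography.
// mode 0: return per-locus site tables (positions, masks, derived counts)
// mode 1: return the 9 within-species ABC summary statistics
// mode 2: return the 21 between-species ABC summary statistics
// [[Rcpp::export]]
SEXP cpp_simulate_study(IntegerVector n1, IntegerVector n2, NumericVector L,
                        CharacterVector names, double theta, double rho,
                        NumericVector sizes, double mig, NumericMatrix events,
                        double seed, int mode) {
  const int nloc = n1.size();
  if (n2.size() != nloc || L.size() != nloc || names.size() != nloc)
    stop("locus configuration vectors must have equal length");
  std::vector<double> sz = as_sizes(sizes);
  if (events.ncol() != 4 && events.nrow() > 0) stop("events must have 4 columns");
  for (int e = 1; e < events.nrow(); e++)
    if (events(e, 0) < events(e - 1, 0)) stop("events must be sorted by time");
  if (theta < 0 || rho < 0) stop("theta and rho must be >= 0");

  SimOut out;
  std::vector<int> pos;
  std::vector<uint64_t> mask;

  List tables(nloc);
  std::vector<double> thw, pi, he, dd;
  int nmono = 0;
  // between-species accumulators
  std::vector<double> s1v, s2v, ssv, sfv, pi1v, pi2v, fstv, d1v;
  double tot_s1 = 0, tot_s2 = 0, tot_ss = 0, tot_sf = 0;
  int nloc_fixed = 0;

  for (int j = 0; j < nloc; j++) {
    uint64_t lseed = mix2((uint64_t)seed, fnv1a(CHAR(STRING_ELT(names, j))));
    Xoshiro rng(lseed);
    int m1 = n1[j], m2 = n2[j];
    if (sz.size() == 1 && m2 > 0) stop("two-deme sample with a one-deme demography");
    sim_one_locus(m1, m2, L[j], theta, rho, sz, mig, events, rng, out);
    discretize(out.muts, L[j], rng, pos, mask);
    const int n = m1 + m2;
    const int S = (int)pos.size();

    if (mode == 0) {
      IntegerVector P(S), D(S), D1(S);
      NumericVector M(S);
      uint64_t m1mask = (m1 >= 64) ? ~0ULL : ((1ULL << m1) - 1);
      for (int s = 0; s < S; s++) {
        P[s] = pos[s];
        D[s] = popcount64(mask[s]);
        D1[s] = popcount64(mask[s] & m1mask);
        M[s] = (double)mask[s];
      }
      tables[j] = List::create(_["pos"] = P, _["d"] = D, _["d1"] = D1,
                               _["mask"] = M, _["n"] = n, _["n1"] = m1,
                               _["L"] = L[j], _["tree_len_bp"] = out.tree_len_bp);
    } else if (mode == 1) {
      LocusWithin w = within_locus_stats(mask, n, L[j]);
      thw.push_back(w.thw); pi.push_back(w.pi); he.push_back(w.he); dd.push_back(w.d);
      if (w.mono) nmono++;
    } else {
      // Wakeley-Hey site classes + within/between diversity + pop-1 Tajima's D
      uint64_t m1mask = (m1 >= 64) ? ~0ULL : ((1ULL << m1) - 1);
      int S1 = 0, S2 = 0, Ss = 0, Sf = 0, Spop1 = 0;
      double pi1 = 0, pi2 = 0, pib = 0, pi1tot = 0;
      for (int s = 0; s < S; s++) {
        int d1 = popcount64(mask[s] & m1mask);
        int d2 = popcount64(mask[s]) - d1;
        bool p1 = d1 > 0 && d1 < m1, p2 = d2 > 0 && d2 < m2;
        if (p1 && p2) Ss++;
        else if (p1) S1++;
        else if (p2) S2++;
        else if ((d1 == 0 && d2 == m2) || (d1 == m1 && d2 == 0)) Sf++;
        if (p1) { Spop1++; pi1tot += 2.0 * d1 * (m1 - d1) / ((double)m1 * (m1 - 1)); }
        pi1 += 2.0 * d1 * (m1 - d1) / ((double)m1 * (m1 - 1));
        pi2 += 2.0 * d2 * (m2 - d2) / ((double)m2 * (m2 - 1));
        pib += (d1 * (double)(m2 - d2) + d2 * (double)(m1 - d1)) / ((double)m1 * m2);
      }
      double fst = (pib > 0) ? 1.0 - 0.5 * (pi1 + pi2) / pib : 0.0;
      double D1 = tajimas_d_cpp(m1, Spop1, pi1tot);
      s1v.push_back(S1); s2v.push_back(S2); ssv.push_back(Ss); sfv.push_back(Sf);
      pi1v.push_back(pi1 / L[j]); pi2v.push_back(pi2 / L[j]); fstv.push_back(fst);
      d1v.push_back(ISNAN(D1) ? 0.0 : D1);
      tot_s1 += S1; tot_s2 += S2; tot_ss += Ss; tot_sf += Sf;
      if (Sf > 0) nloc_fixed++;
    }
  }

  if (mode == 0) return tables;
  if (mode == 1) {
    NumericVector st(9);
    double m, s;
    mean_sd(thw, m, s); st[0] = m; st[1] = s;
    mean_sd(pi, m, s);  st[2] = m; st[3] = s;
    mean_sd(he, m, s);  st[4] = m; st[5] = s;
    mean_sd(dd, m, s);  st[6] = m; st[7] = s;
    st[8] = (double)nmono / nloc;
    return st;
  }
  NumericVector st(21);
  double m, s;
  mean_sd(s1v, m, s);  st[0] = m;  st[1] = s;
  mean_sd(s2v, m, s);  st[2] = m;  st[3] = s;
  mean_sd(ssv, m, s);  st[4] = m;  st[5] = s;
  mean_sd(sfv, m, s);  st[6] = m;  st[7] = s;
  mean_sd(pi1v, m, s); st[8] = m;  st[9] = s;
  mean_sd(pi2v, m, s); st[10] = m; st[11] = s;
  mean_sd(fstv, m, s); st[12] = m; st[13] = s;
  mean_sd(d1v, m, s);  st[14] = m; st[15] = s;
  st[16] = tot_s1; st[17] = tot_s2; st[18] = tot_ss; st[19] = tot_sf;
  st[20] = nloc_fixed;
  return st;
}

// Constant-size no-recombination genealogies conditioned on S segregating
// sites (mutations placed proportional to branch length); returns per-replicate
// Tajima's D and Fay & Wu's H (total), used for neutrality p-values.
// [[Rcpp::export]]
NumericMatrix cpp_fixed_s_reps(int n, int S, int reps, double seed) {
  if (n < 2) stop("n must be >= 2");
  if (S < 1) stop("S must be >= 1");
  Xoshiro rng(mix2((uint64_t)seed, 0xFEEDFACEULL));
  NumericMatrix out(reps, 2);
  std::vector<double> blen;
  std::vector<int> bdesc;
  std::vector<double> alen;   // active lineage accumulated length
  std::vector<int> adesc;
  for (int r = 0; r < reps; r++) {
    blen.clear(); bdesc.clear();
    alen.assign(n, 0.0);
    adesc.assign(n, 1);
    int k = n;
    while (k > 1) {
      double t = rng.rexp((double)k * (k - 1));  // scale cancels under fixed S
      for (int i = 0; i < k; i++) alen[i] += t;
      int ia = rng.rint(k), ib = rng.rint(k - 1);
      if (ib >= ia) ib++;
      blen.push_back(alen[ia]); bdesc.push_back(adesc[ia]);
      blen.push_back(alen[ib]); bdesc.push_back(adesc[ib]);
      int nd = adesc[ia] + adesc[ib];
      if (ia > ib) std::swap(ia, ib);
      adesc[ia] = nd; alen[ia] = 0.0;
      adesc.erase(adesc.begin() + ib); alen.erase(alen.begin() + ib);
      k--;
    }
    double tot = 0.0;
    for (size_t i = 0; i < blen.size(); i++) tot += blen[i];
    double pitot = 0.0, thH = 0.0;
    for (int s = 0; s < S; s++) {
      double u = rng.unif() * tot, acc = 0.0;
      int d = bdesc.back();
      for (size_t i = 0; i < blen.size(); i++) {
        if (u <= acc + blen[i]) { d = bdesc[i]; break; }
        acc += blen[i];
      }
      pitot += 2.0 * d * (n - d) / ((double)n * (n - 1));
      thH += 2.0 * (double)d * d / ((double)n * (n - 1));
    }
    out(r, 0) = tajimas_d_cpp(n, S, pitot);
    out(r, 1) = pitot - thH;
  }
  return out;
}

// deterministic seed derivation for independent simulation streams
// [[Rcpp::export]]
double cpp_mix_seed(double seed, double i) {
  uint64_t h = mix2((uint64_t)seed, (uint64_t)i + 0x51ED270B0ULL);
  return (double)(h >> 11);  // < 2^53, exactly representable
}
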