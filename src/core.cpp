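// Core engine: 2-bit packed canonical k-mers, sorted-array counting with
// strand attribution, conservative contig extension (count / strand-balance /
// bounded-path filters with bidirectional verification), pair connection by
// exhaustive bounded path enumeration, and seed-diagonal alignment blocks for
// the assembly evaluator.
//
// K-mers are packed most-significant-base-first and left-aligned so that the
// numeric order of the word vector equals the lexicographic order of the
// string; canonical form is min(forward, reverse complement).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
#include <map>

using namespace Rcpp;

static const int MAXW = 12;          // up to k = 384

// ---------------- base coding ----------------

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char I2B[4] = {'A', 'C', 'G', 'T'};

static inline char cpl(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = cpl(c);
  return r;
}

// ---------------- packed k-mers ----------------

struct KSpec {
  int k, W;
  uint64_t lastmask;
  explicit KSpec(int k_) : k(k_) {
    if (k < 1 || k > 32 * MAXW) stop("k out of supported range [1, %d]", 32 * MAXW);
    W = (k + 31) / 32;
    int nb = 2 * (k - 32 * (W - 1));
    lastmask = (nb >= 64) ? ~0ULL : (~0ULL << (64 - nb));
  }
};

struct KArr { uint64_t w[MAXW]; };

struct KView { KArr f, r; };        // forward and reverse-complement packings

static inline void shl_add(const KSpec& S, KArr& a, int b) {
  for (int i = 0; i + 1 < S.W; ++i) a.w[i] = (a.w[i] << 2) | (a.w[i + 1] >> 62);
  a.w[S.W - 1] <<= 2;
  int j = S.k - 1, wi = j >> 5, sh = 62 - 2 * (j & 31);
  a.w[wi] |= (uint64_t)b << sh;
  a.w[S.W - 1] &= S.lastmask;
}

static inline void shr_add(const KSpec& S, KArr& a, int b) {
  for (int i = S.W - 1; i > 0; --i) a.w[i] = (a.w[i] >> 2) | (a.w[i - 1] << 62);
  a.w[0] >>= 2;
  a.w[0] |= (uint64_t)b << 62;
  a.w[S.W - 1] &= S.lastmask;
}

static inline int cmpw(const KSpec& S, const uint64_t* a, const uint64_t* b) {
  for (int i = 0; i < S.W; ++i) {
    if (a[i] < b[i]) return -1;
    if (a[i] > b[i]) return 1;
  }
  return 0;
}

static inline void step_right(const KSpec& S, const KView& x, int b, KView& y) {
  y = x;
  shl_add(S, y.f, b);
  shr_add(S, y.r, 3 - b);
}

static bool encode_kmer(const KSpec& S, const char* s, KView& v) {
  std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
  std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
  for (int i = 0; i < S.k; ++i) {
    int b = b2i(s[i]);
    if (b < 0) return false;
    shl_add(S, v.f, b);
    shr_add(S, v.r, 3 - b);
  }
  return true;
}

static std::string decode_kmer(const KSpec& S, const uint64_t* w) {
  std::string s(S.k, 'A');
  for (int j = 0; j < S.k; ++j) {
    int wi = j >> 5, sh = 62 - 2 * (j & 31);
    s[j] = I2B[(w[wi] >> sh) & 3];
  }
  return s;
}

static uint64_t mixhash(const uint64_t* w, int W) {
  uint64_t h = 0x9e3779b97f4a7c15ULL;
  for (int i = 0; i < W; ++i) {
    uint64_t x = w[i] + h;
    x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
    x ^= x >> 27; x *= 0x94d049bb133111ebULL;
    x ^= x >> 31;
    h = x;
  }
  return h;
}

// Iterate all valid windows (no N) of all sequences; fn(canonical_words, is_plus).
template <class F>
static void for_each_window(const std::vector<std::string>& seqs, const KSpec& S, F fn) {
  KView v;
  for (const auto& s : seqs) {
    if ((int)s.size() < S.k) continue;
    std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
    std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = b2i(s[i]);
      if (b < 0) { valid = 0; continue; }
      shl_add(S, v.f, b);
      shr_add(S, v.r, 3 - b);
      if (++valid >= S.k) {
        int c = cmpw(S, v.f.w, v.r.w);
        fn((c <= 0) ? v.f.w : v.r.w, c <= 0);
      }
    }
  }
}

// ---------------- k-mer table ----------------

struct KmerTable {
  KSpec S;
  size_t n = 0;
  std::vector<uint64_t> keys;          // n * W, sorted ascending
  std::vector<uint32_t> plus, minus;
  std::vector<uint8_t> used;
  explicit KmerTable(int k) : S(k) {}
  const uint64_t* key(size_t i) const { return &keys[i * S.W]; }
  long long find(const uint64_t* q) const {
    size_t lo = 0, hi = n;
    while (lo < hi) {
      size_t mid = lo + (hi - lo) / 2;
      if (cmpw(S, key(mid), q) < 0) lo = mid + 1; else hi = mid;
    }
    if (lo < n && cmpw(S, key(lo), q) == 0) return (long long)lo;
    return -1;
  }
  void push_entry(const uint64_t* kw, uint32_t p, uint32_t m) {
    for (int w = 0; w < S.W; ++w) keys.push_back(kw[w]);
    plus.push_back(p);
    minus.push_back(m);
    ++n;
  }
};

static std::vector<std::string> as_strvec(const CharacterVector& x) {
  std::vector<std::string> v;
  v.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v.push_back(as<std::string>(x[i]));
  return v;
}

static KmerTable* build_table(const std::vector<std::string>& seqs, int k,
                              int c_min, int n_batches) {
  KmerTable* T = new KmerTable(k);
  const KSpec& S = T->S;
  for (int batch = 0; batch < n_batches; ++batch) {
    if (k <= 31) {
      // single word, low bit free for the strand flag
      std::vector<uint64_t> buf;
      for_each_window(seqs, S, [&](const uint64_t* kw, bool plus) {
        if (n_batches > 1 && (int)(mixhash(kw, 1) % n_batches) != batch) return;
        buf.push_back(kw[0] | (plus ? 0ULL : 1ULL));
      });
      std::sort(buf.begin(), buf.end());
      size_t i = 0;
      while (i < buf.size()) {
        uint64_t key = buf[i] & ~1ULL;
        uint32_t p = 0, m = 0;
        while (i < buf.size() && (buf[i] & ~1ULL) == key) {
          if (buf[i] & 1ULL) ++m; else ++p;
          ++i;
        }
        if (p + m >= (uint32_t)c_min) T->push_entry(&key, p, m);
      }
    } else if (k <= 63) {
      // two words packed into one 128-bit value, strand in the lowest bit
      std::vector<unsigned __int128> buf;
      for_each_window(seqs, S, [&](const uint64_t* kw, bool plus) {
        if (n_batches > 1 && (int)(mixhash(kw, 2) % n_batches) != batch) return;
        unsigned __int128 v = ((unsigned __int128)kw[0] << 64) | kw[1] | (plus ? 0 : 1);
        buf.push_back(v);
      });
      std::sort(buf.begin(), buf.end());
      size_t i = 0;
      while (i < buf.size()) {
        unsigned __int128 key = buf[i] & ~(unsigned __int128)1;
        uint32_t p = 0, m = 0;
        while (i < buf.size() && (buf[i] & ~(unsigned __int128)1) == key) {
          if ((uint64_t)(buf[i] & 1)) ++m; else ++p;
          ++i;
        }
        if (p + m >= (uint32_t)c_min) {
          uint64_t kw[2] = {(uint64_t)(key >> 64), (uint64_t)key};
          T->push_entry(kw, p, m);
        }
      }
    } else {
      // generic: flat key buffer plus index sort
      std::vector<uint64_t> flat;
      std::vector<uint8_t> strand;
      for_each_window(seqs, S, [&](const uint64_t* kw, bool plus) {
        if (n_batches > 1 && (int)(mixhash(kw, S.W) % n_batches) != batch) return;
        for (int w = 0; w < S.W; ++w) flat.push_back(kw[w]);
        strand.push_back(plus ? 0 : 1);
      });
      size_t m = strand.size();
      std::vector<uint32_t> idx(m);
      for (size_t i = 0; i < m; ++i) idx[i] = (uint32_t)i;
      std::sort(idx.begin(), idx.end(), [&](uint32_t a, uint32_t b) {
        return cmpw(S, &flat[(size_t)a * S.W], &flat[(size_t)b * S.W]) < 0;
      });
      size_t i = 0;
      while (i < m) {
        const uint64_t* kw = &flat[(size_t)idx[i] * S.W];
        uint32_t p = 0, mi = 0;
        while (i < m && cmpw(S, &flat[(size_t)idx[i] * S.W], kw) == 0) {
          if (strand[idx[i]]) ++mi; else ++p;
          ++i;
        }
        if (p + mi >= (uint32_t)c_min) T->push_entry(kw, p, mi);
      }
    }
  }
  if (n_batches > 1) {
    // entries from different hash batches are disjoint but interleaved: re-sort
    std::vector<uint32_t> idx(T->n);
    for (size_t i = 0; i < T->n; ++i) idx[i] = (uint32_t)i;
    std::sort(idx.begin(), idx.end(), [&](uint32_t a, uint32_t b) {
      return cmpw(S, T->key(a), T->key(b)) < 0;
    });
    std::vector<uint64_t> keys2(T->keys.size());
    std::vector<uint32_t> p2(T->n), m2(T->n);
    for (size_t i = 0; i < T->n; ++i) {
      std::memcpy(&keys2[i * S.W], T->key(idx[i]), sizeof(uint64_t) * S.W);
      p2[i] = T->plus[idx[i]];
      m2[i] = T->minus[idx[i]];
    }
    T->keys.swap(keys2);
    T->plus.swap(p2);
    T->minus.swap(m2);
  }
  T->used.assign(T->n, 0);
  return T;
}

static KmerTable* get_tbl(SEXP xp) {
  XPtr<KmerTable> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP kt_build(CharacterVector seqs, int k, int c_min, int n_batches) {
  std::vector<std::string> v = as_strvec(seqs);
  KmerTable* T = build_table(v, k, c_min, n_batches < 1 ? 1 : n_batches);
  XPtr<KmerTable> p(T, true);
  return p;
}

// [[Rcpp::export]]
List kt_info(SEXP xp) {
  KmerTable* T = get_tbl(xp);
  return List::create(_["k"] = T->S.k, _["n"] = (double)T->n);
}

// [[Rcpp::export]]
DataFrame kt_dump(SEXP xp, double max_n) {
  KmerTable* T = get_tbl(xp);
  size_t m = T->n;
  if (max_n >= 0 && (double)m > max_n) m = (size_t)max_n;
  CharacterVector km(m);
  IntegerVector p(m), mi(m);
  for (size_t i = 0; i < m; ++i) {
    km[i] = decode_kmer(T->S, T->key(i));
    p[i] = (int)T->plus[i];
    mi[i] = (int)T->minus[i];
  }
  return DataFrame::create(_["kmer"] = km, _["plus"] = p, _["minus"] = mi,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame kt_histogram_cpp(SEXP xp) {
  KmerTable* T = get_tbl(xp);
  std::map<uint32_t, int> bins;
  for (size_t i = 0; i < T->n; ++i) ++bins[T->plus[i] + T->minus[i]];
  IntegerVector cnt(bins.size()), mult(bins.size());
  int j = 0;
  for (auto& kv : bins) { cnt[j] = (int)kv.first; mult[j] = kv.second; ++j; }
  return DataFrame::create(_["count"] = cnt, _["n_kmers"] = mult);
}

// [[Rcpp::export]]
double kt_mean_count(SEXP xp) {
  KmerTable* T = get_tbl(xp);
  if (T->n == 0) return 0.0;
  double s = 0;
  for (size_t i = 0; i < T->n; ++i) s += (double)T->plus[i] + T->minus[i];
  return s / (double)T->n;
}

// [[Rcpp::export]]
DataFrame kt_lookup(SEXP xp, CharacterVector kmers) {
  KmerTable* T = get_tbl(xp);
  const KSpec& S = T->S;
  R_xlen_t m = kmers.size();
  LogicalVector present(m), usd(m);
  IntegerVector p(m), mi(m);
  KView v;
  for (R_xlen_t i = 0; i < m; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != S.k || !encode_kmer(S, s.data(), v)) {
      present[i] = false; p[i] = 0; mi[i] = 0; usd[i] = false;
      continue;
    }
    const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
    long long ix = T->find(canon);
    present[i] = ix >= 0;
    p[i] = ix >= 0 ? (int)T->plus[ix] : 0;
    mi[i] = ix >= 0 ? (int)T->minus[ix] : 0;
    usd[i] = ix >= 0 ? (bool)T->used[ix] : false;
  }
  return DataFrame::create(_["present"] = present, _["plus"] = p,
                           _["minus"] = mi, _["used"] = usd);
}

// [[Rcpp::export]]
void kt_set_used(SEXP xp, CharacterVector kmers, bool value) {
  KmerTable* T = get_tbl(xp);
  const KSpec& S = T->S;
  KView v;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != S.k || !encode_kmer(S, s.data(), v)) continue;
    const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
    long long ix = T->find(canon);
    if (ix >= 0) T->used[ix] = value ? 1 : 0;
  }
}

// [[Rcpp::export]]
void kt_reset_used(SEXP xp) {
  KmerTable* T = get_tbl(xp);
  std::fill(T->used.begin(), T->used.end(), 0);
}

// total windows / windows containing N, for conservation checks
// [[Rcpp::export]]
List count_windows_cpp(CharacterVector seqs, int k) {
  std::vector<std::string> v = as_strvec(seqs);
  double total = 0, with_n = 0;
  for (const auto& s : v) {
    if ((int)s.size() < k) continue;
    int nwin = (int)s.size() - k + 1;
    total += nwin;
    // windows containing at least one non-ACGT base
    std::vector<int> bad;
    for (size_t i = 0; i < s.size(); ++i) if (b2i(s[i]) < 0) bad.push_back((int)i);
    if (!bad.empty()) {
      std::vector<char> hit(nwin, 0);
      for (int p : bad)
        for (int w = std::max(0, p - k + 1); w <= std::min(nwin - 1, p); ++w) hit[w] = 1;
      for (int w = 0; w < nwin; ++w) with_n += hit[w];
    }
  }
  return List::create(_["total"] = total, _["with_n"] = with_n);
}

// ---------------- extension machinery ----------------

struct Params {
  double ext_frac, balance_frac;
  int fork_steps;
};

struct Cand {
  bool present[4];
  long long idx[4];
  double tot[4];
  uint32_t p[4], m[4];
  KView y[4];
};

static void candidates_of(const KmerTable& T, const KView& x, Cand& C) {
  for (int b = 0; b < 4; ++b) {
    step_right(T.S, x, b, C.y[b]);
    const uint64_t* canon = (cmpw(T.S, C.y[b].f.w, C.y[b].r.w) <= 0) ? C.y[b].f.w : C.y[b].r.w;
    long long ix = T.find(canon);
    C.idx[b] = ix;
    C.present[b] = ix >= 0;
    if (ix >= 0) {
      C.p[b] = T.plus[ix];
      C.m[b] = T.minus[ix];
      C.tot[b] = (double)T.plus[ix] + T.minus[ix];
    } else {
      C.p[b] = C.m[b] = 0;
      C.tot[b] = 0;
    }
  }
}

static int count_filter_mask(const Cand& C, double ext_frac) {
  double mx = 0;
  for (int b = 0; b < 4; ++b) if (C.present[b] && C.tot[b] > mx) mx = C.tot[b];
  int mask = 0;
  for (int b = 0; b < 4; ++b)
    if (C.present[b] && C.tot[b] >= ext_frac * mx - 1e-9) mask |= 1 << b;
  return mask;
}

static int strand_filter_mask(const Cand& C, int mask, double balance_frac) {
  int bal = 0;
  for (int b = 0; b < 4; ++b) if (mask & (1 << b)) {
    double p = C.p[b], m = C.m[b];
    if (std::min(p, m) >= balance_frac * (p + m) - 1e-9) bal |= 1 << b;
  }
  return bal ? bal : mask;
}

// Greedy bounded walk used for fork resolution.  Filters use counts only
// (never the used flags) so the outcome does not depend on assembly order.
// A walk that itself forks is ambiguous and counts as surviving.
static bool walk_survives(const KmerTable& T, KView cur, const Params& P) {
  Cand C;
  for (int s = 0; s < P.fork_steps; ++s) {
    candidates_of(T, cur, C);
    int mask = count_filter_mask(C, P.ext_frac);
    if (!mask) return false;                      // died at a dead end
    if (__builtin_popcount((unsigned)mask) > 1)
      mask = strand_filter_mask(C, mask, P.balance_frac);
    if (__builtin_popcount((unsigned)mask) > 1) return true;
    cur = C.y[__builtin_ctz((unsigned)mask)];
  }
  return true;
}

// One-directional cascade: 0 = dead end, 1 = unique (bout set), 2 = break.
static int cascade(const KmerTable& T, const KView& x, const Params& P,
                   Cand& C, int& bout) {
  candidates_of(T, x, C);
  int mask = count_filter_mask(C, P.ext_frac);
  if (!mask) return 0;
  if (__builtin_popcount((unsigned)mask) > 1)
    mask = strand_filter_mask(C, mask, P.balance_frac);
  if (__builtin_popcount((unsigned)mask) > 1) {
    int surv = 0, sb = -1;
    for (int b = 0; b < 4; ++b) if (mask & (1 << b)) {
      if (walk_survives(T, C.y[b], P)) {
        ++surv;
        sb = b;
        if (surv > 1) break;
      }
    }
    if (surv != 1) return 2;
    bout = sb;
    return 1;
  }
  bout = __builtin_ctz((unsigned)mask);
  return 1;
}

// Full step: unique forward extension that is also the unique backward
// extension of the new k-mer (bidirectional verification).
static int step_verified(const KmerTable& T, const KView& x, const Params& P,
                         Cand& C, int& bout) {
  int st = cascade(T, x, P, C, bout);
  if (st != 1) return st;
  KView yr;
  yr.f = C.y[bout].r;
  yr.r = C.y[bout].f;
  Cand C2;
  int b2;
  int st2 = cascade(T, yr, P, C2, b2);
  if (st2 != 1) return 2;
  if (cmpw(T.S, C2.y[b2].f.w, x.r.w) != 0) return 2;
  return 1;
}

enum { R_NONE = 0, R_DEAD = 1, R_BREAK = 2, R_COLL = 3 };

struct Ctg {
  std::string seq;
  bool circ = false, prior = false, dead = false;
  bool fresh_l = true, fresh_r = true;
  int reason_l = R_NONE, reason_r = R_NONE;
  int added_l = 0, added_r = 0;
};

static void flip_ctg(Ctg& c) {
  c.seq = revcomp_str(c.seq);
  std::swap(c.reason_l, c.reason_r);
  std::swap(c.added_l, c.added_r);
  std::swap(c.fresh_l, c.fresh_r);
}

// Extend seq rightward, claiming k-mers.  Sets circ when the extension closes
// on the sequence's own first k-mer in the same orientation.
static int do_extend_right(KmerTable& T, const Params& P, std::string& seq,
                           int& added, bool& circ) {
  const KSpec& S = T.S;
  KView x, f0;
  if (!encode_kmer(S, seq.data() + seq.size() - S.k, x)) return R_DEAD;
  encode_kmer(S, seq.data(), f0);
  Cand C;
  int b;
  for (;;) {
    int st = step_verified(T, x, P, C, b);
    if (st == 0) return R_DEAD;
    if (st == 2) return R_BREAK;
    long long iy = C.idx[b];
    if (T.used[iy]) {
      if (cmpw(S, C.y[b].f.w, f0.f.w) == 0) {
        // closed on its own start: drop the duplicated k-1 wraparound bases
        circ = true;
        seq.erase(seq.size() - (size_t)(S.k - 1));
        return R_NONE;
      }
      return R_COLL;
    }
    T.used[iy] = 1;
    seq.push_back(I2B[b]);
    ++added;
    x = C.y[b];
  }
}

static int do_extend_left(KmerTable& T, const Params& P, std::string& seq,
                          int& added, bool& circ) {
  std::string r = revcomp_str(seq);
  int st = do_extend_right(T, P, r, added, circ);
  seq = revcomp_str(r);
  return st;
}

static void claim_seq(KmerTable& T, const std::string& seq) {
  std::vector<std::string> one(1, seq);
  for_each_window(one, T.S, [&](const uint64_t* kw, bool) {
    long long ix = T.find(kw);
    if (ix >= 0) T.used[ix] = 1;
  });
}

// One assembly iteration at the table's k.  Prior contigs are claimed and
// end-extended first; fresh contigs are seeded from unused above-valley
// k-mers in canonical (or partition-interleaved) order; a post-pass connector
// heals collisions, detects circles and merges across iterations' seams.
// [[Rcpp::export]]
List asm_iterate(SEXP xp, int valley, double ext_frac, double balance_frac,
                 CharacterVector prior_seq, LogicalVector prior_circ,
                 int n_partitions) {
  KmerTable& T = *get_tbl(xp);
  const KSpec& S = T.S;
  Params P{ext_frac, balance_frac, std::max(100, S.k)};
  std::vector<Ctg> ctgs;

  // prior contigs: claim their k-mers, then try to grow their ends
  for (R_xlen_t i = 0; i < prior_seq.size(); ++i) {
    Ctg c;
    c.seq = as<std::string>(prior_seq[i]);
    c.circ = prior_circ[i];
    c.prior = true;
    c.fresh_l = c.fresh_r = false;
    claim_seq(T, c.seq);
    ctgs.push_back(std::move(c));
  }
  for (auto& c : ctgs) {
    if (c.circ || (int)c.seq.size() < S.k) continue;
    bool circ = false;
    c.reason_r = do_extend_right(T, P, c.seq, c.added_r, circ);
    if (circ) { c.circ = true; c.reason_l = c.reason_r = R_NONE; continue; }
    circ = false;
    c.reason_l = do_extend_left(T, P, c.seq, c.added_l, circ);
    if (circ) { c.circ = true; c.reason_l = c.reason_r = R_NONE; }
  }

  // fresh seeds
  int Pn = n_partitions < 1 ? 1 : n_partitions;
  for (int part = 0; part < Pn; ++part) {
    for (size_t i = part; i < T.n; i += Pn) {
      if (T.used[i]) continue;
      if ((int)(T.plus[i] + T.minus[i]) <= valley) continue;
      Ctg c;
      c.seq = decode_kmer(S, T.key(i));
      T.used[i] = 1;
      bool circ = false;
      c.reason_r = do_extend_right(T, P, c.seq, c.added_r, circ);
      if (circ) {
        c.circ = true;
        c.reason_l = c.reason_r = R_NONE;
      } else {
        circ = false;
        c.reason_l = do_extend_left(T, P, c.seq, c.added_l, circ);
        if (circ) { c.circ = true; c.reason_l = c.reason_r = R_NONE; }
      }
      ctgs.push_back(std::move(c));
    }
  }

  // connector: heal collision ends (merge fragments, close circles)
  bool changed = true;
  while (changed) {
    changed = false;
    std::unordered_map<std::string, std::pair<int, int>> tmap;  // end 0=left, 1=right
    for (int i = 0; i < (int)ctgs.size(); ++i) {
      Ctg& c = ctgs[i];
      if (c.dead || c.circ || (int)c.seq.size() < S.k) continue;
      tmap[c.seq.substr(0, S.k)] = {i, 0};
      tmap[revcomp_str(c.seq.substr(c.seq.size() - S.k))] = {i, 1};
    }
    for (int i = 0; i < (int)ctgs.size() && !changed; ++i) {
      Ctg& c = ctgs[i];
      if (c.dead || c.circ || (int)c.seq.size() < S.k) continue;
      if (c.reason_r != R_COLL && c.reason_l == R_COLL) flip_ctg(c);
      if (c.reason_r != R_COLL) continue;
      KView x;
      encode_kmer(S, c.seq.data() + c.seq.size() - S.k, x);
      Cand C;
      int b;
      int st = step_verified(T, x, P, C, b);
      if (st != 1) {
        c.reason_r = (st == 0) ? R_DEAD : R_BREAK;
        changed = true;
        continue;
      }
      std::string y = decode_kmer(S, C.y[b].f.w);
      if (y == c.seq.substr(0, S.k)) {          // closed on itself
        c.circ = true;
        c.seq.erase(c.seq.size() - (size_t)(S.k - 1));
        c.reason_l = c.reason_r = R_NONE;
        changed = true;
        continue;
      }
      auto it = tmap.find(y);
      if (it == tmap.end() || it->second.first == i) {
        c.reason_r = R_BREAK;                   // collided into a contig interior
        changed = true;
        continue;
      }
      Ctg& d = ctgs[it->second.first];
      if (d.dead || d.circ) {
        c.reason_r = R_BREAK;
        changed = true;
        continue;
      }
      if (it->second.second == 1) flip_ctg(d);
      c.seq += d.seq.substr(S.k - 1);
      c.reason_r = d.reason_r;
      c.added_r = d.added_r;
      c.fresh_r = d.fresh_r;
      c.prior = c.prior || d.prior;
      d.dead = true;
      changed = true;
    }
  }

  // end-trimming and short-contig drop
  for (auto& c : ctgs) {
    if (c.dead || c.circ) continue;
    int trim_l = 0, trim_r = 0;
    if (c.reason_l == R_DEAD || c.reason_l == R_BREAK || c.reason_l == R_COLL)
      trim_l = c.fresh_l ? S.k - 1 : std::min(S.k - 1, c.added_l);
    if (c.reason_r == R_DEAD || c.reason_r == R_BREAK || c.reason_r == R_COLL)
      trim_r = c.fresh_r ? S.k - 1 : std::min(S.k - 1, c.added_r);
    if (trim_l + trim_r >= (int)c.seq.size()) {
      if (!c.prior) c.dead = true;
      continue;
    }
    if (trim_r > 0) c.seq.erase(c.seq.size() - trim_r);
    if (trim_l > 0) c.seq.erase(0, trim_l);
    if (!c.prior && (int)c.seq.size() < S.k) c.dead = true;
  }

  std::vector<std::string> out;
  std::vector<int> circ;
  for (auto& c : ctgs) {
    if (c.dead) continue;
    out.push_back(c.seq);
    circ.push_back(c.circ ? 1 : 0);
  }
  return List::create(_["seq"] = wrap(out), _["circular"] = wrap(circ));
}

// Diagnostic: per-base candidate counts for the k-mer at a contig end.
// [[Rcpp::export]]
List candidate_bases_cpp(SEXP xp, std::string kmer, bool include_used) {
  KmerTable& T = *get_tbl(xp);
  const KSpec& S = T.S;
  if ((int)kmer.size() != S.k) stop("k-mer length does not match table k");
  KView x;
  if (!encode_kmer(S, kmer.data(), x)) stop("k-mer contains non-ACGT characters");
  Cand C;
  candidates_of(T, x, C);
  IntegerVector p(4), m(4);
  LogicalVector usd(4);
  for (int b = 0; b < 4; ++b) {
    bool u = C.present[b] && T.used[C.idx[b]];
    usd[b] = u;
    if (C.present[b] && (include_used || !u)) {
      p[b] = (int)C.p[b];
      m[b] = (int)C.m[b];
    } else {
      p[b] = 0;
      m[b] = 0;
    }
  }
  p.attr("names") = CharacterVector::create("A", "C", "G", "T");
  m.attr("names") = CharacterVector::create("A", "C", "G", "T");
  return List::create(_["plus"] = p, _["minus"] = m, _["used"] = usd);
}

// Diagnostic: run the filter cascade (optionally with bidirectional
// verification) from an oriented k-mer.  status: 0 dead end, 1 unique, 2 break.
// [[Rcpp::export]]
List cascade_cpp(SEXP xp, std::string kmer, double ext_frac, double balance_frac,
                 bool bidirectional) {
  KmerTable& T = *get_tbl(xp);
  const KSpec& S = T.S;
  if ((int)kmer.size() != S.k) stop("k-mer length does not match table k");
  KView x;
  if (!encode_kmer(S, kmer.data(), x)) stop("k-mer contains non-ACGT characters");
  Params P{ext_frac, balance_frac, std::max(100, S.k)};
  Cand C;
  int b = -1;
  int st = bidirectional ? step_verified(T, x, P, C, b) : cascade(T, x, P, C, b);
  std::string base = (st == 1) ? std::string(1, I2B[b]) : std::string();
  return List::create(_["status"] = st, _["base"] = base);
}

// ---------------- pair connection ----------------

struct DFS {
  const KmerTable* T;
  KArr target;
  int maxdepth;
  long long steps, budget;
  bool overflow;
  int nhits;
  std::string hit1, path;

  void go(const KView& cur, int depth) {
    if (overflow || nhits > 1) return;
    if (depth > 0 && cmpw(T->S, cur.f.w, target.w) == 0) {
      ++nhits;
      if (nhits == 1) hit1 = path;
      if (nhits > 1) return;
    }
    if (depth >= maxdepth) return;
    if (++steps > budget) { overflow = true; return; }
    Cand C;
    candidates_of(*T, cur, C);
    for (int b = 0; b < 4; ++b) {
      if (!C.present[b]) continue;
      path.push_back(I2B[b]);
      go(C.y[b], depth + 1);
      path.pop_back();
      if (overflow || nhits > 1) return;
    }
  }
};

// All fragments consistent with the pair: direct overlap placements (mates
// overlapping by >= k) plus graph paths between the anchor k-mers.  Empty
// string when zero or more than one candidate exists.
static std::string search_dir(const KmerTable& T, const std::string& m1,
                              const std::string& m2, int max_insert,
                              long long budget) {
  const KSpec& S = T.S;
  int k = S.k;
  int L1 = (int)m1.size(), L2 = (int)m2.size();
  if (L1 < k || L2 < k) return "";
  std::string fr = revcomp_str(m2);
  std::vector<std::string> frags;
  for (int p = 0; p + k <= L1; ++p) {
    int ov = L1 - p;
    if (ov > L2) continue;
    if (p + L2 > max_insert) continue;
    if (std::memcmp(m1.data() + p, fr.data(), ov) == 0)
      frags.push_back(m1.substr(0, (size_t)p) + fr);
  }
  KView a, t;
  bool ok = encode_kmer(S, m1.data() + L1 - k, a) && encode_kmer(S, fr.data(), t);
  if (ok) {
    const uint64_t* ca = (cmpw(S, a.f.w, a.r.w) <= 0) ? a.f.w : a.r.w;
    const uint64_t* ct = (cmpw(S, t.f.w, t.r.w) <= 0) ? t.f.w : t.r.w;
    if (T.find(ca) >= 0 && T.find(ct) >= 0) {
      DFS dfs;
      dfs.T = &T;
      dfs.target = t.f;
      dfs.maxdepth = max_insert - L1 - L2 + k;
      dfs.steps = 0;
      dfs.budget = budget;
      dfs.overflow = false;
      dfs.nhits = 0;
      if (dfs.maxdepth > 0) dfs.go(a, 0);
      if (dfs.overflow || dfs.nhits > 1) return "";
      if (dfs.nhits == 1) frags.push_back(m1 + dfs.hit1 + fr.substr(k));
    }
  }
  if (frags.size() != 1) return "";
  return frags[0];
}

static std::string connect_one(const KmerTable& T, const std::string& m1,
                               const std::string& m2, int max_insert,
                               long long budget) {
  std::string fwd = search_dir(T, m1, m2, max_insert, budget);
  if (fwd.empty()) return "";
  std::string rev = search_dir(T, m2, m1, max_insert, budget);
  if (rev.empty()) return "";
  if (revcomp_str(rev) != fwd) return "";
  return fwd;
}

// [[Rcpp::export]]
CharacterVector cpp_connect_pairs(SEXP xp, CharacterVector m1, CharacterVector m2,
                                  int max_insert, double path_cap) {
  KmerTable& T = *get_tbl(xp);
  R_xlen_t n = m1.size();
  if (m2.size() != n) stop("mate vectors differ in length");
  long long budget = (long long)(path_cap * (double)max_insert);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string f = connect_one(T, as<std::string>(m1[i]), as<std::string>(m2[i]),
                                max_insert, budget);
    if (f.empty()) out[i] = NA_STRING; else out[i] = f;
  }
  return out;
}

// ---------------- marking reads as used ----------------

// sorted flat key store for ad-hoc k-mer sets
struct KeySet {
  KSpec S;
  std::vector<uint64_t> keys;
  std::vector<int> aux1, aux2;         // optional payload per key
  size_t n = 0;
  explicit KeySet(int k) : S(k) {}
  const uint64_t* key(size_t i) const { return &keys[i * S.W]; }
  long long find(const uint64_t* q) const {
    size_t lo = 0, hi = n;
    while (lo < hi) {
      size_t mid = lo + (hi - lo) / 2;
      if (cmpw(S, key(mid), q) < 0) lo = mid + 1; else hi = mid;
    }
    if (lo < n && cmpw(S, key(lo), q) == 0) return (long long)lo;
    return -1;
  }
  void finalize(bool keep_aux, bool drop_dups) {
    // sort by key; with keep_aux retain payload of the first occurrence and
    // record multiplicity in aux2's sign (negative = ambiguous)
    size_t m = n;
    std::vector<uint32_t> idx(m);
    for (size_t i = 0; i < m; ++i) idx[i] = (uint32_t)i;
    std::sort(idx.begin(), idx.end(), [&](uint32_t a, uint32_t b) {
      return cmpw(S, key(a), key(b)) < 0;
    });
    std::vector<uint64_t> k2;
    std::vector<int> a1, a2;
    size_t i = 0;
    while (i < m) {
      const uint64_t* kw = key(idx[i]);
      size_t j = i;
      while (j < m && cmpw(S, key(idx[j]), kw) == 0) ++j;
      bool dup = (j - i) > 1;
      if (!(dup && drop_dups)) {
        for (int w = 0; w < S.W; ++w) k2.push_back(kw[w]);
        if (keep_aux) {
          a1.push_back(aux1[idx[i]]);
          a2.push_back(dup ? -(int)(j - i) : aux2[idx[i]]);
        }
      }
      i = j;
    }
    keys.swap(k2);
    aux1.swap(a1);
    aux2.swap(a2);
    n = keys.size() / S.W;
  }
};

// [[Rcpp::export]]
LogicalVector cpp_mark_used_reads(CharacterVector contigs, LogicalVector circular,
                                  CharacterVector reads, int k, double M) {
  KSpec S(k);
  KeySet KS(k);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    bool circ = circular[ci];
    std::string scan = circ ? seq + seq.substr(0, (size_t)std::min((int)seq.size(), k - 1)) : seq;
    int L = (int)seq.size();
    if ((int)scan.size() < k) continue;
    // roll over scan, keep qualifying windows
    KView v;
    std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
    std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
    int valid = 0;
    for (size_t i = 0; i < scan.size(); ++i) {
      int b = b2i(scan[i]);
      if (b < 0) { valid = 0; continue; }
      shl_add(S, v.f, b);
      shr_add(S, v.r, 3 - b);
      if (++valid < k) continue;
      int o = (int)i - k + 1;                   // window start
      bool okwin = circ || ((double)o > M && (double)(L - o - k) > M);
      if (!okwin) continue;
      const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
      for (int w = 0; w < S.W; ++w) KS.keys.push_back(canon[w]);
      ++KS.n;
    }
  }
  KS.finalize(false, false);
  R_xlen_t nr = reads.size();
  LogicalVector out(nr);
  for (R_xlen_t ri = 0; ri < nr; ++ri) {
    std::string s = as<std::string>(reads[ri]);
    bool hit = false;
    if ((int)s.size() >= k && KS.n > 0) {
      KView v;
      std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
      std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
      int valid = 0;
      for (size_t i = 0; i < s.size() && !hit; ++i) {
        int b = b2i(s[i]);
        if (b < 0) { valid = 0; continue; }
        shl_add(S, v.f, b);
        shr_add(S, v.r, 3 - b);
        if (++valid < k) continue;
        const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
        if (KS.find(canon) >= 0) hit = true;
      }
    }
    out[ri] = hit;
  }
  return out;
}

// Map each mate pair onto contigs by unique k-mer hits; returns per pair the
// 1-based contig index (0 = unmapped/ambiguous), and the 1-based inclusive
// span [start, end] of matched k-mer footprints on the contig (circular
// contigs are scanned doubled; positions refer to the doubled sequence).
// [[Rcpp::export]]
IntegerMatrix cpp_map_pairs(CharacterVector contigs, LogicalVector circular,
                            CharacterVector m1, CharacterVector m2, int k) {
  KSpec S(k);
  KeySet KS(k);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    if (circular[ci]) seq += seq;
    if ((int)seq.size() < k) continue;
    KView v;
    std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
    std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = b2i(seq[i]);
      if (b < 0) { valid = 0; continue; }
      shl_add(S, v.f, b);
      shr_add(S, v.r, 3 - b);
      if (++valid < k) continue;
      const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
      for (int w = 0; w < S.W; ++w) KS.keys.push_back(canon[w]);
      KS.aux1.push_back((int)ci);
      KS.aux2.push_back((int)i - k + 1);
      ++KS.n;
    }
  }
  KS.finalize(true, false);

  R_xlen_t np = m1.size();
  IntegerMatrix out(np, 3);
  for (R_xlen_t pi = 0; pi < np; ++pi) {
    int ctg = -1, lo = -1, hi = -1;
    bool conflict = false;
    for (int mate = 0; mate < 2 && !conflict; ++mate) {
      std::string s = as<std::string>(mate == 0 ? m1[pi] : m2[pi]);
      if ((int)s.size() < k) continue;
      KView v;
      std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
      std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
      int valid = 0;
      for (size_t i = 0; i < s.size() && !conflict; ++i) {
        int b = b2i(s[i]);
        if (b < 0) { valid = 0; continue; }
        shl_add(S, v.f, b);
        shr_add(S, v.r, 3 - b);
        if (++valid < k) continue;
        const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
        long long ix = KS.find(canon);
        if (ix < 0) continue;
        if (KS.aux2[ix] < 0) continue;         // multi-mapping k-mer: skip
        int c = KS.aux1[ix], pos = KS.aux2[ix];
        if (ctg < 0) { ctg = c; lo = hi = pos; }
        else if (c != ctg) conflict = true;
        else { lo = std::min(lo, pos); hi = std::max(hi, pos); }
      }
    }
    if (conflict || ctg < 0) {
      out(pi, 0) = 0;
      out(pi, 1) = out(pi, 2) = NA_INTEGER;
    } else {
      out(pi, 0) = ctg + 1;
      out(pi, 1) = lo + 1;
      out(pi, 2) = hi + k;                     // inclusive end of footprint
    }
  }
  return out;
}

// ---------------- read trimming support ----------------

// Census of 19-mers (or any k <= 31): number of distinct reads containing
// each canonical k-mer in either orientation.
// [[Rcpp::export]]
DataFrame cpp_kmer_read_census(CharacterVector reads, int k, double min_reads) {
  if (k > 31) stop("census k must be <= 31");
  KSpec S(k);
  std::vector<std::pair<uint64_t, uint32_t>> recs;   // (canonical key, read id)
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string s = as<std::string>(reads[ri]);
    if ((int)s.size() < k) continue;
    KView v;
    std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
    std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = b2i(s[i]);
      if (b < 0) { valid = 0; continue; }
      shl_add(S, v.f, b);
      shr_add(S, v.r, 3 - b);
      if (++valid >= k) {
        uint64_t canon = (v.f.w[0] <= v.r.w[0]) ? v.f.w[0] : v.r.w[0];
        recs.emplace_back(canon, (uint32_t)ri);
      }
    }
  }
  std::sort(recs.begin(), recs.end());
  recs.erase(std::unique(recs.begin(), recs.end()), recs.end());
  size_t i = 0;
  std::vector<std::pair<double, std::string>> keep;
  while (i < recs.size()) {
    uint64_t key = recs[i].first;
    size_t j = i;
    while (j < recs.size() && recs[j].first == key) ++j;
    double cnt = (double)(j - i);
    if (cnt >= min_reads) keep.emplace_back(cnt, decode_kmer(S, &key));
    i = j;
  }
  CharacterVector kk(keep.size());
  NumericVector nn(keep.size());
  for (size_t t = 0; t < keep.size(); ++t) {
    kk[t] = keep[t].second;
    nn[t] = keep[t].first;
  }
  return DataFrame::create(_["kmer"] = kk, _["n_reads"] = nn,
                           _["stringsAsFactors"] = false);
}

// First position (0-based) at which a canonical suspect k-mer starts in each
// read, or -1 when none occurs.
// [[Rcpp::export]]
IntegerVector cpp_first_suspect_pos(CharacterVector reads, CharacterVector suspects,
                                    int k) {
  if (k > 31) stop("suspect k must be <= 31");
  KSpec S(k);
  std::vector<uint64_t> keys;
  KView v;
  for (R_xlen_t i = 0; i < suspects.size(); ++i) {
    std::string s = as<std::string>(suspects[i]);
    if ((int)s.size() != k || !encode_kmer(S, s.data(), v)) continue;
    keys.push_back(std::min(v.f.w[0], v.r.w[0]));
  }
  std::sort(keys.begin(), keys.end());
  IntegerVector out(reads.size());
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string s = as<std::string>(reads[ri]);
    int pos = -1;
    if ((int)s.size() >= k && !keys.empty()) {
      std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
      std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
      int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = b2i(s[i]);
        if (b < 0) { valid = 0; continue; }
        shl_add(S, v.f, b);
        shr_add(S, v.r, 3 - b);
        if (++valid < k) continue;
        uint64_t canon = std::min(v.f.w[0], v.r.w[0]);
        if (std::binary_search(keys.begin(), keys.end(), canon)) {
          pos = (int)i - k + 1;
          break;
        }
      }
    }
    out[ri] = pos;
  }
  return out;
}

// ---------------- misc sequence utilities ----------------

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}

// Canonical rotation of a circular sequence: over both strands and all
// rotations, start at the lexicographically smallest k-mer (ties broken by
// the full rotation string).
// [[Rcpp::export]]
std::string cpp_canonical_rotation(std::string seq, int k) {
  int L = (int)seq.size();
  if (L < k) return seq;
  std::string best;
  for (int strand = 0; strand < 2; ++strand) {
    std::string s = strand ? revcomp_str(seq) : seq;
    std::string d = s + s.substr(0, (size_t)(k - 1));
    // find minimal k-substring over start positions 0..L-1
    int bestpos = 0;
    for (int i = 1; i < L; ++i)
      if (d.compare(i, k, d, bestpos, k) < 0) bestpos = i;
    // all positions achieving the minimum: compare full rotations
    std::string minmer = d.substr(bestpos, k);
    for (int i = 0; i < L; ++i) {
      if (d.compare(i, k, minmer) != 0) continue;
      std::string rot = s.substr(i) + s.substr(0, i);
      if (best.empty() || rot < best) best = rot;
    }
  }
  return best;
}

// Mean total count of the table's k-mers over the windows of a sequence
// (absent windows count zero); circular sequences wrap.
// [[Rcpp::export]]
double cpp_mean_window_count(SEXP xp, std::string seq, bool circular) {
  KmerTable& T = *get_tbl(xp);
  const KSpec& S = T.S;
  std::string scan = circular ? seq + seq.substr(0, (size_t)std::min((int)seq.size(), S.k - 1))
                              : seq;
  if ((int)scan.size() < S.k) return 0.0;
  double s = 0;
  long n = 0;
  KView v;
  std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
  std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
  int valid = 0;
  for (size_t i = 0; i < scan.size(); ++i) {
    int b = b2i(scan[i]);
    if (b < 0) { valid = 0; ++n; continue; }   // N windows count zero
    shl_add(S, v.f, b);
    shr_add(S, v.r, 3 - b);
    if (++valid < S.k) continue;
    const uint64_t* canon = (cmpw(S, v.f.w, v.r.w) <= 0) ? v.f.w : v.r.w;
    long long ix = T.find(canon);
    s += (ix >= 0) ? (double)T.plus[ix] + T.minus[ix] : 0.0;
    ++n;
  }
  return n > 0 ? s / (double)n : 0.0;
}

// [[Rcpp::export]]
double cpp_count_mismatches(std::string a, std::string b) {
  size_t n = std::min(a.size(), b.size());
  double mm = 0;
  for (size_t i = 0; i < n; ++i) if (a[i] != b[i]) ++mm;
  return mm;
}

// ---------------- evaluator: seed-diagonal alignment blocks ----------------

// Exact seed matches between contig and reference grouped by (strand,
// diagonal); blocks are maximal diagonal runs extended outward while bases
// match.  Positions are 1-based; query coordinates refer to the oriented
// (forward or reverse-complemented) contig.
// [[Rcpp::export]]
DataFrame cpp_align_blocks(std::string ref, std::string contig, int seedlen,
                           int max_occ) {
  if (seedlen > 31) stop("seed length must be <= 31");
  KSpec S(seedlen);
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    KView v;
    std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
    std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
    int valid = 0;
    for (size_t i = 0; i < ref.size(); ++i) {
      int b = b2i(ref[i]);
      if (b < 0) { valid = 0; continue; }
      shl_add(S, v.f, b);
      if (++valid >= seedlen) index[v.f.w[0]].push_back((int)i - seedlen + 1);
    }
  }
  std::vector<int> o_strand, o_qs, o_qe, o_rs, o_re;
  std::vector<double> o_mm;
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = strand ? revcomp_str(contig) : contig;
    std::map<long long, std::pair<int, int>> diags;   // diag -> [min,max] query pos
    KView v;
    std::memset(v.f.w, 0, sizeof(uint64_t) * S.W);
    std::memset(v.r.w, 0, sizeof(uint64_t) * S.W);
    int valid = 0;
    for (size_t i = 0; i < q.size(); ++i) {
      int b = b2i(q[i]);
      if (b < 0) { valid = 0; continue; }
      shl_add(S, v.f, b);
      if (++valid < seedlen) continue;
      auto it = index.find(v.f.w[0]);
      if (it == index.end() || (int)it->second.size() > max_occ) continue;
      int qp = (int)i - seedlen + 1;
      for (int rp : it->second) {
        long long dg = (long long)rp - qp;
        auto dit = diags.find(dg);
        if (dit == diags.end()) diags[dg] = {qp, qp};
        else {
          dit->second.first = std::min(dit->second.first, qp);
          dit->second.second = std::max(dit->second.second, qp);
        }
      }
    }
    for (auto& kv : diags) {
      long long dg = kv.first;
      int qs = kv.second.first, qe = kv.second.second + seedlen - 1; // inclusive
      // extend outward while bases match
      while (qs > 0 && dg + qs - 1 >= 0 && dg + qs - 1 < (long long)ref.size() &&
             q[qs - 1] == ref[dg + qs - 1]) --qs;
      while (qe + 1 < (int)q.size() && dg + qe + 1 < (long long)ref.size() &&
             q[qe + 1] == ref[dg + qe + 1]) ++qe;
      double mm = 0;
      for (int p = qs; p <= qe; ++p) {
        long long rp = dg + p;
        if (rp < 0 || rp >= (long long)ref.size() || q[p] != ref[rp]) ++mm;
      }
      o_strand.push_back(strand ? -1 : 1);
      o_qs.push_back(qs + 1);
      o_qe.push_back(qe + 1);
      o_rs.push_back((int)(dg + qs) + 1);
      o_re.push_back((int)(dg + qe) + 1);
      o_mm.push_back(mm);
    }
  }
  return DataFrame::create(_["strand"] = wrap(o_strand), _["qstart"] = wrap(o_qs),
                           _["qend"] = wrap(o_qe), _["rstart"] = wrap(o_rs),
                           _["rend"] = wrap(o_re), _["mismatches"] = wrap(o_mm));
}
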