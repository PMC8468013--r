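// Core sequence kernels: global affine-gap alignment, k-mer counting,
// greedy centroid clustering, and primer-site scanning.
//
// Conventions fixed across the package:
//  - scoring: match +1, mismatch -1; a gap run of length L costs
//    gap_open + L * gap_ext (open charged once per run, extension per column);
//  - identity = match columns / total alignment columns (terminal gaps count);
//  - 'N' (or any character outside A/C/G/T for nucleotide input) never matches,
//    not even another 'N';
//  - tie-breaking in the DP is fixed (diagonal > gap-in-b > gap-in-a) so the
//    reported alignment is deterministic across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

// ---------------------------------------------------------------------------
// encoding helpers

static inline int8_t enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // ambiguous: never matches
  }
}

static std::vector<int8_t> encode_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

// For protein (or arbitrary-alphabet) input we align on raw characters;
// encode to small ints via identity of the char, ambiguity char 'X' never
// matches. Nucleotide and generic modes share one code path: characters are
// compared by code, code -1 never matches.
static std::vector<int16_t> encode_generic(const std::string& s, bool nucleotide) {
  std::vector<int16_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    if (nucleotide) {
      v[i] = enc_base(s[i]);
    } else {
      char c = std::toupper(static_cast<unsigned char>(s[i]));
      v[i] = (c == 'X' || c == '*') ? -1 : static_cast<int16_t>(c);
    }
  }
  return v;
}

static inline bool chars_match(int16_t a, int16_t b) {
  return a >= 0 && b >= 0 && a == b;
}

// ---------------------------------------------------------------------------
// Global affine alignment, score + identity only (two-row DP, no traceback).
// Each DP state packs (score, matches, paired columns) into one int64
// (score bits 28+, matches bits 14-27, pairs bits 0-13), so a single max()
// implements the deterministic tie-break: among score-optimal alignments the
// one with the most matches, then the most paired columns, is reported.
// Sequence lengths are limited to 16383 by the 14-bit fields.

struct AlnStats {
  int score;
  int matches;
  int pairs;   // columns pairing two residues (match or mismatch)
};

static const int64_t PK_NEG = std::numeric_limits<int64_t>::min() / 4;

static inline int64_t pk(int score, int matches, int pairs) {
  return static_cast<int64_t>(score) * (int64_t(1) << 28) +
         (static_cast<int64_t>(matches) << 14) +
         static_cast<int64_t>(pairs);
}

static inline int64_t max3i(int64_t a, int64_t b, int64_t c) {
  return std::max(a, std::max(b, c));
}

static AlnStats nw_stats(const std::vector<int16_t>& a, const std::vector<int16_t>& b,
                         int match, int mismatch, int gap_open, int gap_ext) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n > 16383 || m > 16383) stop("sequence longer than 16383 not supported");
  const int64_t INC_MATCH = pk(match, 1, 1);
  const int64_t INC_MISM  = pk(mismatch, 0, 1);
  const int64_t PEN_OPEN  = static_cast<int64_t>(gap_open + gap_ext) * (int64_t(1) << 28);
  const int64_t PEN_EXT   = static_cast<int64_t>(gap_ext) * (int64_t(1) << 28);

  // layers: M (diag), X (gap in b: consumes a), Y (gap in a: consumes b)
  std::vector<int64_t> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<int64_t> pM(m + 1), pX(m + 1), pY(m + 1);
  pM[0] = 0; pX[0] = PK_NEG; pY[0] = PK_NEG;
  for (int j = 1; j <= m; ++j) {
    pM[j] = PK_NEG; pX[j] = PK_NEG;
    pY[j] = pk(-(gap_open + j * gap_ext), 0, 0);
  }
  const int64_t INC_DIFF = INC_MATCH - INC_MISM;
  for (int i = 1; i <= n; ++i) {
    M[0] = PK_NEG; Y[0] = PK_NEG;
    X[0] = pk(-(gap_open + i * gap_ext), 0, 0);
    const int16_t ai = a[i - 1];
    int64_t yprev = PK_NEG;          // Y(i, j-1)
    int64_t mleft = M[0], xleft = X[0];  // M(i, j-1), X(i, j-1)
    int64_t mdiag = pM[0], xdiag = pX[0], ydiag = pY[0];
    int64_t* __restrict Mr = M.data(); int64_t* __restrict Xr = X.data();
    int64_t* __restrict Yr = Y.data();
    const int64_t* __restrict pMr = pM.data();
    const int64_t* __restrict pXr = pX.data();
    const int64_t* __restrict pYr = pY.data();
    const int16_t* __restrict br = b.data();
    for (int j = 1; j <= m; ++j) {
      const int64_t inc = INC_MISM +
        (static_cast<int64_t>(ai >= 0 && ai == br[j - 1]) * INC_DIFF);
      const int64_t mv = max3i(mdiag, xdiag, ydiag) + inc;
      const int64_t xv = max3i(pMr[j] - PEN_OPEN, pXr[j] - PEN_EXT,
                               pYr[j] - PEN_OPEN);
      const int64_t yv = std::max(std::max(mleft, xleft) - PEN_OPEN,
                                  yprev - PEN_EXT);
      mdiag = pMr[j]; xdiag = pXr[j]; ydiag = pYr[j];
      mleft = mv; xleft = xv;
      Mr[j] = mv; Xr[j] = xv; Yr[j] = yv; yprev = yv;
    }
    std::swap(M, pM); std::swap(X, pX); std::swap(Y, pY);
  }
  const int64_t best = max3i(pM[m], pX[m], pY[m]);
  AlnStats out;
  out.score = static_cast<int>(best >> 28);
  out.matches = static_cast<int>((best >> 14) & 0x3FFF);
  out.pairs = static_cast<int>(best & 0x3FFF);
  return out;
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_ext,
                     bool nucleotide) {
  if (a.empty() || b.empty()) stop("empty sequence in alignment");
  std::vector<int16_t> ea = encode_generic(a, nucleotide);
  std::vector<int16_t> eb = encode_generic(b, nucleotide);
  AlnStats s = nw_stats(ea, eb, match, mismatch, gap_open, gap_ext);
  int cols = static_cast<int>(a.size() + b.size()) - s.pairs;
  return List::create(_["identity"] = static_cast<double>(s.matches) / cols,
                      _["matches"] = s.matches,
                      _["columns"] = cols,
                      _["score"] = s.score);
}

// ---------------------------------------------------------------------------
// Full alignment with traceback (aligned strings); used for the concatenated
// core-gene alignment, where cluster members are projected onto the
// representative's coordinates.

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_ext,
                  bool nucleotide) {
  if (a.empty() || b.empty()) stop("empty sequence in alignment");
  std::vector<int16_t> ea = encode_generic(a, nucleotide);
  std::vector<int16_t> eb = encode_generic(b, nucleotide);
  const int n = static_cast<int>(a.size()), m = static_cast<int>(b.size());
  const size_t W = static_cast<size_t>(m) + 1;
  std::vector<int> Ms(W * (n + 1), NEG_INF), Xs(W * (n + 1), NEG_INF), Ys(W * (n + 1), NEG_INF);
  // traceback codes: predecessor layer 0=M,1=X,2=Y
  std::vector<int8_t> Mt(W * (n + 1)), Xt(W * (n + 1)), Yt(W * (n + 1));
  Ms[0] = 0;
  for (int j = 1; j <= m; ++j) { Ys[j] = -(gap_open + j * gap_ext); Yt[j] = (j == 1) ? 0 : 2; }
  for (int i = 1; i <= n; ++i) { Xs[i * W] = -(gap_open + i * gap_ext); Xt[i * W] = (i == 1) ? 0 : 1; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j, l = i * W + (j - 1);
      const int sub = chars_match(ea[i - 1], eb[j - 1]) ? match : mismatch;
      int bs = Ms[d]; int8_t bt = 0;
      if (Xs[d] > bs) { bs = Xs[d]; bt = 1; }
      if (Ys[d] > bs) { bs = Ys[d]; bt = 2; }
      if (bs > NEG_INF) { Ms[c] = bs + sub; Mt[c] = bt; }
      int xo = (Ms[u] > NEG_INF) ? Ms[u] - gap_open - gap_ext : NEG_INF;
      int xe = (Xs[u] > NEG_INF) ? Xs[u] - gap_ext : NEG_INF;
      int xy = (Ys[u] > NEG_INF) ? Ys[u] - gap_open - gap_ext : NEG_INF;
      if (xo >= xe && xo >= xy) { Xs[c] = xo; Xt[c] = 0; }
      else if (xe >= xy)        { Xs[c] = xe; Xt[c] = 1; }
      else                      { Xs[c] = xy; Xt[c] = 2; }
      int yo = (Ms[l] > NEG_INF) ? Ms[l] - gap_open - gap_ext : NEG_INF;
      int yx = (Xs[l] > NEG_INF) ? Xs[l] - gap_open - gap_ext : NEG_INF;
      int ye = (Ys[l] > NEG_INF) ? Ys[l] - gap_ext : NEG_INF;
      if (yo >= yx && yo >= ye) { Ys[c] = yo; Yt[c] = 0; }
      else if (yx >= ye)        { Ys[c] = yx; Yt[c] = 1; }
      else                      { Ys[c] = ye; Yt[c] = 2; }
    }
  }
  // terminal layer
  const size_t end = static_cast<size_t>(n) * W + m;
  int layer = 0, best = Ms[end];
  if (Xs[end] > best) { best = Xs[end]; layer = 1; }
  if (Ys[end] > best) { best = Ys[end]; layer = 2; }
  std::string aa, ab;
  aa.reserve(n + m); ab.reserve(n + m);
  int i = n, j = m, matches = 0;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (layer == 0 && i > 0 && j > 0) {
      aa.push_back(a[i - 1]); ab.push_back(b[j - 1]);
      if (chars_match(ea[i - 1], eb[j - 1])) ++matches;
      layer = Mt[c]; --i; --j;
    } else if (layer == 1 && i > 0) {
      aa.push_back(a[i - 1]); ab.push_back('-');
      layer = Xt[c]; --i;
    } else if (layer == 2 && j > 0) {
      aa.push_back('-');
      ab.push_back(b[j - 1]);
      layer = Yt[c]; --j;
    } else {
      // boundary: forced moves
      if (i > 0) { aa.push_back(a[i - 1]); ab.push_back('-'); --i; }
      else       { aa.push_back('-'); ab.push_back(b[j - 1]); --j; }
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  return List::create(_["aligned_a"] = aa, _["aligned_b"] = ab,
                      _["identity"] = static_cast<double>(matches) / aa.size(),
                      _["matches"] = matches,
                      _["columns"] = static_cast<int>(aa.size()),
                      _["score"] = best);
}

// ---------------------------------------------------------------------------
// k-mer machinery (2-bit encoded, windows containing N are skipped)

static std::vector<uint32_t> kmer_list(const std::vector<int8_t>& s, int k) {
  std::vector<uint32_t> out;
  const int n = static_cast<int>(s.size());
  if (n < k) return out;
  out.reserve(n - k + 1);
  uint32_t val = 0;
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int run = 0; // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    if (s[i] < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | static_cast<uint32_t>(s[i])) & mask;
    if (++run >= k) out.push_back(val);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// multiset intersection size of two sorted k-mer lists
static int shared_kmers(const std::vector<uint32_t>& x, const std::vector<uint32_t>& y) {
  size_t i = 0, j = 0; int n = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (y[j] < x[i]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// [[Rcpp::export(name = ".shared_kmer_count_cpp")]]
int shared_kmer_count_cpp(std::string a, std::string b, int k) {
  std::vector<uint32_t> ka = kmer_list(encode_seq(a), k);
  std::vector<uint32_t> kb = kmer_list(encode_seq(b), k);
  return shared_kmers(ka, kb);
}

// ---------------------------------------------------------------------------
// Greedy centroid clustering. Sequences must arrive in canonical order
// (length desc, then id); each becomes a member of the first accepted
// representative, candidates examined in descending shared-k-mer order
// (ties: older representative first), with maxaccepts=1 and a maxrejects cap
// on failed alignments. Provably non-matching candidates
// (len_short/len_long < cutoff  =>  identity < cutoff) are skipped free.

// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
List greedy_cluster_cpp(CharacterVector seqs, double cutoff, int k, int maxrejects,
                        int match, int mismatch, int gap_open, int gap_ext,
                        bool nucleotide) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  std::vector<std::vector<int16_t>> enc(n);
  std::vector<std::vector<uint32_t>> km(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    enc[i] = encode_generic(ss[i], nucleotide);
    len[i] = static_cast<int>(ss[i].size());
    if (nucleotide) {
      km[i] = kmer_list(encode_seq(ss[i]), k);
    } else {
      // generic alphabet: hash successive k chars into 32 bits
      std::vector<uint32_t> v;
      const std::string& s = ss[i];
      if (static_cast<int>(s.size()) >= k) {
        v.reserve(s.size() - k + 1);
        for (size_t p = 0; p + k <= s.size(); ++p) {
          uint32_t h = 2166136261u;
          for (int q = 0; q < k; ++q) { h ^= static_cast<uint8_t>(s[p + q]); h *= 16777619u; }
          v.push_back(h);
        }
        std::sort(v.begin(), v.end());
      }
      km[i] = v;
    }
  }

  std::vector<int> reps;                 // gene index of each representative
  IntegerVector cluster(n);              // cluster index (0-based, founding order)
  NumericVector ident(n);
  std::vector<std::pair<int,int>> order; // (-shared, rep_rank) sort keys, reused

  for (int i = 0; i < n; ++i) {
    int chosen = -1; double chosen_id = 1.0;
    const int nr = static_cast<int>(reps.size());
    if (nr > 0) {
      order.clear(); order.reserve(nr);
      std::vector<int> sh(nr);
      for (int r = 0; r < nr; ++r) sh[r] = shared_kmers(km[i], km[reps[r]]);
      std::vector<int> idx(nr);
      for (int r = 0; r < nr; ++r) idx[r] = r;
      std::stable_sort(idx.begin(), idx.end(), [&](int x, int y) {
        if (sh[x] != sh[y]) return sh[x] > sh[y];
        return x < y;
      });
      int rejects = 0;
      for (int t = 0; t < nr && rejects < maxrejects; ++t) {
        const int g = reps[idx[t]];
        const int ls = std::min(len[i], len[g]), ll = std::max(len[i], len[g]);
        if (static_cast<double>(ls) / ll < cutoff) continue; // provable miss, free
        AlnStats st = nw_stats(enc[i], enc[g], match, mismatch, gap_open, gap_ext);
        const int cols = len[i] + len[g] - st.pairs;
        const double id = static_cast<double>(st.matches) / cols;
        if (id >= cutoff) { chosen = idx[t]; chosen_id = id; break; }
        ++rejects;
      }
    }
    if (chosen < 0) {
      reps.push_back(i);
      cluster[i] = static_cast<int>(reps.size()) - 1;
      ident[i] = 1.0;
    } else {
      cluster[i] = chosen;
      ident[i] = chosen_id;
    }
  }

  IntegerVector repv(reps.size());
  for (size_t r = 0; r < reps.size(); ++r) repv[r] = reps[r] + 1; // 1-based
  cluster = cluster + 1;
  return List::create(_["cluster"] = cluster, _["identity"] = ident,
                      _["representative"] = repv);
}

// ---------------------------------------------------------------------------
// Primer site scan: occurrences of `pattern` in `seq` with at most max_mm
// mismatches; positions flagged in `exact` (1-based within pattern) must
// match exactly. Indels are not modelled (primer binding surrogate).
// Returns 1-based start positions and mismatch counts.

// [[Rcpp::export(name = ".primer_scan_cpp")]]
List primer_scan_cpp(std::string seq, std::string pattern, int max_mm,
                     IntegerVector exact) {
  std::vector<int8_t> s = encode_seq(seq), p = encode_seq(pattern);
  const int n = static_cast<int>(s.size()), m = static_cast<int>(p.size());
  std::vector<bool> must(m, false);
  for (int e : exact) {
    if (e < 1 || e > m) stop("exact position outside pattern");
    must[e - 1] = true;
  }
  std::vector<int> starts, mms;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0; bool ok = true;
    for (int j = 0; j < m; ++j) {
      const bool hit = (p[j] >= 0 && s[i + j] == p[j]);
      if (!hit) {
        if (must[j]) { ok = false; break; }
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(i + 1); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}
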