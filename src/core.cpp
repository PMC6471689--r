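#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2-bit DNA codes: A=0, C=1, G=2, T=3. The mapping preserves lexicographic
// order (A<C<G<T), so integer comparison of equal-length packed words agrees
// with string comparison.
// ---------------------------------------------------------------------------

static const int SYMS_PER_WORD = 31;  // 62 payload bits; sign bit stays 0

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char code_base(int c) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[c];
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static std::string hex16(uint64_t w) {
  static const char* d = "0123456789abcdef";
  std::string s(16, '0');
  for (int i = 15; i >= 0; --i) { s[i] = d[w & 0xF]; w >>= 4; }
  return s;
}

static uint64_t parse_hex(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) {
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else stop("invalid hex word '%s'", s.c_str());
    v = (v << 4) | (uint64_t)d;
  }
  return v;
}

// Pack a sequence into 62-bit payload words, 31 symbols each. All words
// except possibly the last are full; in the last word the symbols sit in
// the low-order bits, i.e. the word is left-padded with zero bits.
static std::vector<uint64_t> pack_words(const std::string& seq) {
  size_t n = seq.size();
  size_t nw = (n + SYMS_PER_WORD - 1) / SYMS_PER_WORD;
  std::vector<uint64_t> words(nw, 0);
  for (size_t w = 0; w < nw; ++w) {
    size_t cnt = std::min<size_t>(SYMS_PER_WORD, n - w * SYMS_PER_WORD);
    uint64_t v = 0;
    for (size_t j = 0; j < cnt; ++j) {
      int c = base_code(seq[w * SYMS_PER_WORD + j]);
      if (c < 0)
        stop("invalid symbol '%c' (only A/C/G/T can be 2-bit packed)",
             seq[w * SYMS_PER_WORD + j]);
      v = (v << 2) | (uint64_t)c;
    }
    words[w] = v;
  }
  return words;
}

// [[Rcpp::export]]
List cpp_pack(std::string seq) {
  if (seq.empty()) stop("cannot pack an empty sequence");
  std::vector<uint64_t> words = pack_words(seq);
  CharacterVector hx(words.size());
  for (size_t i = 0; i < words.size(); ++i) hx[i] = hex16(words[i]);
  return List::create(_["words"] = hx, _["length"] = (int)seq.size());
}

// [[Rcpp::export]]
std::string cpp_unpack(CharacterVector words, int length) {
  if (length < 1) stop("corrupt packed sequence: non-positive length");
  size_t nw_expect = ((size_t)length + SYMS_PER_WORD - 1) / SYMS_PER_WORD;
  if ((size_t)words.size() != nw_expect)
    stop("corrupt packed sequence: %d words for length %d (expected %d)",
         (int)words.size(), length, (int)nw_expect);
  std::string out;
  out.reserve(length);
  for (int w = 0; w < words.size(); ++w) {
    size_t cnt = std::min<size_t>(SYMS_PER_WORD,
                                  (size_t)length - (size_t)w * SYMS_PER_WORD);
    uint64_t v = parse_hex(as<std::string>(words[w]));
    if (v >> (2 * cnt))
      stop("corrupt packed sequence: non-zero padding bits in word %d", w + 1);
    for (size_t j = 0; j < cnt; ++j)
      out.push_back(code_base((int)((v >> (2 * (cnt - 1 - j))) & 3)));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_encode_symbol(CharacterVector base) {
  IntegerVector out(base.size());
  for (int i = 0; i < base.size(); ++i) {
    std::string b = as<std::string>(base[i]);
    int c = (b.size() == 1) ? base_code(b[0]) : -1;
    if (c < 0) stop("invalid symbol '%s': expected one of A, C, G, T", b.c_str());
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seq) {
  CharacterVector out(seq.size());
  for (int i = 0; i < seq.size(); ++i) {
    std::string s = as<std::string>(seq[i]);
    for (char c : s)
      if (base_code(c) < 0) stop("invalid symbol '%c' in sequence", c);
    out[i] = revcomp(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector seq) {
  CharacterVector out(seq.size());
  for (int i = 0; i < seq.size(); ++i) {
    std::string s = as<std::string>(seq[i]);
    for (char c : s)
      if (base_code(c) < 0) stop("invalid symbol '%c' in sequence", c);
    std::string r = revcomp(s);
    out[i] = (r < s) ? r : s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Signatures: canonical m-mers that do not start with AAA or ACA and do not
// contain AA anywhere except at the very beginning.
// ---------------------------------------------------------------------------

static bool mmer_allowed(const std::string& s) {
  size_t n = s.size();
  if (n >= 3) {
    if (s[0] == 'A' && s[1] == 'A' && s[2] == 'A') return false;
    if (s[0] == 'A' && s[1] == 'C' && s[2] == 'A') return false;
  }
  for (size_t i = 1; i + 1 < n; ++i)
    if (s[i] == 'A' && s[i + 1] == 'A') return false;
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_is_allowed(CharacterVector mmers) {
  LogicalVector out(mmers.size());
  for (int i = 0; i < mmers.size(); ++i) {
    std::string s = as<std::string>(mmers[i]);
    if (s.size() < 3) stop("m-mer must have length >= 3, got %d", (int)s.size());
    for (char c : s)
      if (base_code(c) < 0) stop("invalid symbol '%c' in m-mer", c);
    out[i] = mmer_allowed(s);
  }
  return out;
}

// Signature rank: allowed m-mers beat disallowed ones; within a class,
// lexicographically smaller canonical form wins.
struct MmerRank {
  bool bad;
  std::string canon;
};

static inline bool rank_less(const MmerRank& a, const MmerRank& b) {
  if (a.bad != b.bad) return b.bad;
  return a.canon < b.canon;
}

static std::vector<MmerRank> window_ranks(const std::string& frag, int m) {
  size_t np = frag.size() - m + 1;
  std::vector<MmerRank> r(np);
  for (size_t i = 0; i < np; ++i) {
    std::string mm = frag.substr(i, m);
    std::string rc = revcomp(mm);
    std::string canon = (rc < mm) ? rc : mm;
    r[i].canon = canon;
    r[i].bad = !mmer_allowed(canon);
  }
  return r;
}

// [[Rcpp::export]]
List cpp_signature_of(std::string kmer, int m) {
  int k = (int)kmer.size();
  if (m < 3 || m > k) stop("m must satisfy 3 <= m <= k (m=%d, k=%d)", m, k);
  for (char c : kmer)
    if (base_code(c) < 0) stop("invalid symbol '%c' in k-mer", c);
  std::vector<MmerRank> r = window_ranks(kmer, m);
  size_t best = 0;
  for (size_t i = 1; i < r.size(); ++i)
    if (rank_less(r[i], r[best])) best = i;
  return List::create(_["mmer"] = r[best].canon, _["allowed"] = !r[best].bad);
}

// [[Rcpp::export]]
CharacterVector cpp_clean_fragments(std::string seq) {
  std::vector<std::string> frags;
  std::string cur;
  for (char c : seq) {
    char u = (c >= 'a' && c <= 'z') ? (char)(c - 'a' + 'A') : c;
    if (base_code(u) >= 0) {
      cur.push_back(u);
    } else if (!cur.empty()) {
      frags.push_back(cur);
      cur.clear();
    }
  }
  if (!cur.empty()) frags.push_back(cur);
  return wrap(frags);
}

// Split each fragment into superkmers: maximal runs of consecutive k-mers
// sharing one signature. Signatures are sliding-window minima of the
// per-position m-mer ranks, maintained with a monotone deque in O(n).
// [[Rcpp::export]]
DataFrame cpp_split_superkmers(CharacterVector fragments, int k, int m) {
  if (k < 1) stop("k must be positive");
  if (m < 3 || m > k) stop("m must satisfy 3 <= m <= k (m=%d, k=%d)", m, k);
  std::vector<std::string> seqs, sigs;
  std::vector<int> nk, frag_id;
  std::vector<int> allowed;
  for (int f = 0; f < fragments.size(); ++f) {
    std::string frag = as<std::string>(fragments[f]);
    int n = (int)frag.size();
    if (n < k) continue;  // too short to carry any k-mer
    for (char c : frag)
      if (base_code(c) < 0)
        stop("invalid symbol '%c' in fragment (clean first)", c);
    std::vector<MmerRank> r = window_ranks(frag, m);
    int nwin = n - k + 1;
    int span = k - m;  // last m-mer offset inside a k-mer window
    std::deque<int> dq;
    std::vector<int> winner(nwin);
    for (int j = 0; j <= span; ++j) {
      while (!dq.empty() && rank_less(r[j], r[dq.back()])) dq.pop_back();
      dq.push_back(j);
    }
    winner[0] = dq.front();
    for (int i = 1; i < nwin; ++i) {
      int j = i + span;
      while (!dq.empty() && rank_less(r[j], r[dq.back()])) dq.pop_back();
      dq.push_back(j);
      while (dq.front() < i) dq.pop_front();
      winner[i] = dq.front();
    }
    int run_start = 0;
    for (int i = 1; i <= nwin; ++i) {
      bool brk = (i == nwin) ||
                 r[winner[i]].canon != r[winner[run_start]].canon;
      if (brk) {
        int a = run_start, b = i - 1;
        seqs.push_back(frag.substr(a, b - a + k));
        sigs.push_back(r[winner[a]].canon);
        allowed.push_back(!r[winner[a]].bad);
        nk.push_back(b - a + 1);
        frag_id.push_back(f + 1);
        run_start = i;
      }
    }
  }
  return DataFrame::create(_["seq"] = seqs, _["signature"] = sigs,
                           _["allowed"] = allowed, _["n_kmers"] = nk,
                           _["fragment"] = frag_id,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Shift-based 64-bit integer hash (xorshift-multiply finalizer).
// ---------------------------------------------------------------------------

static inline uint64_t mix64(uint64_t z) {
  z ^= z >> 30;
  z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27;
  z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return z;
}

// [[Rcpp::export]]
CharacterVector cpp_mix64_hex(CharacterVector xhex) {
  CharacterVector out(xhex.size());
  for (int i = 0; i < xhex.size(); ++i)
    out[i] = hex16(mix64(parse_hex(as<std::string>(xhex[i]))));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mix64_mod(NumericVector x, int mod) {
  if (mod < 1) stop("mod must be >= 1");
  IntegerVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = (int)(mix64((uint64_t)x[i]) % (uint64_t)mod);
  return out;
}

// Packed integer value of an m-mer (single word, m <= 31).
static uint64_t mmer_value(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) {
    int code = base_code(c);
    if (code < 0) stop("invalid symbol '%c' in signature", c);
    v = (v << 2) | (uint64_t)code;
  }
  return v;
}

// [[Rcpp::export]]
IntegerVector cpp_sig_bin(CharacterVector sigs, int B) {
  if (B < 1) stop("number of bins B must be >= 1");
  IntegerVector out(sigs.size());
  for (int i = 0; i < sigs.size(); ++i) {
    std::string s = as<std::string>(sigs[i]);
    if (s.size() > 31) stop("signature longer than 31 symbols");
    out[i] = (int)(mix64(mmer_value(s)) % (uint64_t)B);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_int_bin(IntegerVector ids, int B) {
  if (B < 1) stop("number of bins B must be >= 1");
  IntegerVector out(ids.size());
  for (int i = 0; i < ids.size(); ++i)
    out[i] = (int)(mix64((uint64_t)ids[i]) % (uint64_t)B);
  return out;
}

// ---------------------------------------------------------------------------
// Counting: slide a k-window over each sequence, canonicalize on request,
// aggregate in a hash table keyed by the packed k-mer.
// ---------------------------------------------------------------------------

struct PackedKeyHash {
  size_t operator()(const std::vector<uint64_t>& v) const {
    uint64_t h = 0x9E3779B97F4A7C15ULL ^ (uint64_t)v.size();
    for (uint64_t w : v) h = mix64(h ^ w);
    return (size_t)h;
  }
};

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  if (k < 1) stop("k must be positive");
  std::unordered_map<std::vector<uint64_t>, double, PackedKeyHash> tab;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = (int)s.size();
    if (n < k) continue;
    for (char c : s)
      if (base_code(c) < 0)
        stop("invalid symbol '%c' in sequence (clean first)", c);
    for (int j = 0; j + k <= n; ++j) {
      std::string km = s.substr(j, k);
      if (canonical) {
        std::string rc = revcomp(km);
        if (rc < km) km = rc;
      }
      tab[pack_words(km)] += 1.0;
    }
  }
  CharacterVector kmers(tab.size());
  NumericVector counts(tab.size());
  int i = 0;
  for (auto& kv : tab) {
    std::string dec;
    dec.reserve(k);
    size_t nw = kv.first.size();
    for (size_t w = 0; w < nw; ++w) {
      size_t cnt = std::min<size_t>(SYMS_PER_WORD, (size_t)k - w * SYMS_PER_WORD);
      for (size_t j = 0; j < cnt; ++j)
        dec.push_back(code_base((int)((kv.first[w] >> (2 * (cnt - 1 - j))) & 3)));
    }
    kmers[i] = dec;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// ---------------------------------------------------------------------------
// Exact multiprocessor-scheduling optimum by pruned exhaustive search.
// Oracle for the LPT heuristic on small instances only.
// ---------------------------------------------------------------------------

static void mps_rec(const std::vector<double>& s, size_t idx, int t,
                    std::vector<double>& load, double cur_max, double& best) {
  if (cur_max >= best) return;
  if (idx == s.size()) {
    best = cur_max;
    return;
  }
  for (int j = 0; j < t; ++j) {
    if (j > 0 && load[j] == load[j - 1]) continue;  // symmetric machine
    double nl = load[j] + s[idx];
    if (nl >= best) continue;
    load[j] += s[idx];
    mps_rec(s, idx + 1, t, load, std::max(cur_max, nl), best);
    load[j] -= s[idx];
  }
}

// [[Rcpp::export]]
double cpp_brute_force_opt(NumericVector sizes, int t) {
  int n = sizes.size();
  if (t < 1) stop("t must be >= 1");
  if (n > 14 || t > 4)
    stop("instance too large for exhaustive search (need n <= 14, t <= 4)");
  if (n == 0) return 0.0;
  std::vector<double> s(sizes.begin(), sizes.end());
  for (double v : s)
    if (v < 0) stop("job sizes must be non-negative");
  std::sort(s.rbegin(), s.rend());
  std::vector<double> load(t, 0.0);
  double total = 0.0;
  for (double v : s) total += v;
  double best = total + 1.0;
  mps_rec(s, 0, t, load, 0.0, best);
  return best;
}
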