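#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Fixed, documented hash seed for MinHash sketching. Bit-compatibility with
// external sketching tools is not a goal; the estimator contract is.
static const uint64_t HASH_SEED = 0x9E3779B97F4A7C15ULL;
// Hash values are truncated to 53 bits so they round-trip exactly through
// R numerics (doubles).
static const uint64_t MASK53 = (1ULL << 53) - 1;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// All canonical k-mer hash values of a sequence; windows containing a
// non-ACGT letter are skipped. Canonical = min(k-mer, reverse complement)
// on the 2-bit encoding.
static std::vector<uint64_t> canonical_hashes(const std::string& seq, int k) {
  std::vector<uint64_t> out;
  const int n = static_cast<int>(seq.size());
  if (n < k || k < 1 || k > 31) return out;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  out.reserve(n - k + 1);
  for (int i = 0; i < n; ++i) {
    const int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & mask;
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      const uint64_t canon = std::min(fwd, rev);
      out.push_back(splitmix64(canon ^ HASH_SEED) & MASK53);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(std::string seq, int k, int s) {
  std::vector<uint64_t> h = canonical_hashes(seq, k);
  std::sort(h.begin(), h.end());
  h.erase(std::unique(h.begin(), h.end()), h.end());
  const int keep = std::min<int>(s, static_cast<int>(h.size()));
  NumericVector out(keep);
  for (int i = 0; i < keep; ++i) out[i] = static_cast<double>(h[i]);
  return out;
}

// Exact Jaccard index over the full canonical k-mer sets of two sequences.
// [[Rcpp::export]]
double kmer_jaccard_cpp(std::string a, std::string b, int k) {
  std::vector<uint64_t> ha = canonical_hashes(a, k);
  std::vector<uint64_t> hb = canonical_hashes(b, k);
  std::sort(ha.begin(), ha.end());
  ha.erase(std::unique(ha.begin(), ha.end()), ha.end());
  std::sort(hb.begin(), hb.end());
  hb.erase(std::unique(hb.begin(), hb.end()), hb.end());
  if (ha.empty() && hb.empty()) return 1.0;
  std::size_t i = 0, j = 0, inter = 0;
  while (i < ha.size() && j < hb.size()) {
    if (ha[i] == hb[j]) { ++inter; ++i; ++j; }
    else if (ha[i] < hb[j]) ++i;
    else ++j;
  }
  const std::size_t uni = ha.size() + hb.size() - inter;
  return uni == 0 ? 1.0 : static_cast<double>(inter) / static_cast<double>(uni);
}

// --- simplified fragment ANI -------------------------------------------------
// Query is cut into consecutive full fragments; each fragment is placed on the
// subject at its best ungapped offset, located by exact seed-word voting
// (seed length 12), then scored by per-site identity.

struct FragHit {
  int frag;      // fragment index in query
  double ident;  // per-site identity at best offset
  long mid;      // subject coordinate of fragment midpoint
  bool found;
};

static std::vector<FragHit> best_fragment_hits(const std::string& q,
                                               const std::string& s,
                                               int frag_len) {
  const int seed_len = 12;
  const int ns = static_cast<int>(s.size());
  const int nq = static_cast<int>(q.size());
  std::vector<FragHit> hits;
  if (ns < seed_len || nq < frag_len) return hits;

  // index of seed-word -> subject positions (capped per word)
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
    uint64_t w = 0;
    int valid = 0;
    for (int i = 0; i < ns; ++i) {
      const int c = base_code(s[i]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | static_cast<uint64_t>(c)) & mask;
      if (++valid >= seed_len) {
        std::vector<int>& v = index[w];
        if (v.size() < 64) v.push_back(i - seed_len + 1);
      }
    }
  }

  const int n_frag = nq / frag_len;
  for (int f = 0; f < n_frag; ++f) {
    const int p0 = f * frag_len;
    // vote for subject offsets (subject start of this fragment)
    std::unordered_map<long, int> votes;
    {
      const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
      uint64_t w = 0;
      int valid = 0;
      for (int i = p0; i < p0 + frag_len; ++i) {
        const int c = base_code(q[i]);
        if (c < 0) { valid = 0; w = 0; continue; }
        w = ((w << 2) | static_cast<uint64_t>(c)) & mask;
        if (++valid >= seed_len) {
          auto it = index.find(w);
          if (it == index.end()) continue;
          const int qpos = i - seed_len + 1;
          for (int spos : it->second) {
            const long off = static_cast<long>(spos) - (qpos - p0);
            votes[off] += 1;
          }
        }
      }
    }
    // evaluate the top-voted offsets
    std::vector<std::pair<int, long>> ranked;
    ranked.reserve(votes.size());
    for (auto& kv : votes) ranked.push_back({kv.second, kv.first});
    std::sort(ranked.begin(), ranked.end(),
              [](const std::pair<int, long>& a, const std::pair<int, long>& b) {
                return a.first > b.first || (a.first == b.first && a.second < b.second);
              });
    FragHit best{f, 0.0, 0, false};
    const int n_eval = std::min<std::size_t>(5, ranked.size());
    for (int r = 0; r < n_eval; ++r) {
      const long off = ranked[r].second;
      if (off < 0 || off + frag_len > ns) continue;
      int match = 0;
      for (int i = 0; i < frag_len; ++i) {
        const int cq = base_code(q[p0 + i]);
        const int cs = base_code(s[off + i]);
        if (cq >= 0 && cq == cs) ++match;
      }
      const double ident = static_cast<double>(match) / frag_len;
      if (!best.found || ident > best.ident) {
        best.ident = ident;
        best.mid = off + frag_len / 2;
        best.found = true;
      }
    }
    hits.push_back(best);
  }
  return hits;
}

// Reciprocal-best fragment ANI between two sequences. Returns the mean
// identity over reciprocal best fragment pairs with identity >= min_identity,
// or NA when no pair qualifies.
// [[Rcpp::export]]
List fragment_ani_cpp(std::string a, std::string b, int frag_len,
                      double min_identity) {
  std::vector<FragHit> ab = best_fragment_hits(a, b, frag_len);
  std::vector<FragHit> ba = best_fragment_hits(b, a, frag_len);
  const int nb_frag = static_cast<int>(b.size()) / frag_len;
  const int na_frag = static_cast<int>(a.size()) / frag_len;

  // map each b-fragment to the a-fragment its best hit midpoint falls in
  std::vector<int> b_to_a(nb_frag, -1);
  for (const FragHit& h : ba) {
    if (h.found) {
      const int af = static_cast<int>(h.mid) / frag_len;
      if (af >= 0 && af < na_frag) b_to_a[h.frag] = af;
    }
  }

  double sum = 0.0;
  int n_pairs = 0;
  for (const FragHit& h : ab) {
    if (!h.found || h.ident < min_identity) continue;
    const int bf = static_cast<int>(h.mid) / frag_len;
    if (bf < 0 || bf >= nb_frag) continue;
    if (b_to_a[bf] != h.frag) continue;  // not reciprocal
    // average the two directions' identities for this reciprocal pair
    double pair_ident = h.ident;
    for (const FragHit& g : ba) {
      if (g.frag == bf && g.found) { pair_ident = (h.ident + g.ident) / 2.0; break; }
    }
    if (pair_ident < min_identity) continue;
    sum += pair_ident;
    ++n_pairs;
  }
  if (n_pairs == 0)
    return List::create(_["ani"] = NA_REAL, _["n_pairs"] = 0);
  return List::create(_["ani"] = sum / n_pairs, _["n_pairs"] = n_pairs);
}
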