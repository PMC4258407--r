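#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; 4 = N/other (never matches, never seeded)
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

// reverse complement in code space (N stays N)
static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : 4;
  }
  return r;
}

// mismatches of read codes vs ref codes at start, early exit beyond limit
static inline int count_mm(const std::vector<uint8_t>& ref, const std::vector<uint8_t>& rd,
                           int start, int limit) {
  int mm = 0;
  const int L = (int) rd.size();
  for (int i = 0; i < L; ++i) {
    uint8_t a = ref[start + i], b = rd[i];
    if (a != b || a > 3) {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

struct Hit {
  int ref, pos, strand, mm;
};

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
        case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
        case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
        case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
        default: r[j] = c;
      }
    }
    out[i] = r;
  }
  return out;
}

// Ungapped end-to-end mapping of reads against a set of references.
// Seed-and-verify with a k-mer positional index at seed length `k_use`;
// reads too short for the pigeonhole sensitivity guarantee (or containing N)
// are scanned exhaustively, so all placements with <= max_mm mismatches are
// always reported. Hits sorted by (mm, ref_rank, pos, strand) per read and
// truncated at max_hits (uniqueness statistics computed before truncation).
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                   int k_use, int max_mm, int max_hits, IntegerVector ref_rank) {
  const int n_ref = ref_seqs.size();
  const int n_read = read_seqs.size();

  std::vector<std::vector<uint8_t> > refs(n_ref);
  for (int r = 0; r < n_ref; ++r) refs[r] = encode(as<std::string>(ref_seqs[r]));

  // global k-mer index over forward strands of all references
  const uint64_t mask = (k_use >= 32) ? ~0ULL : ((1ULL << (2 * k_use)) - 1);
  std::unordered_map<uint64_t, std::vector<int64_t> > index;
  index.reserve(1 << 20);
  for (int r = 0; r < n_ref; ++r) {
    const std::vector<uint8_t>& rc = refs[r];
    const int n = (int) rc.size();
    uint64_t key = 0;
    int run = 0; // valid (non-N) bases accumulated
    for (int i = 0; i < n; ++i) {
      if (rc[i] > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | rc[i]) & mask;
      if (++run >= k_use) {
        int pos = i - k_use + 1;
        index[key].push_back(((int64_t) r << 32) | (uint32_t) pos);
      }
    }
  }

  const int guarantee_len = (max_mm + 1) * k_use + max_mm;

  std::vector<int> o_read, o_ref, o_pos, o_strand, o_mm;
  IntegerVector n_hits(n_read), n_total(n_read), best_mm(n_read), n_best(n_read);
  LogicalVector truncated(n_read);

  std::vector<Hit> hits;
  std::vector<int64_t> cands;

  for (int q = 0; q < n_read; ++q) {
    std::string rs = as<std::string>(read_seqs[q]);
    std::vector<uint8_t> fwd = encode(rs);
    std::vector<uint8_t> rev = revcomp_codes(fwd);
    const int L = (int) fwd.size();
    bool has_n = false;
    for (int i = 0; i < L; ++i) if (fwd[i] > 3) { has_n = true; break; }

    hits.clear();
    bool seeded = (!has_n) && (L >= guarantee_len) && (L >= k_use);

    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t>& rd = (strand == 0) ? fwd : rev;
      if (seeded) {
        cands.clear();
        uint64_t key = 0;
        for (int i = 0; i < L; ++i) {
          key = ((key << 2) | rd[i]) & mask;
          if (i >= k_use - 1) {
            int off = i - k_use + 1;
            std::unordered_map<uint64_t, std::vector<int64_t> >::const_iterator it =
              index.find(key);
            if (it != index.end()) {
              for (size_t j = 0; j < it->second.size(); ++j) {
                int64_t packed = it->second[j];
                int r = (int)(packed >> 32);
                int p = (int)(packed & 0xffffffffLL);
                int start = p - off;
                if (start >= 0 && start + L <= (int) refs[r].size())
                  cands.push_back(((int64_t) r << 32) | (uint32_t) start);
              }
            }
          }
        }
        std::sort(cands.begin(), cands.end());
        cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
        for (size_t c = 0; c < cands.size(); ++c) {
          int r = (int)(cands[c] >> 32);
          int start = (int)(cands[c] & 0xffffffffLL);
          int mm = count_mm(refs[r], rd, start, max_mm);
          if (mm <= max_mm) { Hit h = {r, start, strand, mm}; hits.push_back(h); }
        }
      } else {
        for (int r = 0; r < n_ref; ++r) {
          const int n = (int) refs[r].size();
          for (int start = 0; start + L <= n; ++start) {
            int mm = count_mm(refs[r], rd, start, max_mm);
            if (mm <= max_mm) { Hit h = {r, start, strand, mm}; hits.push_back(h); }
          }
        }
      }
    }

    struct Cmp {
      const IntegerVector& rank;
      Cmp(const IntegerVector& rk) : rank(rk) {}
      bool operator()(const Hit& a, const Hit& b) const {
        if (a.mm != b.mm) return a.mm < b.mm;
        if (rank[a.ref] != rank[b.ref]) return rank[a.ref] < rank[b.ref];
        if (a.pos != b.pos) return a.pos < b.pos;
        return a.strand < b.strand;
      }
    };
    std::sort(hits.begin(), hits.end(), Cmp(ref_rank));

    int tot = (int) hits.size();
    n_total[q] = tot;
    if (tot == 0) {
      best_mm[q] = NA_INTEGER; n_best[q] = 0; n_hits[q] = 0; truncated[q] = false;
      continue;
    }
    int bm = hits[0].mm, nb = 0;
    for (int i = 0; i < tot; ++i) if (hits[i].mm == bm) ++nb;
    best_mm[q] = bm; n_best[q] = nb;
    int keep = std::min(tot, max_hits);
    truncated[q] = tot > max_hits;
    n_hits[q] = keep;
    for (int i = 0; i < keep; ++i) {
      o_read.push_back(q + 1);
      o_ref.push_back(hits[i].ref + 1);
      o_pos.push_back(hits[i].pos);
      o_strand.push_back(hits[i].strand);
      o_mm.push_back(hits[i].mm);
    }
  }

  return List::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref), _["pos"] = wrap(o_pos),
    _["strand"] = wrap(o_strand), _["mm"] = wrap(o_mm),
    _["n_hits"] = n_hits, _["n_total"] = n_total, _["best_mm"] = best_mm,
    _["n_best"] = n_best, _["truncated"] = truncated);
}

// Per-base pileup counts over one reference from ungapped placements.
// Returns a 4 x ref_len matrix of A,C,G,T counts; N bases are ignored.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_len, CharacterVector bases, IntegerVector starts,
                         LogicalVector rev) {
  IntegerMatrix counts(4, ref_len);
  const int n = bases.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(bases[i]);
    std::vector<uint8_t> v = encode(s);
    if (rev[i]) v = revcomp_codes(v);
    int start = starts[i];
    for (size_t j = 0; j < v.size(); ++j) {
      if (v[j] < 4) {
        int p = start + (int) j;
        if (p >= 0 && p < ref_len) counts(v[j], p) += 1;
      }
    }
  }
  return counts;
}

// depth accumulation: +1 over [start, start+len) per interval
// [[Rcpp::export]]
IntegerVector cpp_depth(int ref_len, IntegerVector starts, IntegerVector lens) {
  std::vector<int> delta(ref_len + 1, 0);
  const int n = starts.size();
  for (int i = 0; i < n; ++i) {
    int s = starts[i], e = starts[i] + lens[i];
    if (s < 0) s = 0;
    if (e > ref_len) e = ref_len;
    if (s < e) { delta[s] += 1; delta[e] -= 1; }
  }
  IntegerVector out(ref_len);
  int acc = 0;
  for (int i = 0; i < ref_len; ++i) { acc += delta[i]; out[i] = acc; }
  return out;
}
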