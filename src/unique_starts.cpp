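// Extended-uniqueome computation.
//
// A genome-contig forward start s is "unique" iff no other occurrence
// location (contig, start, strand) -- over all contigs including decoys,
// both strands, excluding only the identical '+' self-placement -- carries
// an L-mer within Hamming distance m of the L-mer at s.  Windows containing
// a non-ACGT base are never occurrences (they are never unique and never
// disqualify a neighbour), matching exact-matching semantics where N never
// matches.
//
// Algorithm: pigeonhole seed partition.  Two L-mers within m mismatches
// must agree exactly on at least one of m+1 disjoint seeds, so hashing all
// occurrences by each seed and verifying Hamming distance within buckets
// finds every disqualifying pair.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct Occ {
  int seq;      // contig index
  int pos;      // 0-based offset into the oriented string
  bool minus;   // true if the occurrence lives on the reverse strand
};

// [[Rcpp::export]]
List cpp_unique_starts(CharacterVector seqs, LogicalVector isDecoy,
                       int L, int m) {
  const int nseq = seqs.size();
  if (m < 0 || m >= L) stop("need 0 <= m < L");

  std::vector<std::string> fwd(nseq), rev(nseq);
  for (int i = 0; i < nseq; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    std::string r(fwd[i].rbegin(), fwd[i].rend());
    for (size_t j = 0; j < r.size(); ++j) r[j] = complement_base(r[j]);
    rev[i] = r;
  }

  // enumerate N-free windows on both orientations of every contig
  std::vector<Occ> occ;
  for (int i = 0; i < nseq; ++i) {
    const int len = (int) fwd[i].size();
    if (len < L) continue;
    for (int o = 0; o < 2; ++o) {
      const std::string &s = o ? rev[i] : fwd[i];
      // nextBad[p] = smallest q >= p with a non-ACGT base (or len)
      std::vector<int> nextBad(len + 1, len + L);
      int nb = len + L;
      for (int p = len - 1; p >= 0; --p) {
        char c = s[p];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') nb = p;
        nextBad[p] = nb;
      }
      for (int p = 0; p + L <= len; ++p)
        if (nextBad[p] >= p + L)
          occ.push_back(Occ{i, p, o == 1});
    }
  }
  const int nocc = (int) occ.size();

  // candidates: genome-contig forward windows, initially assumed unique
  std::vector<char> uniq(nocc, 0);
  for (int q = 0; q < nocc; ++q)
    if (!occ[q].minus && !isDecoy[occ[q].seq]) uniq[q] = 1;

  const int k = m + 1;
  const int seedLen = std::max(1, L / k);

  auto windowPtr = [&](const Occ &oc) -> const char * {
    const std::string &s = oc.minus ? rev[oc.seq] : fwd[oc.seq];
    return s.data() + oc.pos;
  };
  auto hammingWithin = [&](const Occ &a, const Occ &b) -> bool {
    const char *pa = windowPtr(a), *pb = windowPtr(b);
    int d = 0;
    for (int t = 0; t < L; ++t)
      if (pa[t] != pb[t] && ++d > m) return false;
    return true;
  };

  for (int j = 0; j < k; ++j) {
    const int off = j * seedLen;
    if (off + seedLen > L) break;
    std::unordered_map<std::string, std::vector<int> > buckets;
    buckets.reserve((size_t) nocc * 2);
    for (int q = 0; q < nocc; ++q)
      buckets[std::string(windowPtr(occ[q]) + off, seedLen)].push_back(q);
    for (std::unordered_map<std::string, std::vector<int> >::iterator it =
           buckets.begin(); it != buckets.end(); ++it) {
      std::vector<int> &v = it->second;
      const int B = (int) v.size();
      if (B < 2) continue;
      for (int a = 0; a < B; ++a) {
        for (int b = a + 1; b < B; ++b) {
          const int qa = v[a], qb = v[b];
          if (!uniq[qa] && !uniq[qb]) continue;   // outcome already settled
          if (hammingWithin(occ[qa], occ[qb])) {
            uniq[qa] = 0;
            uniq[qb] = 0;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // collect surviving genome forward starts, 1-based
  std::vector<std::vector<int> > res(nseq);
  for (int q = 0; q < nocc; ++q)
    if (uniq[q]) res[occ[q].seq].push_back(occ[q].pos + 1);
  List out(nseq);
  for (int i = 0; i < nseq; ++i) {
    std::sort(res[i].begin(), res[i].end());
    out[i] = wrap(res[i]);
  }
  return out;
}
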