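#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>

// Canonical k-mer set of a DNA sequence, 2-bit packed (k <= 31).
// A k-mer and its reverse complement hash to the same value (the smaller of
// the two encodings), so strandedness of the input cannot change the set.
// K-mers spanning a non-ACGT character are skipped.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector canonical_kmer_set(const std::string& seq, int k) {
  if (k < 1 || k > 31) Rcpp::stop("k must be in [1, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  std::unordered_set<uint64_t> kmers;
  uint64_t fwd = 0, rc = 0;
  int filled = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { filled = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++filled >= k) kmers.insert(fwd < rc ? fwd : rc);
  }
  // 2k <= 62 bits does not fit a double exactly beyond 2^53, so only k <= 26
  // round-trips through numeric; cap enforced in R (default k = 21 is safe).
  if (k > 26) Rcpp::stop("k must be <= 26 to return exact numeric hashes");
  Rcpp::NumericVector out(kmers.size());
  size_t j = 0;
  for (uint64_t v : kmers) out[j++] = (double)v;
  return out;
}

// Sizes of the intersection and union of two canonical k-mer sets.
// [[Rcpp::export]]
Rcpp::NumericVector kmer_set_overlap(const Rcpp::NumericVector& a,
                                     const Rcpp::NumericVector& b) {
  std::unordered_set<uint64_t> sa;
  sa.reserve(a.size() * 2);
  for (double v : a) sa.insert((uint64_t)v);
  double inter = 0;
  std::unordered_set<uint64_t> sb;
  sb.reserve(b.size() * 2);
  for (double v : b) {
    uint64_t u = (uint64_t)v;
    if (sb.insert(u).second && sa.count(u)) inter += 1;
  }
  double uni = (double)sa.size() + (double)sb.size() - inter;
  return Rcpp::NumericVector::create(inter, uni);
}
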