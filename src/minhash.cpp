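// Bottom-s MinHash sketching of canonical k-mers.
//
// k-mers are 2-bit encoded with a rolling window; the canonical form is the
// numeric minimum of the forward and reverse-complement codes. Codes are
// finalized with the splitmix64 mixer (fixed seed) and the s smallest
// distinct hashes are kept. Hashes are right-shifted to 53 bits so they are
// exactly representable as R doubles.

#include <Rcpp.h>
#include <set>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".minhash_hashes")]]
NumericVector minhash_hashes(std::string seq, int k, int s) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  if (s < 1) stop("sketch size must be positive");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  std::set<uint64_t> sketch;  // ascending; keep the s smallest distinct
  for (size_t i = 0; i < seq.size(); ++i) {
    int b;
    switch (seq[i]) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': case 'U': case 'u': b = 3; break;
      default: b = -1;
    }
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++valid < k) continue;
    uint64_t canon = fwd < rev ? fwd : rev;
    uint64_t h = splitmix64(canon) >> 11;  // 53 bits, exact in a double
    if ((int)sketch.size() < s) {
      sketch.insert(h);
    } else if (h < *sketch.rbegin()) {
      sketch.insert(h);
      if ((int)sketch.size() > s) sketch.erase(std::prev(sketch.end()));
    }
  }
  NumericVector out(sketch.size());
  int j = 0;
  for (std::set<uint64_t>::iterator it = sketch.begin(); it != sketch.end(); ++it)
    out[j++] = (double)*it;
  return out;
}
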