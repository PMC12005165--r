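// Canonical k-mer sketching.
//
// Each window of length k containing only A/C/G/T is canonicalized to
// the lexicographic minimum of the k-mer and its reverse complement,
// then hashed with 64-bit FNV-1a (fixed constants, so sketches are
// reproducible across runs and platforms). The top 53 bits of the hash
// are used as the sketch value so it is exactly representable as an R
// double; with a `scaled` factor s only hashes below 2^53 / s are
// retained (s = 1 keeps everything).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static const uint64_t FNV_OFFSET = 1469598103934665603ULL;
static const uint64_t FNV_PRIME = 1099511628211ULL;

// [[Rcpp::export(name = ".sketch_cpp")]]
Rcpp::List sketch_cpp(std::string seq, int k, double scaled) {
  const size_t n = seq.size();
  for (size_t i = 0; i < n; ++i) seq[i] = std::toupper(seq[i]);

  const double max_hash = 9007199254740992.0;  // 2^53
  const double threshold = max_hash / scaled;

  std::unordered_map<uint64_t, int> counts;
  if (k > 0 && (size_t)k <= n) {
    // next_invalid[i] would be overkill; track the most recent invalid
    // position and skip windows containing it.
    long long last_bad = -1;
    for (size_t i = 0; i < n; ++i) {
      if (!valid_base(seq[i])) last_bad = (long long)i;
      if (i + 1 < (size_t)k) continue;
      size_t start = i + 1 - (size_t)k;
      if (last_bad >= (long long)start) continue;

      // canonical orientation: compare forward vs reverse complement
      bool use_fwd = true;
      for (int j = 0; j < k; ++j) {
        char f = seq[start + j];
        char r = comp(seq[start + k - 1 - j]);
        if (f != r) { use_fwd = f < r; break; }
      }

      uint64_t h = FNV_OFFSET;
      if (use_fwd) {
        for (int j = 0; j < k; ++j) {
          h ^= (uint64_t)(unsigned char)seq[start + j];
          h *= FNV_PRIME;
        }
      } else {
        for (int j = 0; j < k; ++j) {
          h ^= (uint64_t)(unsigned char)comp(seq[start + k - 1 - j]);
          h *= FNV_PRIME;
        }
      }
      uint64_t h53 = h >> 11;
      if ((double)h53 < threshold) counts[h53] += 1;
    }
  }

  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  Rcpp::NumericVector hash(keys.size());
  Rcpp::IntegerVector count(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    hash[i] = (double)keys[i];
    count[i] = counts[keys[i]];
  }
  return Rcpp::List::create(Rcpp::Named("hash") = hash,
                            Rcpp::Named("count") = count);
}
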