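#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp(c);
  return out;
}

// Ungapped all-hit scan of each read (both orientations) against each
// reference: every offset with Hamming distance <= max_mm is reported.
// Coordinates are 1-based on the reference forward strand; a "-" hit means
// the reverse complement of the read matches there.
// [[Rcpp::export(name = ".scan_hits")]]
DataFrame scan_hits(CharacterVector reads, CharacterVector refs, int max_mm) {
  std::vector<int> q_idx, r_idx, starts, mms;
  std::vector<char> strands;
  std::vector<std::string> ref_s(refs.size());
  for (int j = 0; j < refs.size(); ++j) ref_s[j] = as<std::string>(refs[j]);

  for (int i = 0; i < reads.size(); ++i) {
    const std::string fwd = as<std::string>(reads[i]);
    const std::string rev = revcomp_str(fwd);
    const int L = (int) fwd.size();
    for (int j = 0; j < (int) ref_s.size(); ++j) {
      const std::string& R = ref_s[j];
      const int M = (int) R.size();
      if (M < L) continue;
      for (int s = 0; s < 2; ++s) {
        const std::string& q = (s == 0) ? fwd : rev;
        const char* qc = q.c_str();
        const char* rc = R.c_str();
        for (int off = 0; off + L <= M; ++off) {
          int mm = 0;
          const char* rp = rc + off;
          for (int k = 0; k < L; ++k) {
            if (qc[k] != rp[k] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) {
            q_idx.push_back(i + 1);
            r_idx.push_back(j + 1);
            starts.push_back(off + 1);
            strands.push_back(s == 0 ? '+' : '-');
            mms.push_back(mm);
          }
        }
      }
    }
  }
  CharacterVector strand_out(strands.size());
  for (size_t k = 0; k < strands.size(); ++k)
    strand_out[k] = std::string(1, strands[k]);
  return DataFrame::create(_["query"] = wrap(q_idx),
                           _["ref"] = wrap(r_idx),
                           _["start"] = wrap(starts),
                           _["strand"] = strand_out,
                           _["mismatches"] = wrap(mms),
                           _["stringsAsFactors"] = false);
}
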