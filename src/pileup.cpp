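#include <Rcpp.h>
#include <map>
#include <string>
#include <tuple>

using namespace Rcpp;

// Decode aligned reads into per-position allele observations.
// Allele keys: single bases for M columns, "+SEQ" for an insertion anchored
// at the reference base preceding it, "-SEQ" for a deletion anchored at the
// reference base preceding the deleted run (SEQ = deleted reference bases).
// Observation qualities: base quality for M, mean inserted-base quality for
// insertions, anchor-base quality for deletions.

struct Obs { int fwd = 0, rev = 0; double qualsum = 0.0; };

// [[Rcpp::export]]
DataFrame pileup_cpp(IntegerVector contig_idx, IntegerVector pos0,
                     LogicalVector is_rev, CharacterVector seq,
                     CharacterVector qual, CharacterVector cigar,
                     CharacterVector ref_seqs) {
  typedef std::tuple<int, int, std::string> Key;
  std::map<Key, Obs> acc;

  const int nreads = contig_idx.size();
  for (int r = 0; r < nreads; ++r) {
    const std::string s = as<std::string>(seq[r]);
    const std::string q = as<std::string>(qual[r]);
    const std::string cg = as<std::string>(cigar[r]);
    const int ci = contig_idx[r] - 1;
    const std::string& ref = as<std::string>(ref_seqs[ci]);
    const bool rev = is_rev[r];

    int rp = pos0[r];     // reference pointer (0-based)
    size_t qp = 0;        // query pointer
    size_t ip = 0;
    const int reflen = (int) ref.size();
    bool seen_m = false;
    while (ip < cg.size()) {
      int len = 0;
      while (ip < cg.size() && isdigit(cg[ip])) {
        len = len * 10 + (cg[ip] - '0');
        ++ip;
      }
      const char op = cg[ip++];
      if (op == 'M') {
        for (int x = 0; x < len; ++x) {
          if (rp >= 0 && rp < reflen && qp < s.size()) {
            Obs& o = acc[Key(ci, rp, std::string(1, s[qp]))];
            if (rev) o.rev++; else o.fwd++;
            o.qualsum += (double) (q[qp] - 33);
          }
          ++rp; ++qp;
        }
        seen_m = true;
      } else if (op == 'I') {
        if (seen_m && rp - 1 >= 0 && rp - 1 < reflen && qp + len <= s.size()) {
          double qs = 0;
          for (int x = 0; x < len; ++x) qs += (double) (q[qp + x] - 33);
          Obs& o = acc[Key(ci, rp - 1, "+" + s.substr(qp, len))];
          if (rev) o.rev++; else o.fwd++;
          o.qualsum += qs / len;
        }
        qp += len;
      } else if (op == 'D') {
        if (seen_m && rp - 1 >= 0 && rp + len <= reflen) {
          Obs& o = acc[Key(ci, rp - 1, "-" + ref.substr(rp, len))];
          if (rev) o.rev++; else o.fwd++;
          o.qualsum += (double) (qp > 0 ? (q[qp - 1] - 33) : 30);
        }
        rp += len;
      } else if (op == 'S') {
        qp += len;
      } else if (op == 'H') {
        // consumes nothing
      } else if (op == 'N') {
        rp += len;
      } else {
        stop("pileup_cpp: unsupported CIGAR op");
      }
    }
  }

  const int nout = (int) acc.size();
  IntegerVector o_ci(nout), o_pos(nout), o_fwd(nout), o_rev(nout);
  NumericVector o_qs(nout);
  CharacterVector o_allele(nout);
  int i = 0;
  for (std::map<Key, Obs>::const_iterator it = acc.begin(); it != acc.end();
       ++it, ++i) {
    o_ci[i] = std::get<0>(it->first) + 1;
    o_pos[i] = std::get<1>(it->first);
    o_allele[i] = std::get<2>(it->first);
    o_fwd[i] = it->second.fwd;
    o_rev[i] = it->second.rev;
    o_qs[i] = it->second.qualsum;
  }
  return DataFrame::create(_["contig_idx"] = o_ci, _["pos"] = o_pos,
                           _["allele"] = o_allele, _["fwd"] = o_fwd,
                           _["rev"] = o_rev, _["qualsum"] = o_qs,
                           _["stringsAsFactors"] = false);
}
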