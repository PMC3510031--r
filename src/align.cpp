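#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// 5'-anchored assignment of reads to mature miRNA references under an
// internal / 3'-end mismatch budget.
//
// For a read of length L against a mature of length M with flank F:
//  * position p (0-based) compares to mature[p] for p < M, flank[p-M]
//    beyond the mature terminus;
//  * a mismatching position counts to the 3'-end class when it lies in the
//    read's terminal `end3_window` bases or beyond the mature terminus,
//    otherwise to the internal class;
//  * feasible iff internal <= max_internal, end3 <= max_end3 and the
//    overhang (L - M) does not exceed max_overhang;
//  * candidates are ranked by fewest total mismatches, then fewest
//    internal, then longest overlap; the catalog is expected pre-sorted by
//    name so the earliest index breaks remaining ties, and a surviving tie
//    on all three keys flags the read ambiguous.
//
// [[Rcpp::export]]
DataFrame align_seqs_cpp(CharacterVector seqs,
                         CharacterVector mature,
                         CharacterVector flank,
                         int max_internal,
                         int max_end3,
                         int end3_window,
                         int max_overhang) {
  int n = seqs.size();
  int m = mature.size();
  std::vector<std::string> mat(m), fl(m);
  for (int j = 0; j < m; ++j) {
    mat[j] = as<std::string>(mature[j]);
    fl[j] = as<std::string>(flank[j]);
  }
  IntegerVector entry(n, NA_INTEGER), internal(n, NA_INTEGER),
      end3(n, NA_INTEGER), overlap(n, NA_INTEGER), offset(n, NA_INTEGER);
  LogicalVector ambiguous(n, false);

  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(seqs[i]);
    int L = r.size();
    int bIdx = -1, bTot = 0, bInt = 0, bEnd = 0, bOv = 0;
    bool tie = false;
    for (int j = 0; j < m; ++j) {
      int M = mat[j].size();
      int off = L - M;
      if (off > max_overhang) continue;
      if (off > (int)fl[j].size()) continue;
      int ov = (L < M) ? L : M;
      int ni = 0, ne = 0;
      for (int p = 0; p < L; ++p) {
        char tpl = (p < M) ? mat[j][p] : fl[j][p - M];
        if (r[p] != tpl) {
          if (p >= L - end3_window || p >= M) ++ne; else ++ni;
        }
      }
      if (ni > max_internal || ne > max_end3) continue;
      int tot = ni + ne;
      int cmp;
      if (bIdx < 0) cmp = -1;
      else if (tot != bTot) cmp = (tot < bTot) ? -1 : 1;
      else if (ni != bInt) cmp = (ni < bInt) ? -1 : 1;
      else if (ov != bOv) cmp = (ov > bOv) ? -1 : 1;
      else cmp = 1;  // equal on all keys: earlier (smaller name) index kept
      if (cmp < 0) {
        bIdx = j; bTot = tot; bInt = ni; bEnd = ne; bOv = ov;
        tie = false;
      } else if (bIdx >= 0 && tot == bTot && ni == bInt && ov == bOv) {
        tie = true;
      }
    }
    if (bIdx >= 0) {
      entry[i] = bIdx + 1;
      internal[i] = bInt;
      end3[i] = bEnd;
      overlap[i] = bOv;
      offset[i] = L - (int)mat[bIdx].size();
      ambiguous[i] = tie;
    }
  }
  return DataFrame::create(
      _["entry"] = entry, _["internal_mismatches"] = internal,
      _["end3_mismatches"] = end3, _["overlap_len"] = overlap,
      _["terminal_read_offset"] = offset, _["ambiguous"] = ambiguous,
      _["stringsAsFactors"] = false);
}
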