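#include <Rcpp.h>
using namespace Rcpp;

// A base pair "matches" only when both characters are equal and one of
// A/C/G/T: N (or any ambiguity code) never matches, even against itself.
static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

// Enumerate every ungapped placement of `query` on every subject with
// Hamming distance <= v.  Early exit as soon as a window exceeds v
// mismatches.  Returns parallel vectors (subject index 1-based, start
// 0-based, mismatch count).
// [[Rcpp::export]]
List cpp_scan_hits(CharacterVector subjects, std::string query, int v) {
  std::vector<int> sidx, start, mm;
  const int qlen = (int) query.size();
  for (int s = 0; s < subjects.size(); ++s) {
    const char *sub = CHAR(STRING_ELT(subjects, s));
    int slen = (int) LENGTH(STRING_ELT(subjects, s));
    for (int off = 0; off + qlen <= slen; ++off) {
      int d = 0;
      for (int j = 0; j < qlen; ++j) {
        if (!base_match(sub[off + j], query[j])) {
          if (++d > v) break;
        }
      }
      if (d <= v) {
        sidx.push_back(s + 1);
        start.push_back(off);
        mm.push_back(d);
      }
    }
  }
  return List::create(_["subject"] = wrap(sidx),
                      _["start"] = wrap(start),
                      _["mismatches"] = wrap(mm));
}

// Maximal ungapped complementary blocks between two equal-alphabet
// strings a and b along every diagonal.  a is expected to be the
// reverse complement of the lncRNA; b the mRNA.  A block is grown
// greedily from a run of matches, absorbing mismatch gaps while the
// block still starts and ends on a match and its mismatch fraction
// stays <= max_mm_frac; blocks shorter than min_block are dropped.
// Returns 0-based half-open intervals on a and b plus mismatch counts.
// When `diags` is non-empty only those diagonals are scanned (used by
// the k-mer pre-screen, which guarantees every reportable block's
// diagonal carries an exact seed match).
// [[Rcpp::export]]
DataFrame cpp_diagonal_blocks(std::string a, std::string b,
                              int min_block, double max_mm_frac,
                              IntegerVector diags = IntegerVector::create()) {
  std::vector<int> a_start, a_end, b_start, b_end, mism;
  const int la = (int) a.size(), lb = (int) b.size();
  std::vector<int> dlist;
  if (diags.size() > 0) {
    dlist.assign(diags.begin(), diags.end());
  } else {
    for (int d = -(la - 1); d <= lb - 1; ++d) dlist.push_back(d);
  }
  // diagonal d: a[i] vs b[i + d]
  for (int d : dlist) {
    if (d < -(la - 1) || d > lb - 1) continue;
    int i0 = std::max(0, -d);
    int i1 = std::min(la, lb - d);       // exclusive
    if (i1 - i0 < min_block) continue;
    int i = i0;
    while (i < i1) {
      // find start of next match run
      while (i < i1 && !base_match(a[i], b[i + d])) ++i;
      if (i >= i1) break;
      int bs = i;          // block start (a match)
      int be = i;          // block end, inclusive (last match)
      int nm = 0;          // mismatches inside [bs, be]
      int j = i;
      while (j < i1) {
        // extend over the current match run
        while (j < i1 && base_match(a[j], b[j + d])) ++j;
        be = j - 1;
        if (j >= i1) break;
        // try to absorb the next mismatch gap + following match run
        int gap_start = j;
        while (j < i1 && !base_match(a[j], b[j + d])) ++j;
        if (j >= i1) { j = gap_start; break; }
        int gap = j - gap_start;
        // peek at the next match run end
        int k = j;
        while (k < i1 && base_match(a[k], b[k + d])) ++k;
        int cand_len = k - bs;
        int cand_mm = nm + gap;
        if ((double) cand_mm <= max_mm_frac * (double) cand_len) {
          nm = cand_mm;      // absorb and continue from the run
        } else {
          j = gap_start;     // stop: block ends at last match
          break;
        }
      }
      int len = be - bs + 1;
      if (len >= min_block) {
        a_start.push_back(bs);
        a_end.push_back(be + 1);
        b_start.push_back(bs + d);
        b_end.push_back(be + 1 + d);
        mism.push_back(nm);
      }
      i = be + 1;
    }
  }
  return DataFrame::create(_["a_start"] = wrap(a_start),
                           _["a_end"] = wrap(a_end),
                           _["b_start"] = wrap(b_start),
                           _["b_end"] = wrap(b_end),
                           _["mismatches"] = wrap(mism));
}
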