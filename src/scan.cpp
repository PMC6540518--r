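#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Telomeric sequences tile in hexamer units, so all scanners here use
// non-overlapping left-to-right greedy matching: a match advances the scan
// by the motif length, a miss advances by one base.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline std::string revcomp6(const std::string& s, size_t i) {
  std::string out(6, 'N');
  for (int k = 0; k < 6; ++k) out[k] = comp(s[i + 5 - k]);
  return out;
}

static inline bool match_at(const std::string& s, size_t i, const std::string& p) {
  if (i + p.size() > s.size()) return false;
  return s.compare(i, p.size(), p) == 0;
}

// Count telomere-repeat hits per sequence. Non-consecutive mode counts all
// non-overlapping hits of any pattern; consecutive mode returns the length
// (in pattern units) of the longest run of adjacent hits, where a run may
// mix patterns from the search set.
// [[Rcpp::export]]
IntegerVector cpp_repeat_hits(CharacterVector seqs, CharacterVector patterns,
                              bool consecutive) {
  R_xlen_t np = patterns.size();
  std::vector<std::string> pats(np);
  for (R_xlen_t k = 0; k < np; ++k) pats[k] = as<std::string>(patterns[k]);
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    const std::string s = as<std::string>(seqs[r]);
    size_t i = 0;
    int count = 0, run = 0, best = 0;
    while (i < s.size()) {
      int hit = -1;
      for (R_xlen_t k = 0; k < np; ++k) {
        if (match_at(s, i, pats[k])) { hit = (int)k; break; }
      }
      if (hit >= 0) {
        ++count;
        ++run;
        if (run > best) best = run;
        i += pats[hit].size();
      } else {
        run = 0;
        ++i;
      }
    }
    out[r] = consecutive ? best : count;
  }
  return out;
}

// Scan one read for telomere-type hexamers: forward-sense NNNGGG, or
// antisense CCCNNN reported as its forward-strand reverse complement.
// A motif hit always advances the frame by 6; it is *counted* only when all
// six base qualities reach min_qual. Qualities are Phred+33 characters; an
// empty quality string disables the filter.
static void scan_hexamers_one(const std::string& s, const std::string& q,
                              int min_qual, std::vector<std::string>& hits) {
  const size_t n = s.size();
  const bool use_qual = !q.empty();
  size_t i = 0;
  while (i + 6 <= n) {
    bool acgt = true;
    for (int k = 0; k < 6; ++k) {
      if (!is_acgt(s[i + k])) { acgt = false; break; }
    }
    if (!acgt) { ++i; continue; }
    bool fwd = (s[i + 3] == 'G' && s[i + 4] == 'G' && s[i + 5] == 'G');
    bool rev = !fwd && (s[i] == 'C' && s[i + 1] == 'C' && s[i + 2] == 'C');
    if (!fwd && !rev) { ++i; continue; }
    bool qual_ok = true;
    if (use_qual) {
      for (int k = 0; k < 6; ++k) {
        if ((int)q[i + k] - 33 < min_qual) { qual_ok = false; break; }
      }
    }
    if (qual_ok) {
      hits.push_back(fwd ? s.substr(i, 6) : revcomp6(s, i));
    }
    i += 6;
  }
}

// [[Rcpp::export]]
List cpp_scan_hexamers(CharacterVector seqs, CharacterVector quals, int min_qual) {
  R_xlen_t n = seqs.size();
  bool have_quals = quals.size() == n;
  List out(n);
  std::vector<std::string> hits;
  for (R_xlen_t r = 0; r < n; ++r) {
    hits.clear();
    const std::string s = as<std::string>(seqs[r]);
    const std::string q = have_quals && !CharacterVector::is_na(quals[r])
                              ? as<std::string>(quals[r])
                              : std::string();
    scan_hexamers_one(s, q, min_qual, hits);
    out[r] = wrap(hits);
  }
  return out;
}

static const std::string TT3 = "TTAGGGTTAGGGTTAGGG";
static const std::string CC3 = "CCCTAACCCTAACCCTAA";

// Singleton variant repeats: a 42-mer (TTAGGG)3-NNNGGG-(TTAGGG)3 with a
// non-canonical centre, in either orientation; every 42-bp window is
// examined (windows may overlap through shared flanks). The base-quality
// rule applies to the central hexamer only.
static void singletons_one(const std::string& s, const std::string& q,
                           int min_qual, std::vector<std::string>& hits) {
  if (s.size() < 42) return;
  const bool use_qual = !q.empty();
  for (size_t i = 0; i + 42 <= s.size(); ++i) {
    std::string centre;
    if (match_at(s, i, TT3) && match_at(s, i + 24, TT3)) {
      bool fine = (s[i + 21] == 'G' && s[i + 22] == 'G' && s[i + 23] == 'G');
      for (int k = 18; fine && k < 21; ++k) fine = is_acgt(s[i + k]);
      if (!fine) continue;
      centre = s.substr(i + 18, 6);
      if (centre == "TTAGGG") continue;
    } else if (match_at(s, i, CC3) && match_at(s, i + 24, CC3)) {
      bool fine = (s[i + 18] == 'C' && s[i + 19] == 'C' && s[i + 20] == 'C');
      for (int k = 21; fine && k < 24; ++k) fine = is_acgt(s[i + k]);
      if (!fine) continue;
      if (s.compare(i + 18, 6, "CCCTAA") == 0) continue;
      centre = revcomp6(s, i + 18);
    } else {
      continue;
    }
    if (use_qual) {
      bool qual_ok = true;
      for (int k = 18; k < 24; ++k) {
        if ((int)q[i + k] - 33 < min_qual) { qual_ok = false; break; }
      }
      if (!qual_ok) continue;
    }
    hits.push_back(centre);
  }
}

// [[Rcpp::export]]
List cpp_detect_singletons(CharacterVector seqs, CharacterVector quals, int min_qual) {
  R_xlen_t n = seqs.size();
  bool have_quals = quals.size() == n;
  List out(n);
  std::vector<std::string> hits;
  for (R_xlen_t r = 0; r < n; ++r) {
    hits.clear();
    const std::string s = as<std::string>(seqs[r]);
    const std::string q = have_quals && !CharacterVector::is_na(quals[r])
                              ? as<std::string>(quals[r])
                              : std::string();
    singletons_one(s, q, min_qual, hits);
    out[r] = wrap(hits);
  }
  return out;
}

static std::string revcomp_span(const std::string& s, size_t i, size_t len) {
  std::string out(len, 'N');
  for (size_t k = 0; k < len; ++k) out[k] = comp(s[i + len - 1 - k]);
  return out;
}

// Flanking-context extraction for a user-selected TVR list: the hexamer scan
// is replayed and, for listed repeats with `flank` bases on both sides, the
// flank pair is recorded in telomere-forward orientation. No quality filter
// is applied.
// [[Rcpp::export]]
DataFrame cpp_extract_contexts(CharacterVector seqs, CharacterVector tvrs, int flank) {
  std::vector<std::string> tvr_set;
  for (R_xlen_t k = 0; k < tvrs.size(); ++k)
    tvr_set.push_back(as<std::string>(tvrs[k]));
  std::vector<std::string> tvr_out, left_out, right_out;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const std::string s = as<std::string>(seqs[r]);
    const size_t n = s.size();
    size_t i = 0;
    while (i + 6 <= n) {
      bool acgt = true;
      for (int k = 0; k < 6; ++k) {
        if (!is_acgt(s[i + k])) { acgt = false; break; }
      }
      if (!acgt) { ++i; continue; }
      bool fwd = (s[i + 3] == 'G' && s[i + 4] == 'G' && s[i + 5] == 'G');
      bool rev = !fwd && (s[i] == 'C' && s[i + 1] == 'C' && s[i + 2] == 'C');
      if (!fwd && !rev) { ++i; continue; }
      std::string hex = fwd ? s.substr(i, 6) : revcomp6(s, i);
      bool listed = false;
      for (size_t k = 0; k < tvr_set.size(); ++k) {
        if (hex == tvr_set[k]) { listed = true; break; }
      }
      if (listed && i >= (size_t)flank && i + 6 + flank <= n) {
        if (fwd) {
          left_out.push_back(s.substr(i - flank, flank));
          right_out.push_back(s.substr(i + 6, flank));
        } else {
          // antisense occurrence: flanks swap and reverse-complement so that
          // "left" precedes the repeat on the telomeric sense strand
          left_out.push_back(revcomp_span(s, i + 6, flank));
          right_out.push_back(revcomp_span(s, i - flank, flank));
        }
        tvr_out.push_back(hex);
      }
      i += 6;
    }
  }
  return DataFrame::create(_["tvr"] = tvr_out, _["left"] = left_out,
                           _["right"] = right_out,
                           _["stringsAsFactors"] = false);
}
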