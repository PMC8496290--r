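#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Canonical 2-bit k-mer machinery. Codes are uint64 internally (k <= 31 fits
// in 62 bits); at the R boundary they travel as doubles, exact for k <= 26
// (codes < 2^52). All scan statistics are computed on this side, so larger k
// never loses precision internally.

static inline int base_bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct KmerSet {
  std::unordered_set<uint64_t> s;
  int k;
};

struct KmerCounter {
  std::unordered_map<uint64_t, uint32_t> m;
  int k;
};

// Emit the canonical code of every valid k-window of seq into out.
template <typename F>
static void for_each_canonical(const char* seq, size_t n, int k, F fun) {
  if (n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // length of current run of ACGT ending at i
  for (size_t i = 0; i < n; ++i) {
    int b = base_bits(seq[i]);
    if (b < 0) {
      valid = 0;
      fwd = rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) fun(std::min(fwd, rev));
  }
}

// [[Rcpp::export]]
NumericVector cpp_encode_windows(CharacterVector windows, int k) {
  R_xlen_t n = windows.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (windows[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* w = CHAR(windows[i]);
    size_t len = LENGTH(windows[i]);
    if (len != (size_t)k) stop("window %d has length %d, expected k = %d",
                               (int)(i + 1), (int)len, k);
    bool got = false;
    uint64_t code = 0;
    for_each_canonical(w, len, k, [&](uint64_t c) { code = c; got = true; });
    out[i] = got ? (double)code : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_codes(NumericVector codes, int k) {
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  static const char bases[] = "ACGT";
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    uint64_t c = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[c & 3ULL];
      c >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sequence_kmers(std::string seq, int k) {
  std::vector<double> acc;
  if (seq.size() >= (size_t)k) acc.reserve(seq.size() - k + 1);
  for_each_canonical(seq.c_str(), seq.size(), k,
                     [&](uint64_t c) { acc.push_back((double)c); });
  return NumericVector(acc.begin(), acc.end());
}

// [[Rcpp::export]]
SEXP cpp_counter_new(int k) {
  XPtr<KmerCounter> p(new KmerCounter, true);
  p->k = k;
  return p;
}

// [[Rcpp::export]]
void cpp_counter_add(SEXP counter, CharacterVector seqs) {
  XPtr<KmerCounter> p(counter);
  int k = p->k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* s = CHAR(seqs[i]);
    size_t n = LENGTH(seqs[i]);
    for_each_canonical(s, n, k, [&](uint64_t c) {
      uint32_t& v = p->m[c];
      if (v < UINT32_MAX) ++v;
    });
  }
}

// [[Rcpp::export]]
double cpp_counter_distinct(SEXP counter) {
  XPtr<KmerCounter> p(counter);
  return (double)p->m.size();
}

// [[Rcpp::export]]
SEXP cpp_counter_to_set(SEXP counter, double min_count) {
  XPtr<KmerCounter> p(counter);
  XPtr<KmerSet> out(new KmerSet, true);
  out->k = p->k;
  uint32_t thr = (uint32_t)min_count;
  for (const auto& kv : p->m)
    if (kv.second >= thr) out->s.insert(kv.first);
  return out;
}

// Split an assembly counter into single-copy (count == 1) and repetitive
// (count > 1) canonical k-mer sets.
// [[Rcpp::export]]
List cpp_counter_split(SEXP counter) {
  XPtr<KmerCounter> p(counter);
  XPtr<KmerSet> single(new KmerSet, true), repet(new KmerSet, true);
  single->k = repet->k = p->k;
  for (const auto& kv : p->m) {
    if (kv.second == 1) single->s.insert(kv.first);
    else repet->s.insert(kv.first);
  }
  return List::create(_["single_copy"] = single, _["repetitive"] = repet);
}

// [[Rcpp::export]]
double cpp_set_size(SEXP set) {
  XPtr<KmerSet> p(set);
  return (double)p->s.size();
}

// [[Rcpp::export]]
int cpp_set_k(SEXP set) {
  XPtr<KmerSet> p(set);
  return p->k;
}

// [[Rcpp::export]]
LogicalVector cpp_set_contains(SEXP set, NumericVector codes) {
  XPtr<KmerSet> p(set);
  R_xlen_t n = codes.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(codes[i])) out[i] = NA_LOGICAL;
    else out[i] = p->s.count((uint64_t)codes[i]) > 0;
  }
  return out;
}

// All codes of a set, sorted ascending. Intended for small sets (tests,
// toy problems); a genome-scale set is hundreds of millions of entries.
// [[Rcpp::export]]
NumericVector cpp_set_codes(SEXP set) {
  XPtr<KmerSet> p(set);
  std::vector<uint64_t> v(p->s.begin(), p->s.end());
  std::sort(v.begin(), v.end());
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
  return out;
}

// Per-scaffold scan counts over the scaffold's DISTINCT canonical k-mers:
//   n_distinct, n_repetitive, n_single_copy,
//   n_absent_both   (distinct k-mers in neither sex's read set),
//   n_unmatched_female, n_unmatched_male (single-copy k-mers absent from
//   the female / male read set respectively).
// [[Rcpp::export]]
NumericVector cpp_scan_counts(std::string seq, SEXP single, SEXP repet,
                              SEXP female, SEXP male) {
  XPtr<KmerSet> ps(single), pr(repet), pf(female), pm(male);
  int k = ps->k;
  std::unordered_set<uint64_t> seen;
  double n_distinct = 0, n_rep = 0, n_single = 0;
  double n_absent_both = 0, n_unm_f = 0, n_unm_m = 0;
  for_each_canonical(seq.c_str(), seq.size(), k, [&](uint64_t c) {
    if (!seen.insert(c).second) return;
    ++n_distinct;
    bool in_f = pf->s.count(c) > 0;
    bool in_m = pm->s.count(c) > 0;
    if (!in_f && !in_m) ++n_absent_both;
    if (pr->s.count(c)) {
      ++n_rep;
    } else {
      ++n_single;
      if (!in_f) ++n_unm_f;
      if (!in_m) ++n_unm_m;
    }
  });
  return NumericVector::create(
      _["n_distinct"] = n_distinct, _["n_repetitive"] = n_rep,
      _["n_single_copy"] = n_single, _["n_absent_both"] = n_absent_both,
      _["n_unmatched_female"] = n_unm_f, _["n_unmatched_male"] = n_unm_m);
}

// Apply base substitutions to reads in place: read_idx (1-based), pos
// (1-based within read), repl single characters. RNG stays on the R side.
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector reads,
                                        IntegerVector read_idx,
                                        IntegerVector pos,
                                        CharacterVector repl) {
  R_xlen_t n = read_idx.size();
  if (pos.size() != n || repl.size() != n)
    stop("read_idx, pos and repl must have equal length");
  CharacterVector out = clone(reads);
  // group edits by read to avoid repeated string rebuilds
  std::unordered_map<int, std::string> bufs;
  for (R_xlen_t i = 0; i < n; ++i) {
    int ri = read_idx[i] - 1;
    if (ri < 0 || ri >= out.size()) stop("read index out of range");
    auto it = bufs.find(ri);
    if (it == bufs.end())
      it = bufs.emplace(ri, std::string(CHAR(out[ri]))).first;
    int pj = pos[i] - 1;
    if (pj < 0 || (size_t)pj >= it->second.size())
      stop("substitution position out of range");
    it->second[pj] = CHAR(repl[i])[0];
  }
  for (auto& kv : bufs) out[kv.first] = kv.second;
  return out;
}
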