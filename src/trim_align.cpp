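#include <Rcpp.h>
#include <climits>
#include <cstring>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3' quality trimming, BWA-style running-sum rule: subtract the cutoff from
// every quality, form partial sums from the 3' end, cut at the minimum.
// Returns, per read, the number of leading bases to keep.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_quality_cut(CharacterVector quals, int cutoff, int offset) {
  int n = quals.size();
  IntegerVector keep(n);
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(quals, r));
    int L = (int)strlen(q);
    long sum = 0, minsum = 0;
    int cut = L;
    for (int i = L - 1; i >= 0; --i) {
      sum += (long)(q[i] - offset) - cutoff;
      if (sum < minsum) {
        minsum = sum;
        cut = i;
      }
    }
    keep[r] = cut;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Semi-global adapter search (cutadapt-like 3' adapter semantics).
// An occurrence is either the full adapter aligned anywhere in the read, or
// an adapter prefix (length >= min_overlap) aligned flush with the read's 3'
// end. Substitutions and indels cost 1. A candidate is acceptable iff
// errors / matched_adapter_length <= max_error_rate. Among acceptable
// candidates the smallest error count wins, ties broken by leftmost start.
// ---------------------------------------------------------------------------

struct AdapterMatch {
  bool found;
  int start;   // 0-based start in read; trimming keeps read[0, start)
  int errors;
  int mlen;    // matched adapter (prefix) length
};

static AdapterMatch find_adapter_core(const char *read, int rlen,
                                      const char *ad, int alen,
                                      double max_err, int min_overlap) {
  AdapterMatch best;
  best.found = false;
  best.start = INT_MAX;
  best.errors = INT_MAX;
  best.mlen = 0;
  std::vector<int> Dprev(rlen + 1), Dcur(rlen + 1);
  std::vector<int> Sprev(rlen + 1), Scur(rlen + 1);
  for (int i = 0; i <= rlen; ++i) {
    Dprev[i] = 0;  // free start anywhere in the read
    Sprev[i] = i;
  }
  for (int j = 1; j <= alen; ++j) {
    Dcur[0] = j;
    Scur[0] = 0;
    for (int i = 1; i <= rlen; ++i) {
      int d = Dprev[i - 1] + (ad[j - 1] == read[i - 1] ? 0 : 1);
      int s = Sprev[i - 1];
      int del = Dprev[i] + 1;  // adapter char unmatched (gap in read)
      if (del < d || (del == d && Sprev[i] < s)) {
        d = del;
        s = Sprev[i];
      }
      int ins = Dcur[i - 1] + 1;  // extra read char inside occurrence
      if (ins < d || (ins == d && Scur[i - 1] < s)) {
        d = ins;
        s = Scur[i - 1];
      }
      Dcur[i] = d;
      Scur[i] = s;
    }
    if (j >= min_overlap) {  // adapter prefix flush with the read 3' end
      int d = Dcur[rlen];
      if ((double)d <= max_err * j &&
          (d < best.errors || (d == best.errors && Scur[rlen] < best.start))) {
        best.found = true;
        best.errors = d;
        best.start = Scur[rlen];
        best.mlen = j;
      }
    }
    if (j == alen) {  // full adapter ending anywhere
      for (int i = 0; i <= rlen; ++i) {
        int d = Dcur[i];
        if ((double)d <= max_err * alen &&
            (d < best.errors || (d == best.errors && Scur[i] < best.start))) {
          best.found = true;
          best.errors = d;
          best.start = Scur[i];
          best.mlen = alen;
        }
      }
    }
    std::swap(Dprev, Dcur);
    std::swap(Sprev, Scur);
  }
  return best;
}

// [[Rcpp::export]]
List cpp_find_adapter(CharacterVector seqs, std::string adapter,
                      double max_error_rate, int min_overlap) {
  int n = seqs.size();
  IntegerVector start(n), errors(n), mlen(n);
  LogicalVector found(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    AdapterMatch m = find_adapter_core(s, (int)strlen(s), adapter.c_str(),
                                       (int)adapter.size(), max_error_rate,
                                       min_overlap);
    found[r] = m.found;
    start[r] = m.found ? m.start : NA_INTEGER;
    errors[r] = m.found ? m.errors : NA_INTEGER;
    mlen[r] = m.found ? m.mlen : NA_INTEGER;
  }
  return List::create(_["found"] = found, _["start"] = start,
                      _["errors"] = errors, _["match_length"] = mlen);
}

// ---------------------------------------------------------------------------
// Batch read trimming: one quality trim, then up to max_rounds rounds each
// removing the earliest-starting acceptable adapter/homopolymer occurrence,
// then status classification (dimer > too_short > quality_fail > kept).
// status codes: 0 kept, 1 adapter_dimer, 2 too_short, 3 quality_fail
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_trim_batch(CharacterVector seqs, CharacterVector quals,
                    CharacterVector adapters, CharacterVector adapter_kinds,
                    int qual_cutoff, int offset, double max_error_rate,
                    int min_overlap, int max_rounds, int dimer_max_len,
                    int min_len, int max_n, LogicalVector force_fail) {
  int n = seqs.size();
  int na = adapters.size();
  std::vector<std::string> ads(na), kinds(na);
  for (int a = 0; a < na; ++a) {
    ads[a] = as<std::string>(adapters[a]);
    kinds[a] = as<std::string>(adapter_kinds[a]);
  }
  IntegerVector status(n), rounds(n);
  CharacterVector out_seq(n), out_qual(n), removed(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string q = as<std::string>(quals[r]);
    std::string rem;
    // quality trim once
    {
      long sum = 0, minsum = 0;
      int L = (int)s.size(), cut = L;
      for (int i = L - 1; i >= 0; --i) {
        sum += (long)(q[i] - offset) - qual_cutoff;
        if (sum < minsum) {
          minsum = sum;
          cut = i;
        }
      }
      if (cut < L) {
        rem += "quality=" + s.substr(cut);
        s = s.substr(0, cut);
        q = q.substr(0, cut);
      }
    }
    int nr = 0;
    for (; nr < max_rounds; ++nr) {
      int best_a = -1, best_start = INT_MAX;
      AdapterMatch best;
      for (int a = 0; a < na; ++a) {
        if ((int)ads[a].size() < min_overlap) continue;
        AdapterMatch m =
            find_adapter_core(s.c_str(), (int)s.size(), ads[a].c_str(),
                              (int)ads[a].size(), max_error_rate, min_overlap);
        if (m.found && m.start < best_start) {
          best_start = m.start;
          best_a = a;
          best = m;
        }
      }
      if (best_a < 0) break;
      if (!rem.empty()) rem += ";";
      rem += kinds[best_a] + "=" + s.substr(best.start);
      s = s.substr(0, best.start);
      q = q.substr(0, best.start);
    }
    rounds[r] = nr;
    int len = (int)s.size();
    int ncount = 0;
    for (int i = 0; i < len; ++i)
      if (s[i] == 'N') ++ncount;
    int st;
    if (len <= dimer_max_len)
      st = 1;
    else if (len < min_len)
      st = 2;
    else if (ncount > max_n || force_fail[r])
      st = 3;
    else
      st = 0;
    status[r] = st;
    out_seq[r] = s;
    out_qual[r] = q;
    removed[r] = rem;
  }
  return List::create(_["status"] = status, _["sequence"] = out_seq,
                      _["quality"] = out_qual, _["removed"] = removed,
                      _["rounds"] = rounds);
}

// ---------------------------------------------------------------------------
// Read-vs-reference alignment: read end-to-end, free end gaps on the
// reference only. errors = unit-cost edit operations on the optimal path;
// identity = 1 - errors / read_length.
// ---------------------------------------------------------------------------

static int semi_global_errors(const char *read, int rlen, const char *ref,
                              int flen) {
  // D[i][j]: read[1..i] vs reference segment ending at j, free leading and
  // trailing reference overhang.
  std::vector<int> prev(flen + 1), cur(flen + 1);
  for (int j = 0; j <= flen; ++j) prev[j] = 0;
  for (int i = 1; i <= rlen; ++i) {
    cur[0] = i;
    for (int j = 1; j <= flen; ++j) {
      int d = prev[j - 1] + (read[i - 1] == ref[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      if (up < d) d = up;
      int left = cur[j - 1] + 1;
      if (left < d) d = left;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  int best = INT_MAX;
  for (int j = 0; j <= flen; ++j)
    if (prev[j] < best) best = prev[j];
  return best;
}

// Banded variant with early abandon: returns maxe + 1 as soon as no
// alignment with at most maxe errors is possible. Identical result to the
// full DP whenever that result is <= maxe.
static int semi_global_errors_bounded(const char *read, int rlen,
                                      const char *ref, int flen, int maxe) {
  if (rlen - flen > maxe) return maxe + 1;
  const int INF = maxe + 1;
  // any path with <= maxe errors keeps j - i within the band below
  int lo_off = -(maxe + (rlen > flen ? rlen - flen : 0));
  int hi_off = maxe + (flen > rlen ? flen - rlen : 0);
  std::vector<int> prev(flen + 1, 0), cur(flen + 1, INF);
  for (int i = 1; i <= rlen; ++i) {
    int jlo = i + lo_off;
    if (jlo < 1) jlo = 1;
    int jhi = i + hi_off;
    if (jhi > flen) jhi = flen;
    if (jlo > jhi) return INF;
    int rowmin = INF;
    cur[0] = i > maxe ? INF : i;
    if (jlo > 1) cur[jlo - 1] = INF;
    for (int j = jlo; j <= jhi; ++j) {
      int d = prev[j - 1] + (read[i - 1] == ref[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      if (up < d) d = up;
      int left = cur[j - 1] + 1;
      if (left < d) d = left;
      if (d > INF) d = INF;
      cur[j] = d;
      if (d < rowmin) rowmin = d;
    }
    if (jhi < flen) cur[jhi + 1] = INF;
    if (rowmin >= INF) return INF;
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), INF);
  }
  int best = INF;
  for (int j = 0; j <= flen; ++j)
    if (prev[j] < best) best = prev[j];
  return best;
}

// All hits at identity >= min_identity, all read x reference pairs.
// [[Rcpp::export]]
DataFrame cpp_map_all(CharacterVector reads, CharacterVector refs,
                      double min_identity) {
  std::vector<int> out_read, out_ref, out_err;
  std::vector<double> out_id;
  int nrd = reads.size(), nrf = refs.size();
  std::vector<std::string> R(nrf);
  for (int f = 0; f < nrf; ++f) R[f] = as<std::string>(refs[f]);
  for (int r = 0; r < nrd; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int rlen = (int)strlen(s);
    if (rlen == 0) continue;
    int maxe = (int)std::floor((1.0 - min_identity) * rlen + 1e-9);
    for (int f = 0; f < nrf; ++f) {
      int e = semi_global_errors(s, rlen, R[f].c_str(), (int)R[f].size());
      if (e <= maxe) {
        out_read.push_back(r + 1);
        out_ref.push_back(f + 1);
        out_err.push_back(e);
        out_id.push_back(1.0 - (double)e / rlen);
      }
    }
  }
  return DataFrame::create(_["read_idx"] = out_read, _["ref_idx"] = out_ref,
                           _["errors"] = out_err, _["identity"] = out_id);
}

// Best hit per read only, with an exact-sequence fast path. `refs` must be
// in the desired tie-break order (lexicographic feature id): the first
// reference achieving the minimal error count wins.
// [[Rcpp::export]]
DataFrame cpp_map_best(CharacterVector reads, CharacterVector refs,
                       double min_identity) {
  int nrd = reads.size(), nrf = refs.size();
  std::vector<std::string> R(nrf);
  std::map<std::string, int> exact;
  for (int f = 0; f < nrf; ++f) {
    R[f] = as<std::string>(refs[f]);
    if (exact.find(R[f]) == exact.end()) exact[R[f]] = f;
  }
  IntegerVector ref_idx(nrd), errors(nrd);
  NumericVector identity(nrd);
  for (int r = 0; r < nrd; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int rlen = (int)strlen(s);
    ref_idx[r] = NA_INTEGER;
    errors[r] = NA_INTEGER;
    identity[r] = NA_REAL;
    if (rlen == 0) continue;
    std::string key(s);
    std::map<std::string, int>::iterator it = exact.find(key);
    if (it != exact.end()) {
      ref_idx[r] = it->second + 1;
      errors[r] = 0;
      identity[r] = 1.0;
      continue;
    }
    int maxe = (int)std::floor((1.0 - min_identity) * rlen + 1e-9);
    int best_e = INT_MAX, best_f = -1;
    for (int f = 0; f < nrf; ++f) {
      int flen = (int)R[f].size();
      if ((double)flen / rlen < min_identity) continue;  // too many insertions
      int bound = best_e <= maxe ? best_e - 1 : maxe;
      int e = semi_global_errors_bounded(s, rlen, R[f].c_str(), flen, bound);
      if (e <= maxe && e < best_e) {
        best_e = e;
        best_f = f;
        if (e == 0) break;
      }
    }
    if (best_f >= 0) {
      ref_idx[r] = best_f + 1;
      errors[r] = best_e;
      identity[r] = 1.0 - (double)best_e / rlen;
    }
  }
  return DataFrame::create(_["ref_idx"] = ref_idx, _["errors"] = errors,
                           _["identity"] = identity);
}
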