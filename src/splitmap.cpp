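#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Suffix array construction and queries
//
// The index is a plain suffix array over the concatenated genome (chromosomes
// joined by '#', terminated by '$').  Reads only contain A,C,G,T plus 'n'
// (the R layer maps read N -> 'n' so that N never matches anything, which
// also keeps seeds from spanning N runs).  Comparison-sort construction is
// O(n log n * avg-lcp); on (near-)random genomes the average lcp is tiny.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector sa_build_cpp(std::string text) {
  const int n = (int) text.size();
  std::vector<int> sa(n);
  for (int i = 0; i < n; ++i) sa[i] = i;
  const char *s = text.c_str();
  std::sort(sa.begin(), sa.end(),
            [s](int a, int b) { return strcmp(s + a, s + b) < 0; });
  return IntegerVector(sa.begin(), sa.end());
}

// narrow SA interval [lo,hi) (all sharing a prefix of length t) to suffixes
// whose character at offset t equals c
static inline void sa_narrow(const char *txt, const int *sa, int lo, int hi,
                             int t, char c, int &nlo, int &nhi) {
  int a = lo, b = hi;
  while (a < b) { int mid = (a + b) / 2; if (txt[sa[mid] + t] < c) a = mid + 1; else b = mid; }
  nlo = a;
  b = hi;
  while (a < b) { int mid = (a + b) / 2; if (txt[sa[mid] + t] <= c) a = mid + 1; else b = mid; }
  nhi = a;
}

// longest prefix of pat[0..plen) that occurs in the text; on return [lo,hi)
// is the SA interval of that prefix.  Returns the matched length.
static int sa_maxmatch(const char *txt, int n, const int *sa, const char *pat,
                       int plen, int &lo, int &hi) {
  lo = 0; hi = n;
  int t = 0;
  while (t < plen) {
    char c = pat[t];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') break;
    int nlo, nhi;
    sa_narrow(txt, sa, lo, hi, t, c, nlo, nhi);
    if (nlo >= nhi) break;
    lo = nlo; hi = nhi;
    ++t;
  }
  return t;
}

// [[Rcpp::export]]
List sa_find_cpp(std::string text, IntegerVector sa, std::string pattern) {
  int lo, hi;
  int L = sa_maxmatch(text.c_str(), (int) sa.size(), INTEGER(sa),
                      pattern.c_str(), (int) pattern.size(), lo, hi);
  IntegerVector pos;
  if (L == (int) pattern.size() && hi > lo) {
    pos = IntegerVector(hi - lo);
    for (int k = lo; k < hi; ++k) pos[k - lo] = sa[k];
    std::sort(pos.begin(), pos.end());
  }
  return List::create(_["match_length"] = L, _["positions"] = pos);
}

static double entropy_of(const char *s, int len) {
  int cnt[256] = {0};
  for (int i = 0; i < len; ++i) cnt[(unsigned char) s[i]]++;
  double h = 0.0;
  for (int c = 0; c < 256; ++c) {
    if (cnt[c] > 0) {
      double p = (double) cnt[c] / len;
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct RawSeed {
  int read_start, read_end, score, ref_len;
  int strand;       // 0 = '+', 1 = '-'
  double entropy;
  std::vector<int> occ;  // text positions (forward coordinates)
};

// scan all suffixes of one oriented read copy; jump-ahead past each maximal
// exact match (geometry independent of the entropy/occurrence filters)
static void scan_orientation(const char *txt, int n, const int *sa,
                             const std::string &s, int strand, int min_len,
                             int max_occ, double entropy_min, int max_err,
                             std::vector<RawSeed> &out) {
  const int m = (int) s.size();
  int i = 0;
  while (i + min_len <= m) {
    int lo, hi;
    int L = sa_maxmatch(txt, n, sa, s.c_str() + i, m - i, lo, hi);
    if (L >= min_len) {
      int nocc = hi - lo;
      int Lfin = L;
      double psi = L;
      if (max_err >= 1 && nocc == 1 && i + L < m) {
        // extend through a single substitution (unique locus only)
        int p = sa[lo];
        int ext = 0;
        while (i + L + 1 + ext < m && p + L + 1 + ext < n) {
          char g = txt[p + L + 1 + ext];
          if (g != 'A' && g != 'C' && g != 'G' && g != 'T') break;
          if (g != s[i + L + 1 + ext]) break;
          ++ext;
        }
        if (ext >= 2) { Lfin = L + 1 + ext; psi = (L + ext) - 1; }
      }
      double ent = entropy_of(s.c_str() + i, Lfin);
      if (nocc <= max_occ && ent >= entropy_min - 1e-12) {
        RawSeed sd;
        sd.strand = strand;
        sd.score = (int) psi;
        sd.ref_len = Lfin;
        sd.entropy = ent;
        if (strand == 0) { sd.read_start = i; sd.read_end = i + Lfin - 1; }
        else             { sd.read_start = m - (i + Lfin); sd.read_end = m - i - 1; }
        sd.occ.assign(sa + lo, sa + hi);
        std::sort(sd.occ.begin(), sd.occ.end());
        out.push_back(sd);
      }
      i += L;  // resume at the first unmatched read position
    } else {
      i += 1;
    }
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'n'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
List collect_seeds_cpp(std::string text, IntegerVector sa, std::string read,
                       int min_len, int max_occ, double entropy_min,
                       int max_err) {
  const char *txt = text.c_str();
  const int n = (int) sa.size();
  const int *sap = INTEGER(sa);
  // map N -> 'n' so it can never match the text
  std::string fwd = read;
  for (auto &c : fwd) if (c != 'A' && c != 'C' && c != 'G' && c != 'T') c = 'n';
  std::string rev = revcomp_str(fwd);
  std::vector<RawSeed> seeds;
  scan_orientation(txt, n, sap, fwd, 0, min_len, max_occ, entropy_min, max_err, seeds);
  scan_orientation(txt, n, sap, rev, 1, min_len, max_occ, entropy_min, max_err, seeds);
  const int k = (int) seeds.size();
  IntegerVector rs(k), re(k), sc(k), rl(k), strand(k), nocc(k);
  NumericVector ent(k);
  List occ(k);
  for (int j = 0; j < k; ++j) {
    rs[j] = seeds[j].read_start; re[j] = seeds[j].read_end;
    sc[j] = seeds[j].score;      rl[j] = seeds[j].ref_len;
    strand[j] = seeds[j].strand; ent[j] = seeds[j].entropy;
    nocc[j] = (int) seeds[j].occ.size();
    occ[j] = IntegerVector(seeds[j].occ.begin(), seeds[j].occ.end());
  }
  return List::create(_["read_start"] = rs, _["read_end"] = re,
                      _["score"] = sc, _["ref_len"] = rl,
                      _["strand"] = strand, _["entropy"] = ent,
                      _["n_occ"] = nocc, _["occ"] = occ);
}

// ---------------------------------------------------------------------------
// Greedy chaining (dynamic program over seeds sorted by read start).
// sigma[i] = psi[i] + max(0, max_{j: re[j] < re[i]} sigma[j] - |re[j]-rs[i]|)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List greedy_chain_cpp(IntegerVector rs, IntegerVector re, IntegerVector psi) {
  const int k = rs.size();
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (rs[a] != rs[b]) return rs[a] < rs[b];
    return re[a] < re[b];
  });
  std::vector<double> sigma(k);
  std::vector<int> back(k, -1), nfrag(k, 1);
  double comparisons = 0;
  for (int oi = 0; oi < k; ++oi) {
    int i = ord[oi];
    double best = 0; int bestj = -1, bestn = 0;
    for (int oj = 0; oj < oi; ++oj) {
      int j = ord[oj];
      comparisons += 1;
      if (re[j] >= re[i]) continue;
      double cand = sigma[j] - std::abs((double) re[j] - (double) rs[i]);
      if (cand > best ||
          (cand == best && bestj >= 0 && nfrag[j] + 1 < bestn)) {
        best = cand; bestj = j; bestn = nfrag[j] + 1;
      }
    }
    if (bestj >= 0 && best > 0) {
      sigma[i] = psi[i] + best; back[i] = bestj; nfrag[i] = bestn;
    } else {
      sigma[i] = psi[i]; back[i] = -1; nfrag[i] = 1;
    }
  }
  return List::create(_["sigma"] = NumericVector(sigma.begin(), sigma.end()),
                      _["back"] = IntegerVector(back.begin(), back.end()),
                      _["nfrag"] = IntegerVector(nfrag.begin(), nfrag.end()),
                      _["comparisons"] = comparisons);
}

// ---------------------------------------------------------------------------
// Local transition alignment.
//
// A Smith-Waterman DP over (read position i, window k, window position j)
// where, in addition to the local-alignment moves, a cell may continue from
// the best score seen in any preceding window at an earlier read position
// (the lms table), paying a transition penalty tau.  The transition cell
// also consumes the (i,j) pair diagonally.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List transition_align_cpp(std::string read, CharacterVector windows,
                          int match, int mismatch, int delta, int tau) {
  const int m = (int) read.size();
  const int K = windows.size();
  const char *r = read.c_str();

  std::vector<std::string> win(K);
  std::vector<int> wlen(K);
  for (int k = 0; k < K; ++k) { win[k] = as<std::string>(windows[k]); wlen[k] = (int) win[k].size(); }

  // best over processed windows of lms[k'][i], plus the arg cell
  std::vector<int> prevLMS(m + 1, 0), prevK(m + 1, -1), prevI(m + 1, 0), prevJ(m + 1, 0);
  // per-window transition-source snapshots and traceback matrices
  std::vector<std::vector<int>> srcK(K), srcI(K), srcJ(K), srcV(K);
  std::vector<std::vector<unsigned char>> dir(K);

  int bestScore = 0, bestK = -1, bestI = 0, bestJ = 0;

  for (int k = 0; k < K; ++k) {
    const int w = wlen[k];
    const char *wp = win[k].c_str();
    srcK[k] = prevK; srcI[k] = prevI; srcJ[k] = prevJ; srcV[k] = prevLMS;
    dir[k].assign((size_t)(m + 1) * (w + 1), 0);
    std::vector<int> prevRow(w + 1, 0), curRow(w + 1, 0);
    std::vector<int> lms(m + 1, 0), lmsAI(m + 1, 0), lmsAJ(m + 1, 0);
    for (int i = 1; i <= m; ++i) {
      unsigned char *dr = &dir[k][(size_t) i * (w + 1)];
      int rowmax = 0, rowaj = 0;
      const char rc = r[i - 1];
      const int transBase = (k > 0) ? prevLMS[i - 1] - tau : INT_MIN / 2;
      curRow[0] = 0;
      for (int j = 1; j <= w; ++j) {
        const int sab = (rc == wp[j - 1] && rc != 'N') ? match : mismatch;
        int best = 0; unsigned char d = 0;
        int v = prevRow[j - 1] + sab;
        if (v > best) { best = v; d = 1; }
        v = prevRow[j] - delta;
        if (v > best) { best = v; d = 2; }
        v = curRow[j - 1] - delta;
        if (v > best) { best = v; d = 3; }
        if (k > 0) {
          v = transBase + sab;
          if (v > best) { best = v; d = 4; }
        }
        curRow[j] = best; dr[j] = d;
        if (best > rowmax) { rowmax = best; rowaj = j; }
      }
      if (rowmax > lms[i - 1]) { lms[i] = rowmax; lmsAI[i] = i; lmsAJ[i] = rowaj; }
      else { lms[i] = lms[i - 1]; lmsAI[i] = lmsAI[i - 1]; lmsAJ[i] = lmsAJ[i - 1]; }
      if (rowmax > bestScore) { bestScore = rowmax; bestK = k; bestI = i; bestJ = rowaj; }
      std::swap(prevRow, curRow);
    }
    for (int i = 1; i <= m; ++i) {
      if (lms[i] > prevLMS[i]) {
        prevLMS[i] = lms[i]; prevK[i] = k; prevI[i] = lmsAI[i]; prevJ[i] = lmsAJ[i];
      }
    }
  }

  if (bestScore <= 0 || bestK < 0) {
    return List::create(_["total"] = 0, _["fragments"] = List(0), _["transitions"] = 0);
  }

  // traceback
  struct Frag { int k, i1, i2, j1, j2; std::string ops; };
  std::vector<Frag> frags;
  int k = bestK, i = bestI, j = bestJ;
  Frag cur; cur.k = k; cur.i2 = i; cur.j2 = j; cur.ops.clear();
  while (true) {
    unsigned char d = dir[k][(size_t) i * (wlen[k] + 1) + j];
    if (d == 0) {
      cur.i1 = i + 1; cur.j1 = j + 1;
      frags.push_back(cur);
      break;
    } else if (d == 1) {
      cur.ops.push_back((r[i - 1] == win[k][j - 1] && r[i - 1] != 'N') ? 'M' : 'X');
      --i; --j;
    } else if (d == 2) {
      cur.ops.push_back('I'); --i;
    } else if (d == 3) {
      cur.ops.push_back('D'); --j;
    } else {
      // transition: this cell consumed (i,j) diagonally; jump to source cell
      cur.ops.push_back((r[i - 1] == win[k][j - 1] && r[i - 1] != 'N') ? 'M' : 'X');
      cur.i1 = i; cur.j1 = j;
      frags.push_back(cur);
      int pk = srcK[k][i - 1], pi = srcI[k][i - 1], pj = srcJ[k][i - 1];
      k = pk; i = pi; j = pj;
      cur = Frag(); cur.k = k; cur.i2 = i; cur.j2 = j; cur.ops.clear();
    }
  }
  std::reverse(frags.begin(), frags.end());

  List fl(frags.size());
  for (size_t f = 0; f < frags.size(); ++f) {
    Frag &fr = frags[f];
    std::reverse(fr.ops.begin(), fr.ops.end());
    int score = 0;
    for (char c : fr.ops) {
      if (c == 'M') score += match;
      else if (c == 'X') score += mismatch;
      else score -= delta;
    }
    fl[f] = List::create(_["window"] = fr.k + 1,
                         _["read_start"] = fr.i1 - 1, _["read_end"] = fr.i2 - 1,
                         _["win_start"] = fr.j1 - 1, _["win_end"] = fr.j2 - 1,
                         _["ops"] = fr.ops, _["score"] = score);
  }
  return List::create(_["total"] = bestScore, _["fragments"] = fl,
                      _["transitions"] = (int) frags.size() - 1);
}

// ---------------------------------------------------------------------------
// Semi-global alignment: minimal edit distance of the full read against any
// substring of the window (free gaps at both window ends), with traceback.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List semi_global_cpp(std::string read, std::string window) {
  const int m = (int) read.size(), w = (int) window.size();
  const char *r = read.c_str(), *g = window.c_str();
  std::vector<int> D((size_t)(m + 1) * (w + 1));
  std::vector<unsigned char> B((size_t)(m + 1) * (w + 1));
  for (int j = 0; j <= w; ++j) { D[j] = 0; B[j] = 0; }
  for (int i = 1; i <= m; ++i) {
    D[(size_t) i * (w + 1)] = i;
    B[(size_t) i * (w + 1)] = 2;
    for (int j = 1; j <= w; ++j) {
      const size_t idx = (size_t) i * (w + 1) + j;
      int diag = D[idx - w - 2] + ((r[i - 1] == g[j - 1] && r[i - 1] != 'N') ? 0 : 1);
      int up   = D[idx - w - 1] + 1;
      int left = D[idx - 1] + 1;
      int best = diag; unsigned char d = 1;
      if (up < best)   { best = up; d = 2; }
      if (left < best) { best = left; d = 3; }
      D[idx] = best; B[idx] = d;
    }
  }
  int dist = INT_MAX, end = 0;
  for (int j = 0; j <= w; ++j) {
    int v = D[(size_t) m * (w + 1) + j];
    if (v < dist) { dist = v; end = j; }
  }
  std::string ops;
  int i = m, j = end;
  while (i > 0) {
    unsigned char d = B[(size_t) i * (w + 1) + j];
    if (d == 1) { ops.push_back((r[i - 1] == g[j - 1] && r[i - 1] != 'N') ? 'M' : 'X'); --i; --j; }
    else if (d == 2) { ops.push_back('I'); --i; }
    else { ops.push_back('D'); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["distance"] = dist, _["end"] = end,
                      _["start"] = j, _["ops"] = ops);
}
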