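#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Exact-word seed finding between two integer-encoded sequences.
// Codes >= alpha are ambiguity codes and any word containing one is skipped.
// Returns a two-column matrix of 1-based word start positions (query, subject).
// [[Rcpp::export]]
IntegerMatrix cpp_find_seeds(IntegerVector q, IntegerVector s, int w, int alpha,
                             int max_seeds = 200000) {
  int nq = q.size(), ns = s.size();
  std::vector<int> qpos, spos;
  if (nq < w || ns < w) return IntegerMatrix(0, 2);

  // index the shorter sequence, stream over the longer one
  bool index_subject = (ns <= nq);
  const IntegerVector &a = index_subject ? s : q; // indexed
  const IntegerVector &b = index_subject ? q : s; // streamed
  int na = a.size(), nb = b.size();

  std::unordered_multimap<long long, int> index;
  index.reserve(na);
  long long base = alpha;
  long long mod = 1;
  for (int i = 0; i < w - 1; ++i) mod *= base;

  // rolling exact encoding (not a lossy hash)
  long long key = 0;
  int valid = 0; // length of current ambiguity-free run
  for (int j = 0; j < na; ++j) {
    int c = a[j];
    if (c >= alpha || c < 0) { valid = 0; key = 0; continue; }
    key = (valid >= w) ? (key % mod) * base + c : key * base + c;
    ++valid;
    if (valid >= w) index.emplace(key, j - w + 2); // 1-based start
  }

  key = 0; valid = 0;
  int total = 0;
  for (int i = 0; i < nb && total < max_seeds; ++i) {
    int c = b[i];
    if (c >= alpha || c < 0) { valid = 0; key = 0; continue; }
    key = (valid >= w) ? (key % mod) * base + c : key * base + c;
    ++valid;
    if (valid >= w) {
      auto range = index.equal_range(key);
      for (auto it = range.first; it != range.second && total < max_seeds; ++it) {
        int bpos = i - w + 2;
        qpos.push_back(index_subject ? bpos : it->second);
        spos.push_back(index_subject ? it->second : bpos);
        ++total;
      }
    }
  }
  IntegerMatrix out(qpos.size(), 2);
  for (size_t k = 0; k < qpos.size(); ++k) {
    out(k, 0) = qpos[k];
    out(k, 1) = spos[k];
  }
  return out;
}

static int xdrop_extend(const int *q, int nq, const int *s, int ns,
                        int q0, int s0, int w, const IntegerMatrix &mat,
                        int xdrop) {
  // q0, s0 are 0-based word starts
  int word = 0;
  for (int k = 0; k < w; ++k) word += mat(q[q0 + k], s[s0 + k]);
  int cur = word, best_r = word;
  for (int i = q0 + w, j = s0 + w; i < nq && j < ns; ++i, ++j) {
    cur += mat(q[i], s[j]);
    if (cur > best_r) best_r = cur;
    if (best_r - cur > xdrop) break;
  }
  cur = best_r;
  int best = best_r;
  for (int i = q0 - 1, j = s0 - 1; i >= 0 && j >= 0; --i, --j) {
    cur += mat(q[i], s[j]);
    if (cur > best) best = cur;
    if (best - cur > xdrop) break;
  }
  return best;
}

// Find seeds, cluster them by diagonal band and subject locality, and
// keep only clusters whose best ungapped X-drop extension reaches
// min_ungapped.  Returns one row per surviving cluster: dlo, dhi (band
// of diagonals) -- the expensive triage loop kept out of R.
// [[Rcpp::export]]
DataFrame cpp_seed_clusters(IntegerVector q, IntegerVector s, int w, int alpha,
                            IntegerMatrix mat, int band_pad, int max_sep,
                            int xdrop, int min_ungapped,
                            int max_seeds = 200000) {
  IntegerMatrix seeds = cpp_find_seeds(q, s, w, alpha, max_seeds);
  int n = seeds.nrow();
  std::vector<int> dlo_out, dhi_out, score_out;
  if (n > 0) {
    std::vector<std::pair<int, int> > ds(n); // (diagonal, spos); qpos = spos - d
    for (int i = 0; i < n; ++i)
      ds[i] = std::make_pair(seeds(i, 1) - seeds(i, 0), seeds(i, 1));
    std::sort(ds.begin(), ds.end());
    const int *qp = &q[0];
    const int *sp = &s[0];
    int nq = q.size(), ns = s.size();
    int i = 0;
    while (i < n) {
      int j = i + 1; // diagonal group [i, j)
      while (j < n && ds[j].first - ds[j - 1].first <= band_pad) ++j;
      int a = i;
      for (int k = a + 1; k <= j; ++k) {
        if (k < j && ds[k].second - ds[k - 1].second <= max_sep) continue;
        // subcluster [a, k): probe up to 8 seeds, keep if one extends
        int m = k - a;
        int best = -1000000000;
        int probes = m < 8 ? m : 8;
        for (int t = 0; t < probes; ++t) {
          int idx = a + (int)((long long)t * (m - 1) / (probes > 1 ? probes - 1 : 1));
          int spos = ds[idx].second - 1;
          int qpos = spos - ds[idx].first; // 0-based
          int sc = xdrop_extend(qp, nq, sp, ns, qpos, spos, w, mat, xdrop);
          if (sc > best) best = sc;
        }
        if (best >= min_ungapped) {
          int lo = ds[a].first, hi = ds[k - 1].first;
          dlo_out.push_back(lo);
          dhi_out.push_back(hi);
          score_out.push_back(best);
        }
        a = k;
      }
      i = j;
    }
  }
  return DataFrame::create(_["dlo"] = dlo_out, _["dhi"] = dhi_out,
                           _["ungapped"] = score_out);
}

// Ungapped X-drop extension of a word seed; returns the best ungapped score.
// q0, s0 are 1-based word start positions.
// [[Rcpp::export]]
int cpp_xdrop(IntegerVector q, IntegerVector s, int q0, int s0, int w,
              IntegerMatrix mat, int xdrop) {
  int nq = q.size(), ns = s.size();
  --q0; --s0; // 0-based
  int word = 0;
  for (int k = 0; k < w; ++k) word += mat(q[q0 + k], s[s0 + k]);
  // extend right of the word
  int cur = word, best_r = word;
  for (int i = q0 + w, j = s0 + w; i < nq && j < ns; ++i, ++j) {
    cur += mat(q[i], s[j]);
    if (cur > best_r) best_r = cur;
    if (best_r - cur > xdrop) break;
  }
  // extend left of the word, on top of the best rightward extension
  cur = best_r;
  int best = best_r;
  for (int i = q0 - 1, j = s0 - 1; i >= 0 && j >= 0; --i, --j) {
    cur += mat(q[i], s[j]);
    if (cur > best) best = cur;
    if (best - cur > xdrop) break;
  }
  return best;
}

// Banded affine-gap Smith-Waterman with traceback.
// Band is over diagonals d = (j - i) with d in [dlo, dhi], i over query rows,
// j over subject columns (both 0-based internally).  A gap of length L costs
// gap_open + L * gap_extend.  Returns the single best local alignment.
// [[Rcpp::export]]
List cpp_banded_sw(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                   int gap_open, int gap_extend, int dlo, int dhi) {
  const int m = q.size(), n = s.size();
  const int W = dhi - dlo + 1;
  if (m == 0 || n == 0 || W <= 0)
    return List::create(_["score"] = 0);
  const int NEG = -1000000000;
  const int gfirst = gap_open + gap_extend;

  // DP rows indexed by band offset k = j - i - dlo in [0, W)
  std::vector<int> Hprev(W + 2, 0), Hcur(W + 2, 0);
  std::vector<int> Eprev(W + 2, NEG), Ecur(W + 2, NEG);
  std::vector<int> Fprev(W + 2, NEG), Fcur(W + 2, NEG);
  // traceback: 2 bits for H (0 stop, 1 diag, 2 E, 3 F), 1 bit each for E/F extend
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0);

  int best = 0, bi = -1, bk = -1;

  // row i = 0 corresponds to zero query consumed: H = 0 everywhere (local)
  for (int i = 1; i <= m; ++i) {
    int qc = q[i - 1];
    for (int k = 0; k < W; ++k) {
      int j = i + dlo + k; // 1-based subject column
      int H = 0, E = NEG, F = NEG;
      unsigned char t = 0;
      if (j >= 1 && j <= n) {
        int sc = s[j - 1];
        // E: gap in query (consume subject), from (i, j-1) = Hcur[k-1]/Ecur[k-1]
        if (k >= 1) {
          int fromH = Hcur[k - 1] - gfirst;
          int fromE = Ecur[k - 1] - gap_extend;
          E = fromH >= fromE ? fromH : fromE;
          if (fromE > fromH) t |= 0x10; // E came from E (extend)
        }
        // F: gap in subject (consume query), from (i-1, j) = Hprev[k+1]/Fprev[k+1]
        if (k + 1 < W) {
          int fromH = Hprev[k + 1] - gfirst;
          int fromF = Fprev[k + 1] - gap_extend;
          F = fromH >= fromF ? fromH : fromF;
          if (fromF > fromH) t |= 0x20; // F came from F
        }
        // diagonal from (i-1, j-1) = Hprev[k]
        int diag = Hprev[k] + mat(qc, sc);
        H = 0; t &= 0x30;
        if (diag > H) { H = diag; t = (t & 0x30) | 1; }
        if (E > H) { H = E; t = (t & 0x30) | 2; }
        if (F > H) { H = F; t = (t & 0x30) | 3; }
        if (H > best) { best = H; bi = i; bk = k; }
      }
      Hcur[k] = H; Ecur[k] = E; Fcur[k] = F;
      tb[(size_t)i * W + k] = t;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback from (bi, bk)
  int i = bi, k = bk;
  int q_end = bi, s_end = bi + dlo + bk;
  int matches = 0, mismatches = 0, gap_openings = 0, gap_cols = 0, columns = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  int q_beg = q_end, s_beg = s_end;
  while (i > 0) {
    unsigned char t = tb[(size_t)i * W + k];
    int j = i + dlo + k;
    if (state == 0) {
      int dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1]) ++matches; else ++mismatches;
        q_beg = i; s_beg = j;
        --i; // k unchanged (diagonal keeps d)
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: gap in query, consumed subject col j
      ++columns; ++gap_cols;
      s_beg = j;
      bool ext = (t & 0x10) != 0;
      --k; // move to (i, j-1)
      if (!ext) { ++gap_openings; state = 0; }
    } else { // F: gap in subject, consumed query row i
      ++columns; ++gap_cols;
      q_beg = i;
      bool ext = (t & 0x20) != 0;
      --i; ++k; // move to (i-1, j)
      if (!ext) { ++gap_openings; state = 0; }
    }
    if (k < 0 || k >= W) break; // safety: band edge
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = q_beg, _["q_end"] = q_end,
    _["s_start"] = s_beg, _["s_end"] = s_end,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_openings"] = gap_openings, _["gap_columns"] = gap_cols,
    _["columns"] = columns);
}
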