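#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// A gap of length L costs gap_open + L * gap_extend (BLAST cost convention),
// so the first gapped position pays gap_open + gap_extend.
namespace {

struct SWResult {
  int score;
  int a_start, a_end;  // 0-based half-open on a
  int b_start, b_end;  // 0-based half-open on b
  int aligned_length;
  int matches;
};

const int NEG_INF = -1000000000;

SWResult smith_waterman(const std::string& a, const std::string& b,
                        int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  // M: ends in match/mismatch; X: gap in b (consume a); Y: gap in a (consume b)
  std::vector<std::vector<int>> M(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int>> X(n + 1, std::vector<int>(m + 1, NEG_INF));
  std::vector<std::vector<int>> Y(n + 1, std::vector<int>(m + 1, NEG_INF));
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int diag = H[i - 1][j - 1] + s;
      M[i][j] = diag;
      int xo = H[i - 1][j] - gap_open - gap_extend;
      int xe = (X[i - 1][j] == NEG_INF) ? NEG_INF : X[i - 1][j] - gap_extend;
      X[i][j] = std::max(xo, xe);
      int yo = H[i][j - 1] - gap_open - gap_extend;
      int ye = (Y[i][j - 1] == NEG_INF) ? NEG_INF : Y[i][j - 1] - gap_extend;
      Y[i][j] = std::max(yo, ye);
      int h = std::max(0, std::max(M[i][j], std::max(X[i][j], Y[i][j])));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SWResult r;
  r.score = best;
  r.a_end = bi; r.b_end = bj;
  r.aligned_length = 0; r.matches = 0;
  // traceback from (bi, bj)
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = X, 2 = Y
  while (i > 0 && j > 0 && H[i][j] > 0) {
    if (state == 0) {
      if (H[i][j] == M[i][j]) {
        r.aligned_length++;
        if (a[i - 1] == b[j - 1]) r.matches++;
        --i; --j;
        continue;
      } else if (H[i][j] == X[i][j]) {
        state = 1;
      } else {
        state = 2;
      }
    }
    if (state == 1) {
      // gap consuming a
      r.aligned_length++;
      if (X[i][j] == H[i - 1][j] - gap_open - gap_extend) state = 0;
      --i;
    } else if (state == 2) {
      r.aligned_length++;
      if (Y[i][j] == H[i][j - 1] - gap_open - gap_extend) state = 0;
      --j;
    }
  }
  r.a_start = i; r.b_start = j;
  return r;
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, int match, int mismatch,
                     int gap_open, int gap_extend) {
  SWResult r = smith_waterman(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(
    _["score"] = r.score,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end,
    _["aligned_length"] = r.aligned_length, _["matches"] = r.matches);
}

// Seed positions of exact word matches of `query` words in `subject` (one
// strand, as given). Returns for each seed the query offset and subject
// offset (0-based). Words containing non-ACGT characters are skipped.
// [[Rcpp::export]]
List cpp_find_seeds(std::string query, std::string subject, int word_size) {
  std::vector<int> qpos, spos;
  const int n = (int)query.size(), m = (int)subject.size();
  if (n >= word_size && m >= word_size) {
    // index subject words in a hash map
    std::unordered_multimap<std::string, int> idx;
    for (int j = 0; j + word_size <= m; ++j) {
      std::string w = subject.substr(j, word_size);
      if (w.find_first_not_of("ACGT") != std::string::npos) continue;
      idx.insert({w, j});
    }
    for (int i = 0; i + word_size <= n; ++i) {
      std::string w = query.substr(i, word_size);
      if (w.find_first_not_of("ACGT") != std::string::npos) continue;
      auto range = idx.equal_range(w);
      for (auto it = range.first; it != range.second; ++it) {
        qpos.push_back(i);
        spos.push_back(it->second);
      }
    }
  }
  return List::create(_["qpos"] = wrap(qpos), _["spos"] = wrap(spos));
}

// Seed-and-extend search of `query` against one strand of `subject`.
// Seeds are grouped by diagonal; for each seeded diagonal a banded local
// alignment of the full query against a subject window centred on the
// diagonal is computed, and overlapping hits are merged keeping the best
// score. Returns hits with subject coordinates on the given strand.
// [[Rcpp::export]]
DataFrame cpp_seed_extend_strand(std::string query, std::string subject,
                                 int word_size, int match, int mismatch,
                                 int gap_open, int gap_extend, int band,
                                 int min_score) {
  const int n = (int)query.size(), m = (int)subject.size();
  List seeds = cpp_find_seeds(query, subject, word_size);
  IntegerVector qpos = seeds["qpos"], spos = seeds["spos"];
  // unique diagonals (binned by band to limit repeated work)
  std::vector<int> diags;
  for (int k = 0; k < qpos.size(); ++k) diags.push_back(spos[k] - qpos[k]);
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  // bin diagonals: one extension per band-wide bin
  std::vector<int> bins;
  int last_bin = NEG_INF;
  for (int d : diags) {
    if (last_bin == NEG_INF || d > last_bin + band) {
      bins.push_back(d);
      last_bin = d;
    }
  }
  struct Hit { int s_start, s_end, q_start, q_end, score, alen, matches; };
  std::vector<Hit> hits;
  for (int d : bins) {
    int w_start = std::max(0, d - band);
    int w_end = std::min(m, d + n + band);
    if (w_end - w_start < word_size) continue;
    std::string window = subject.substr(w_start, w_end - w_start);
    SWResult r = smith_waterman(query, window, match, mismatch, gap_open,
                                gap_extend);
    if (r.score < min_score) continue;
    Hit h;
    h.s_start = w_start + r.b_start;
    h.s_end = w_start + r.b_end;
    h.q_start = r.a_start;
    h.q_end = r.a_end;
    h.score = r.score;
    h.alen = r.aligned_length;
    h.matches = r.matches;
    hits.push_back(h);
  }
  // merge overlapping hits, keep max score (ties: leftmost subject start)
  std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
    if (x.score != y.score) return x.score > y.score;
    return x.s_start < y.s_start;
  });
  std::vector<Hit> kept;
  for (const auto& h : hits) {
    bool overlaps = false;
    for (const auto& k : kept) {
      if (h.s_start < k.s_end && k.s_start < h.s_end) { overlaps = true; break; }
    }
    if (!overlaps) kept.push_back(h);
  }
  int nk = (int)kept.size();
  IntegerVector ss(nk), se(nk), qs(nk), qe(nk), sc(nk), al(nk), mt(nk);
  for (int k = 0; k < nk; ++k) {
    ss[k] = kept[k].s_start; se[k] = kept[k].s_end;
    qs[k] = kept[k].q_start; qe[k] = kept[k].q_end;
    sc[k] = kept[k].score; al[k] = kept[k].alen; mt[k] = kept[k].matches;
  }
  return DataFrame::create(
    _["s_start"] = ss, _["s_end"] = se, _["q_start"] = qs, _["q_end"] = qe,
    _["raw_score"] = sc, _["aligned_length"] = al, _["matches"] = mt);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
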