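#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Protein local alignment machinery shared by the exhaustive Smith-Waterman
// oracle and the seeded (k-mer + banded DP) search engine.
//
// Conventions:
//  - scores are integers from a symmetric substitution matrix with single
//    letter dimnames; characters absent from the matrix are scored as 'X';
//  - affine gaps: a gap of length g costs gap_open + g * gap_extend
//    (so the first gap character costs gap_open + gap_extend);
//  - traceback tie-break: diagonal > up (gap in subject) > left (gap in
//    query); among equal-score end cells the one reached first in
//    (subject, query) scan order wins, which yields the smallest subject
//    coordinates.

static const int NEG_INF = -1000000000;

struct Scoring {
  int n;                       // alphabet size
  std::vector<int> mat;        // n x n scores
  int lookup[256];             // char -> alphabet index
  int score(int a, int b) const { return mat[a * n + b]; }
};

static Scoring make_scoring(const IntegerMatrix& m) {
  Scoring sc;
  sc.n = m.nrow();
  sc.mat.resize(sc.n * sc.n);
  for (int i = 0; i < sc.n; ++i)
    for (int j = 0; j < sc.n; ++j)
      sc.mat[i * sc.n + j] = m(i, j);
  List dn = m.attr("dimnames");
  CharacterVector letters = dn[0];
  int xi = 0;
  for (int i = 0; i < sc.n; ++i) {
    std::string l = as<std::string>(letters[i]);
    if (l == "X") xi = i;
  }
  for (int c = 0; c < 256; ++c) sc.lookup[c] = xi;
  for (int i = 0; i < sc.n; ++i) {
    std::string l = as<std::string>(letters[i]);
    if (l.size() == 1) sc.lookup[(unsigned char)l[0]] = i;
  }
  return sc;
}

static std::vector<int> encode(const std::string& s, const Scoring& sc) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = sc.lookup[(unsigned char)s[i]];
  return v;
}

// traceback codes packed per cell: bits 0-1 H-source (0 stop, 1 diag, 2 up,
// 3 left), bit 2 up-gap extended, bit 3 left-gap extended
struct Aln {
  int score, qstart, qend, sstart, send, nident, length;
  std::string qaln, saln;
};

// Full Smith-Waterman with traceback. q rows, s columns, 1-based DP.
static Aln sw_full(const std::string& qs, const std::string& ss,
                   const Scoring& sc, int go, int ge) {
  int m = (int)qs.size(), n = (int)ss.size();
  Aln out{0, 0, 0, 0, 0, 0, 0, "", ""};
  if (m == 0 || n == 0) return out;
  std::vector<int> q = encode(qs, sc), s = encode(ss, sc);
  // rolling score rows + full byte traceback matrix
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG_INF), Ecur(n + 1, NEG_INF); // up-gap
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Fleft = NEG_INF; // left-gap, rolls along j within row i
    Hcur[0] = 0; Ecur[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      unsigned char t = 0;
      int up_open = Hprev[j] - go - ge;
      int up_ext = Eprev[j] - ge;
      int up = up_open >= up_ext ? up_open : up_ext;
      if (up_ext > up_open) t |= 4;
      int left_open = Hcur[j - 1] - go - ge;
      int left_ext = Fleft - ge;
      int left = left_open >= left_ext ? left_open : left_ext;
      if (left_ext > left_open) t |= 8;
      int diag = Hprev[j - 1] + sc.score(q[i - 1], s[j - 1]);
      int h = 0; int src = 0;
      if (diag >= h && diag >= up && diag >= left) { h = diag; src = 1; }
      else if (up >= h && up >= left) { h = up; src = 2; }
      else if (left >= h) { h = left; src = 3; }
      if (h <= 0) { h = 0; src = 0; }
      t |= src;
      tb[(size_t)i * (n + 1) + j] = t;
      Hcur[j] = h; Ecur[j] = up; Fleft = left;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best <= 0) return out;
  // traceback from (bi, bj)
  std::string qa, sa;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    int src = t & 3;
    if (src == 0) break;
    if (src == 1) { qa.push_back(qs[i - 1]); sa.push_back(ss[j - 1]); --i; --j; }
    else if (src == 2) { // up: gap in subject
      // walk the gap: extended bit tells whether the gap continues
      while (true) {
        qa.push_back(qs[i - 1]); sa.push_back('-');
        bool ext = (tb[(size_t)i * (n + 1) + j] & 4) != 0;
        --i;
        if (!ext) break;
      }
    } else { // left: gap in query
      while (true) {
        qa.push_back('-'); sa.push_back(ss[j - 1]);
        bool ext = (tb[(size_t)i * (n + 1) + j] & 8) != 0;
        --j;
        if (!ext) break;
      }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  out.score = best;
  out.qstart = i + 1; out.qend = bi;
  out.sstart = j + 1; out.send = bj;
  out.qaln = qa; out.saln = sa;
  out.length = (int)qa.size();
  int id = 0;
  for (size_t k = 0; k < qa.size(); ++k)
    if (qa[k] != '-' && qa[k] == sa[k]) ++id;
  out.nident = id;
  return out;
}

// [[Rcpp::export]]
List sw_protein_cpp(std::string q, std::string s, IntegerMatrix mat,
                    int gap_open, int gap_extend) {
  Scoring sc = make_scoring(mat);
  Aln a = sw_full(q, s, sc, gap_open, gap_extend);
  return List::create(
    _["score"] = a.score, _["qstart"] = a.qstart, _["qend"] = a.qend,
    _["sstart"] = a.sstart, _["send"] = a.send, _["q_aln"] = a.qaln,
    _["s_aln"] = a.saln, _["nident"] = a.nident, _["length"] = a.length);
}

// Banded local alignment around diagonal d (d = spos - qpos, 0-based).
// Query rows 1..m in full; subject columns limited to |(j - i) - d| <= band.
static Aln sw_banded(const std::vector<int>& q, const std::vector<int>& s,
                     const std::string& qs, const std::string& ss,
                     const Scoring& sc, int go, int ge, int d, int band) {
  int m = (int)q.size(), n = (int)s.size();
  int width = 2 * band + 1;
  Aln out{0, 0, 0, 0, 0, 0, 0, "", ""};
  std::vector<int> Hprev(width + 2, 0), Hcur(width + 2, 0);
  std::vector<int> Eprev(width + 2, NEG_INF), Ecur(width + 2, NEG_INF);
  std::vector<unsigned char> tb((size_t)(m + 1) * width, 0);
  // column j for row i at band offset b (0..width-1): j = i + d - band + b
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Fleft = NEG_INF;
    for (int b = 0; b < width; ++b) {
      int j = i + d - band + b;
      Hcur[b + 1] = 0; Ecur[b + 1] = NEG_INF;
      if (j < 1 || j > n) { Fleft = NEG_INF; continue; }
      // neighbours: diag = (i-1, j-1) -> prev row same b; up = (i-1, j) ->
      // prev row b+1; left = (i, j-1) -> cur row b-1
      int Hdiag = (j - 1 >= 1 || j - 1 == 0) ? Hprev[b + 1] : 0;
      if (j - 1 == 0) Hdiag = 0; // left edge of matrix
      int up_prev_H = (b + 2 <= width) ? Hprev[b + 2] : NEG_INF;
      int up_prev_E = (b + 2 <= width) ? Eprev[b + 2] : NEG_INF;
      int left_H = (b >= 1) ? Hcur[b] : ((j - 1 == 0) ? 0 : NEG_INF);
      unsigned char t = 0;
      int up_open = up_prev_H == NEG_INF ? NEG_INF : up_prev_H - go - ge;
      int up_ext = up_prev_E == NEG_INF ? NEG_INF : up_prev_E - ge;
      int up = up_open >= up_ext ? up_open : up_ext;
      if (up_ext > up_open) t |= 4;
      int left_open = left_H == NEG_INF ? NEG_INF : left_H - go - ge;
      int left_ext = Fleft == NEG_INF ? NEG_INF : Fleft - ge;
      int left = left_open >= left_ext ? left_open : left_ext;
      if (left_ext > left_open) t |= 8;
      int diag = Hdiag + sc.score(q[i - 1], s[j - 1]);
      int h = 0; int src = 0;
      if (diag >= h && diag >= up && diag >= left) { h = diag; src = 1; }
      else if (up >= h && up >= left) { h = up; src = 2; }
      else if (left >= h) { h = left; src = 3; }
      if (h <= 0) { h = 0; src = 0; }
      t |= src;
      tb[(size_t)(i - 1) * width + b] = t;
      Hcur[b + 1] = h; Ecur[b + 1] = up; Fleft = left;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best <= 0) return out;
  std::string qa, sa;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    int b = j - (i + d - band);
    if (b < 0 || b >= width) break;
    unsigned char t = tb[(size_t)(i - 1) * width + b];
    int src = t & 3;
    if (src == 0) break;
    if (src == 1) { qa.push_back(qs[i - 1]); sa.push_back(ss[j - 1]); --i; --j; }
    else if (src == 2) {
      while (true) {
        int bb = j - (i + d - band);
        bool ext = (tb[(size_t)(i - 1) * width + bb] & 4) != 0;
        qa.push_back(qs[i - 1]); sa.push_back('-');
        --i;
        if (!ext) break;
      }
    } else {
      while (true) {
        int bb = j - (i + d - band);
        bool ext = (tb[(size_t)(i - 1) * width + bb] & 8) != 0;
        qa.push_back('-'); sa.push_back(ss[j - 1]);
        --j;
        if (!ext) break;
      }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  out.score = best;
  out.qstart = i + 1; out.qend = bi;
  out.sstart = j + 1; out.send = bj;
  out.qaln = qa; out.saln = sa;
  out.length = (int)qa.size();
  int id = 0;
  for (size_t k = 0; k < qa.size(); ++k)
    if (qa[k] != '-' && qa[k] == sa[k]) ++id;
  out.nident = id;
  return out;
}

// Ungapped X-drop extension around a k-mer seed; returns best HSP score.
static int xdrop_ungapped(const std::vector<int>& q, const std::vector<int>& s,
                          const Scoring& sc, int qp, int sp, int k, int xdrop,
                          int* send_out) {
  int m = (int)q.size(), n = (int)s.size();
  int score = 0;
  for (int t = 0; t < k; ++t) score += sc.score(q[qp + t], s[sp + t]);
  // right extension
  int cur = score, best = score;
  int qi = qp + k, si = sp + k, best_send = sp + k;
  while (qi < m && si < n) {
    cur += sc.score(q[qi], s[si]);
    if (cur > best) { best = cur; best_send = si + 1; }
    if (best - cur > xdrop) break;
    ++qi; ++si;
  }
  // left extension
  cur = best;
  int b2 = best;
  qi = qp - 1; si = sp - 1;
  while (qi >= 0 && si >= 0) {
    cur += sc.score(q[qi], s[si]);
    if (cur > b2) b2 = cur;
    if (b2 - cur > xdrop) break;
    --qi; --si;
  }
  if (send_out) *send_out = best_send;
  return b2;
}

// [[Rcpp::export]]
DataFrame seeded_frame_search_cpp(std::string qs, std::string ss,
                                  IntegerMatrix mat, int gap_open,
                                  int gap_extend, int k, int xdrop, int band,
                                  int trigger) {
  Scoring sc = make_scoring(mat);
  std::vector<int> q = encode(qs, sc), s = encode(ss, sc);
  int m = (int)q.size(), n = (int)s.size();
  std::vector<Aln> hits;
  std::vector<int> hit_diag;
  if (m >= k && n >= k) {
    // index query k-mers
    std::unordered_map<uint64_t, std::vector<int> > idx;
    uint64_t base = (uint64_t)sc.n;
    for (int i = 0; i + k <= m; ++i) {
      uint64_t key = 0;
      for (int t = 0; t < k; ++t) key = key * base + (uint64_t)q[i + t];
      idx[key].push_back(i);
    }
    std::unordered_map<int, int> diag_seen; // diagonal -> furthest s end extended
    for (int p = 0; p + k <= n; ++p) {
      uint64_t key = 0;
      for (int t = 0; t < k; ++t) key = key * base + (uint64_t)s[p + t];
      auto it = idx.find(key);
      if (it == idx.end()) continue;
      for (int qp : it->second) {
        int d = p - qp;
        auto ds = diag_seen.find(d);
        if (ds != diag_seen.end() && p < ds->second) continue;
        // inside an already-found alignment on a near diagonal?
        bool covered = false;
        for (size_t h = 0; h < hits.size(); ++h) {
          if (qp + 1 >= hits[h].qstart && qp + k <= hits[h].qend &&
              p + 1 >= hits[h].sstart && p + k <= hits[h].send &&
              std::abs(d - hit_diag[h]) <= band) { covered = true; break; }
        }
        if (covered) continue;
        int send = p + k;
        int ung = xdrop_ungapped(q, s, sc, qp, p, k, xdrop, &send);
        diag_seen[d] = send;
        if (ung < trigger) continue;
        Aln a = sw_banded(q, s, qs, ss, sc, gap_open, gap_extend, d, band);
        if (a.score <= 0) continue;
        // dedup: drop if contained in an existing hit with >= score; replace
        // contained existing hits with <= score
        bool skip = false;
        for (size_t h = 0; h < hits.size() && !skip; ++h) {
          if (a.qstart >= hits[h].qstart && a.qend <= hits[h].qend &&
              a.sstart >= hits[h].sstart && a.send <= hits[h].send &&
              hits[h].score >= a.score) skip = true;
        }
        if (skip) continue;
        std::vector<Aln> kept; std::vector<int> kept_d;
        for (size_t h = 0; h < hits.size(); ++h) {
          bool contained = hits[h].qstart >= a.qstart && hits[h].qend <= a.qend &&
                           hits[h].sstart >= a.sstart && hits[h].send <= a.send &&
                           hits[h].score <= a.score;
          if (!contained) { kept.push_back(hits[h]); kept_d.push_back(hit_diag[h]); }
        }
        kept.push_back(a); kept_d.push_back(d);
        hits.swap(kept); hit_diag.swap(kept_d);
      }
    }
  }
  int nh = (int)hits.size();
  IntegerVector score(nh), qstart(nh), qend(nh), sstart(nh), send(nh),
      nident(nh), length(nh);
  CharacterVector qaln(nh), saln(nh);
  for (int h = 0; h < nh; ++h) {
    score[h] = hits[h].score; qstart[h] = hits[h].qstart;
    qend[h] = hits[h].qend; sstart[h] = hits[h].sstart;
    send[h] = hits[h].send; nident[h] = hits[h].nident;
    length[h] = hits[h].length; qaln[h] = hits[h].qaln; saln[h] = hits[h].saln;
  }
  return DataFrame::create(
    _["raw_score"] = score, _["query_start"] = qstart, _["query_end"] = qend,
    _["subject_aa_start"] = sstart, _["subject_aa_end"] = send,
    _["n_ident"] = nident, _["align_length"] = length, _["q_aln"] = qaln,
    _["s_aln"] = saln, _["stringsAsFactors"] = false);
}
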