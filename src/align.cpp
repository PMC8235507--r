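#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Local alignment engine: affine-gap Smith-Waterman (Gotoh) with a banded
// traceback matrix. The band is expressed on the diagonal offset d = j - i
// (query row i, target column j, both 1-based inside the DP); a full-matrix
// alignment is the special case band = [1-n, m-1]. Alignments are split into
// gap-free-ish blocks at any single gap run of length >= split_gap, so a
// long internal deletion yields two collinear segments rather than one
// bridged alignment.
//
// Coordinates returned to R are 0-based half-open on both sequences.

static const int NEG_INF = -1000000000;

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N: never matches
  }
}

struct Block {
  int qs, qe, ts, te, matches, cols, score;
};

struct Hit {
  int score = NEG_INF;          // total best-path score (tie-break unit)
  int qs = 0, qe = 0, ts = 0, te = 0;
  std::vector<Block> blocks;
  bool found = false;
};

static inline int hit_span(const Hit& h) { return (h.qe - h.qs) + (h.te - h.ts); }

static inline bool better_hit(const Hit& a, const Hit& b) {
  // total order: score desc, span desc, target start asc
  if (a.score != b.score) return a.score > b.score;
  if (hit_span(a) != hit_span(b)) return hit_span(a) > hit_span(b);
  return a.ts < b.ts;
}

// ops: 0 = diagonal, 1 = gap consuming target (E), 2 = gap consuming query (F)
static void ops_to_blocks(const std::vector<uint8_t>& ops,
                          const std::vector<int>& q, const std::vector<int>& t,
                          int qi, int tj, int match, int mismatch,
                          int gap_open, int gap_ext, int split_gap,
                          std::vector<Block>& out) {
  Block cur{qi, qi, tj, tj, 0, 0, 0};
  size_t k = 0;
  const size_t K = ops.size();
  while (k < K) {
    if (ops[k] == 0) {
      bool is_m = (q[qi] >= 0 && q[qi] == t[tj]);
      cur.matches += is_m ? 1 : 0;
      cur.score += is_m ? match : mismatch;
      cur.cols += 1;
      ++qi; ++tj; ++k;
    } else {
      uint8_t op = ops[k];
      size_t run = 0;
      while (k + run < K && ops[k + run] == op) ++run;
      if ((int)run >= split_gap) {
        // close current block, skip the gap, open a new block
        cur.qe = qi; cur.te = tj;
        if (cur.cols > 0) out.push_back(cur);
        if (op == 1) tj += (int)run; else qi += (int)run;
        cur = Block{qi, qi, tj, tj, 0, 0, 0};
      } else {
        cur.score += gap_open + (int)run * gap_ext;
        cur.cols += (int)run;
        if (op == 1) tj += (int)run; else qi += (int)run;
      }
      k += run;
    }
  }
  cur.qe = qi; cur.te = tj;
  if (cur.cols > 0) out.push_back(cur);
}

static Hit band_align(const std::vector<int>& q, const std::vector<int>& t,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int dlo, int dhi, int split_gap) {
  const int n = (int)q.size(), m = (int)t.size();
  Hit best;
  if (n == 0 || m == 0) return best;
  dlo = std::max(dlo, 1 - n);
  dhi = std::min(dhi, m - 1);
  if (dlo > dhi) return best;
  const int W = dhi - dlo + 1;

  // traceback byte per in-band cell: bits 0-1 H source (0 stop, 1 diag,
  // 2 from F, 3 from E); bit 2 E extends E; bit 3 F extends F
  std::vector<uint8_t> tb((size_t)n * W, 0);
  std::vector<int> Hprev(m + 2, 0), Hcur(m + 2, 0);
  std::vector<int> Fprev(m + 2, NEG_INF), Fcur(m + 2, NEG_INF);

  int bscore = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i + dlo), jhi = std::min(m, i + dhi);
    if (jlo > jhi) continue;
    int E = NEG_INF;
    const int qi = q[i - 1];
    uint8_t* tbrow = &tb[(size_t)(i - 1) * W];
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t byte = 0;
      // E: gap consuming target (left); invalid at the band's left edge
      int e_open = (j - 1 >= jlo) ? Hcur[j - 1] + gap_open + gap_ext : NEG_INF;
      int e_ext = (j - 1 >= jlo) ? E + gap_ext : NEG_INF;
      if (e_ext > e_open) { E = e_ext; byte |= 4; } else { E = e_open; }
      // F: gap consuming query (up); row i-1 band is [i-1+dlo, i-1+dhi]
      bool up_ok = (i - 1 >= 1) && (j >= i - 1 + dlo) && (j <= i - 1 + dhi);
      int f_open = up_ok ? Hprev[j] + gap_open + gap_ext : NEG_INF;
      int f_ext = up_ok ? Fprev[j] + gap_ext : NEG_INF;
      int F;
      if (f_ext > f_open) { F = f_ext; byte |= 8; } else { F = f_open; }
      Fcur[j] = F;
      // H
      int s = (qi >= 0 && qi == t[j - 1]) ? match : mismatch;
      int diag = (i - 1 == 0 || j - 1 == 0) ? s : Hprev[j - 1] + s;
      int H = 0; uint8_t hd = 0;
      if (diag > H) { H = diag; hd = 1; }
      if (F > H) { H = F; hd = 2; }
      if (E > H) { H = E; hd = 3; }
      Hcur[j] = H;
      tbrow[j - i - dlo] = byte | hd;
      if (H > bscore) { bscore = H; bi = i; bj = j; }
    }
    // keep cells just outside next row's reach from leaking stale values
    if (jlo - 1 >= 0) Hcur[jlo - 1] = 0;
    if (jhi + 1 <= m + 1) { Hcur[jhi + 1] = 0; Fcur[jhi + 1] = NEG_INF; }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  if (bi < 0 || bscore <= 0) return best;

  // traceback: collect ops backwards, then build blocks forwards
  std::vector<uint8_t> ops;
  int i = bi, j = bj, state = 0;  // 0=H,1=E,2=F
  while (i >= 1 && j >= 1 && j >= i + dlo && j <= i + dhi) {
    uint8_t byte = tb[(size_t)(i - 1) * W + (j - i - dlo)];
    if (state == 0) {
      int hd = byte & 3;
      if (hd == 0) break;
      if (hd == 1) { ops.push_back(0); --i; --j; }
      else if (hd == 2) state = 2;
      else state = 1;
    } else if (state == 1) {  // E: consume target
      ops.push_back(1);
      state = (byte & 4) ? 1 : 0;
      --j;
    } else {  // F: consume query
      ops.push_back(2);
      state = (byte & 8) ? 2 : 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  best.score = bscore;
  best.qs = i; best.qe = bi;
  best.ts = j; best.te = bj;
  ops_to_blocks(ops, q, t, i, j, match, mismatch, gap_open, gap_ext,
                split_gap, best.blocks);
  best.found = !best.blocks.empty();
  return best;
}

// score-only full-matrix local alignment (no traceback, no band): used to
// prescreen seedless queries before paying for a traceback matrix
static int best_score_only(const std::vector<int>& q, const std::vector<int>& t,
                           int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Frow(m + 1, NEG_INF);
  int bscore = 0;
  for (int i = 1; i <= n; ++i) {
    int E = NEG_INF;
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] + gap_open + gap_ext, E + gap_ext);
      int F = std::max(Hprev[j] + gap_open + gap_ext, Frow[j] + gap_ext);
      Frow[j] = F;
      int s = (qi >= 0 && qi == t[j - 1]) ? match : mismatch;
      int H = std::max(0, Hprev[j - 1] + s);
      H = std::max(H, std::max(E, F));
      Hcur[j] = H;
      if (H > bscore) bscore = H;
    }
    std::swap(Hprev, Hcur);
  }
  return bscore;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

// diagonals (t_pos - q_pos) carrying exact k-mer matches, sorted unique
static std::vector<int> seed_diagonals(const std::vector<int>& q,
                                       const std::vector<int>& t, int k) {
  std::vector<int> diags;
  const int n = (int)q.size(), m = (int)t.size();
  if (n < k || m < k) return diags;
  const uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  std::unordered_map<uint32_t, std::vector<int>> idx;
  idx.reserve(m * 2);
  uint32_t h = 0; int run = 0;
  for (int j = 0; j < m; ++j) {
    if (t[j] < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)t[j]) & mask;
    if (++run >= k) idx[h].push_back(j - k + 1);
  }
  h = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    if (q[i] < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)q[i]) & mask;
    if (++run >= k) {
      auto it = idx.find(h);
      if (it != idx.end()) {
        int qp = i - k + 1;
        for (int tp : it->second) diags.push_back(tp - qp);
      }
    }
  }
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  return diags;
}

// best hit of one (already oriented) query against the target
static Hit strand_hit(const std::vector<int>& q, const std::vector<int>& t,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int kmer, int band_pad, int split_gap, bool force_full,
                      int score_floor) {
  const int n = (int)q.size(), m = (int)t.size();
  Hit best;
  if (n == 0 || m == 0) return best;

  // fast path: exact substring (leftmost occurrence == smallest ts tie-break)
  bool has_n = std::find(q.begin(), q.end(), -1) != q.end();
  if (!force_full && n <= m && !has_n) {
    auto pos = std::search(t.begin(), t.end(), q.begin(), q.end());
    if (pos != t.end()) {
      int ts = (int)(pos - t.begin());
      best.score = n * match;
      best.qs = 0; best.qe = n; best.ts = ts; best.te = ts + n;
      best.blocks.push_back(Block{0, n, ts, ts + n, n, n, n * match});
      best.found = true;
      return best;
    }
  }

  if (force_full || n < kmer) {
    return band_align(q, t, match, mismatch, gap_open, gap_ext, 1 - n, m - 1,
                      split_gap);
  }
  std::vector<int> diags = seed_diagonals(q, t, kmer);
  if (diags.empty()) {
    if (score_floor > 0 &&
        best_score_only(q, t, match, mismatch, gap_open, gap_ext) < score_floor) {
      return best;  // nothing reportable can be in here
    }
    return band_align(q, t, match, mismatch, gap_open, gap_ext, 1 - n, m - 1,
                      split_gap);
  }
  // cluster nearby diagonals; one banded DP per cluster
  size_t start = 0;
  for (size_t e = 1; e <= diags.size(); ++e) {
    if (e == diags.size() || diags[e] - diags[e - 1] > 100) {
      int dmin = diags[start], dmax = diags[e - 1];
      Hit h = band_align(q, t, match, mismatch, gap_open, gap_ext,
                         dmin - band_pad, dmax + band_pad, split_gap);
      if (h.found && (!best.found || better_hit(h, best))) best = h;
      start = e;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_local_align(std::string query, std::string target, int match,
                     int mismatch, int gap_open, int gap_ext, int kmer,
                     int band_pad, int split_gap, bool force_full,
                     int score_floor) {
  std::vector<int> q = encode(query), t = encode(target);
  const int n = (int)q.size();
  std::vector<int> qrc(n);
  for (int i = 0; i < n; ++i) {
    int b = q[n - 1 - i];
    qrc[i] = (b >= 0) ? 3 - b : -1;
  }
  Hit hp = strand_hit(q, t, match, mismatch, gap_open, gap_ext, kmer,
                      band_pad, split_gap, force_full, score_floor);
  Hit hm = strand_hit(qrc, t, match, mismatch, gap_open, gap_ext, kmer,
                      band_pad, split_gap, force_full, score_floor);
  if (hm.found) {
    // map minus-strand coordinates back to the original read frame
    int tmp = hm.qs; hm.qs = n - hm.qe; hm.qe = n - tmp;
    for (Block& b : hm.blocks) {
      tmp = b.qs; b.qs = n - b.qe; b.qe = n - tmp;
    }
    std::reverse(hm.blocks.begin(), hm.blocks.end());
  }
  bool minus;
  if (hp.found && hm.found) minus = better_hit(hm, hp);  // tie keeps plus
  else minus = hm.found;
  const Hit& best = minus ? hm : hp;

  const int nb = (int)best.blocks.size();
  IntegerVector bqs(nb), bqe(nb), bts(nb), bte(nb), bm(nb), bc(nb), bs(nb);
  for (int b = 0; b < nb; ++b) {
    const Block& blk = best.blocks[b];
    bqs[b] = blk.qs; bqe[b] = blk.qe; bts[b] = blk.ts; bte[b] = blk.te;
    bm[b] = blk.matches; bc[b] = blk.cols; bs[b] = blk.score;
  }
  return List::create(
      _["found"] = best.found, _["strand"] = minus ? "-" : "+",
      _["score"] = best.score,
      _["read_start"] = best.qs, _["read_end"] = best.qe,
      _["ref_start"] = best.ts, _["ref_end"] = best.te,
      _["block_read_start"] = bqs, _["block_read_end"] = bqe,
      _["block_ref_start"] = bts, _["block_ref_end"] = bte,
      _["block_matches"] = bm, _["block_columns"] = bc,
      _["block_score"] = bs);
}
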