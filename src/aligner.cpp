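// Seed-and-extend local similarity search used by search_segments() and
// assign_family_80_80(). Ungapped x-drop extension from exact k-mer seeds:
// adequate for the substitution-level divergence the annotation stage must
// tolerate (indel-rich homology is delegated to the external-aligner adapter).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N / ambiguity: breaks seeds, never matches
  }
}

static std::vector<int8_t> encode_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) encode_base(s[i]);
  return v;
}

static std::vector<int8_t> revcomp_enc(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (int8_t)(3 - b) : (int8_t)4;
  }
  return r;
}

struct Extension { int q0, q1, t0, t1, matches; };

// Ungapped x-drop extension around a seed [qpos, qpos+k) / [tpos, tpos+k).
// Match +1, mismatch -1; stops when score drops `xdrop` below the running max.
// Endpoints are the last positions attaining the maximal score.
static Extension extend_seed(const std::vector<int8_t>& q,
                             const std::vector<int8_t>& t,
                             int qpos, int tpos, int k, int xdrop) {
  Extension e;
  e.q0 = qpos; e.q1 = qpos + k - 1;
  e.t0 = tpos; e.t1 = tpos + k - 1;
  e.matches = k;

  // right extension
  {
    int score = 0, best = 0, m = 0, best_m = 0, best_i = -1;
    int qi = qpos + k, ti = tpos + k, i = 0;
    while (qi < (int)q.size() && ti < (int)t.size()) {
      bool match = (q[qi] < 4) && (q[qi] == t[ti]);
      score += match ? 1 : -1;
      if (match) ++m;
      if (score > best) { best = score; best_m = m; best_i = i; }
      if (best - score > xdrop) break;
      ++qi; ++ti; ++i;
    }
    if (best_i >= 0) {
      e.q1 = qpos + k + best_i;
      e.t1 = tpos + k + best_i;
      e.matches += best_m;
    }
  }
  // left extension
  {
    int score = 0, best = 0, m = 0, best_m = 0, best_i = -1;
    int qi = qpos - 1, ti = tpos - 1, i = 0;
    while (qi >= 0 && ti >= 0) {
      bool match = (q[qi] < 4) && (q[qi] == t[ti]);
      score += match ? 1 : -1;
      if (match) ++m;
      if (score > best) { best = score; best_m = m; best_i = i; }
      if (best - score > xdrop) break;
      --qi; --ti; ++i;
    }
    if (best_i >= 0) {
      e.q0 = qpos - 1 - best_i;
      e.t0 = tpos - 1 - best_i;
      e.matches += best_m;
    }
  }
  return e;
}

// [[Rcpp::export]]
DataFrame cpp_search_segments(CharacterVector seg_seqs,
                              CharacterVector lib_seqs,
                              int k = 11,
                              double min_identity = 80.0,
                              int min_len = 50,
                              int xdrop = 15) {
  const int nlib = lib_seqs.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // targets: forward then reverse-complement of every library entry
  std::vector<std::vector<int8_t>> targets;
  targets.reserve(2 * nlib);
  std::vector<int> tgt_lib(2 * nlib);
  std::vector<bool> tgt_rc(2 * nlib);
  for (int i = 0; i < nlib; ++i) {
    std::vector<int8_t> f = encode_seq(as<std::string>(lib_seqs[i]));
    targets.push_back(f);
    targets.push_back(revcomp_enc(f));
    tgt_lib[2 * i] = i;     tgt_rc[2 * i] = false;
    tgt_lib[2 * i + 1] = i; tgt_rc[2 * i + 1] = true;
  }

  // k-mer index over all targets
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> index;
  for (int t = 0; t < (int)targets.size(); ++t) {
    const std::vector<int8_t>& s = targets[t];
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      if (s[i] >= 4) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)s[i]) & mask;
      if (++run >= k) index[h].emplace_back(t, i - k + 1);
    }
  }

  std::vector<int> out_seg, out_lib, out_qs, out_qe, out_ss, out_se, out_len, out_mat;
  std::vector<double> out_id;
  std::vector<std::string> out_strand;

  for (int si = 0; si < seg_seqs.size(); ++si) {
    std::vector<int8_t> q = encode_seq(as<std::string>(seg_seqs[si]));
    if ((int)q.size() < k) continue;
    // regions of the segment already explained, per target
    std::unordered_map<int, std::vector<std::pair<int, int>>> covered;

    uint64_t h = 0; int run = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      if (q[i] >= 4) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)q[i]) & mask;
      if (++run < k) continue;
      int qpos = i - k + 1;
      auto it = index.find(h);
      if (it == index.end()) continue;
      for (const auto& seed : it->second) {
        int t = seed.first, tpos = seed.second;
        bool skip = false;
        auto cv = covered.find(t);
        if (cv != covered.end()) {
          for (const auto& iv : cv->second)
            if (qpos >= iv.first && qpos <= iv.second) { skip = true; break; }
        }
        if (skip) continue;
        Extension e = extend_seed(q, targets[t], qpos, tpos, k, xdrop);
        int len = e.q1 - e.q0 + 1;
        double ident = 100.0 * e.matches / len;
        covered[t].emplace_back(e.q0, e.q1);
        if (len < min_len || ident < min_identity) continue;
        int L = (int)targets[t].size();
        int ss, se;
        if (!tgt_rc[t]) { ss = e.t0 + 1; se = e.t1 + 1; }
        else { ss = L - e.t1; se = L - e.t0; } // map back to forward consensus
        out_seg.push_back(si + 1);
        out_lib.push_back(tgt_lib[t] + 1);
        out_strand.push_back(tgt_rc[t] ? "-" : "+");
        out_qs.push_back(e.q0 + 1);
        out_qe.push_back(e.q1 + 1);
        out_ss.push_back(ss);
        out_se.push_back(se);
        out_len.push_back(len);
        out_mat.push_back(e.matches);
        out_id.push_back(ident);
      }
    }
  }

  return DataFrame::create(
    _["seg"] = out_seg, _["lib"] = out_lib, _["strand"] = out_strand,
    _["qstart"] = out_qs, _["qend"] = out_qe,
    _["sstart"] = out_ss, _["send"] = out_se,
    _["length"] = out_len, _["matches"] = out_mat, _["identity"] = out_id,
    _["stringsAsFactors"] = false);
}

// Best ungapped local correspondence between two sequences, used by the
// 80/80 family rule. Seeds vote for diagonals; on the best diagonal the
// maximum-scoring run (match +1 / mismatch -1) is located exactly.
// Returns identity over that run, its length, and the orientation.
// [[Rcpp::export]]
List cpp_best_diagonal_hit(std::string a, std::string b, int k = 11) {
  std::vector<int8_t> qa = encode_seq(a);
  std::vector<int8_t> fb = encode_seq(b);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  double best_id = 0; int best_len = 0; std::string best_strand = "+";
  int best_score_all = -1;

  for (int ori = 0; ori < 2; ++ori) {
    std::vector<int8_t> qb = (ori == 0) ? fb : revcomp_enc(fb);
    if ((int)qa.size() < k || (int)qb.size() < k) continue;

    std::unordered_map<uint64_t, std::vector<int32_t>> idx;
    {
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < (int)qb.size(); ++i) {
        if (qb[i] >= 4) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)qb[i]) & mask;
        if (++run >= k) idx[h].push_back(i - k + 1);
      }
    }
    std::unordered_map<int, int> diag_votes;
    {
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < (int)qa.size(); ++i) {
        if (qa[i] >= 4) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)qa[i]) & mask;
        if (++run < k) continue;
        auto it = idx.find(h);
        if (it == idx.end()) continue;
        int apos = i - k + 1;
        for (int bpos : it->second) diag_votes[apos - bpos]++;
      }
    }
    if (diag_votes.empty()) continue;

    // evaluate the handful of best-supported diagonals exactly
    std::vector<std::pair<int, int>> diags(diag_votes.begin(), diag_votes.end());
    std::sort(diags.begin(), diags.end(),
              [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
                return x.second > y.second;
              });
    int ndiag = std::min((size_t)3, diags.size());
    for (int d = 0; d < ndiag; ++d) {
      int off = diags[d].first;
      int a0 = std::max(0, off), a1 = std::min((int)qa.size(), (int)qb.size() + off);
      if (a1 - a0 < k) continue;
      // Kadane max-scoring run with match counts
      int score = 0, start = a0, m = 0;
      int bscore = -1, b0 = a0, b1 = a0, bm = 0;
      for (int i = a0; i < a1; ++i) {
        bool match = (qa[i] < 4) && (qa[i] == qb[i - off]);
        score += match ? 1 : -1;
        if (match) ++m;
        if (score > bscore) { bscore = score; b0 = start; b1 = i; bm = m; }
        if (score < 0) { score = 0; m = 0; start = i + 1; }
      }
      int len = b1 - b0 + 1;
      if (bscore > best_score_all && len > 0) {
        best_score_all = bscore;
        best_len = len;
        best_id = 100.0 * bm / len;
        best_strand = (ori == 0) ? "+" : "-";
      }
    }
  }
  return List::create(_["identity"] = best_id, _["length"] = best_len,
                      _["strand"] = best_strand);
}
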