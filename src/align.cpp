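#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two nucleotide strings with linear
// gap cost. Under linear gap scoring many co-optimal alignments differ only
// in how gap runs are split; the traceback records every optimal direction
// per cell and, among them, prefers continuing the previous move (keeping
// gap runs contiguous), then diagonal, then up (gap in b), then left
// (gap in a). Deterministic.
// [[Rcpp::export]]
CharacterVector nw_align_cpp(std::string a, std::string b,
                             int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // direction bitmask per cell: 1 diag, 2 up (consume a), 4 left (consume b)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 4; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int sd = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int su = prev[j] + gap;
      int sl = cur[j - 1] + gap;
      int best = std::max(sd, std::max(su, sl));
      unsigned char mask = 0;
      if (sd == best) mask |= 1;
      if (su == best) mask |= 2;
      if (sl == best) mask |= 4;
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = mask;
    }
    std::swap(prev, cur);
  }
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  unsigned char last = 0;  // previous move taken (0 = none yet)
  while (i > 0 || j > 0) {
    unsigned char mask = tb[(size_t)i * (m + 1) + j];
    unsigned char dir;
    if (last != 0 && (mask & last)) dir = last;        // continue the run
    else if (mask & 1) dir = 1;
    else if (mask & 2) dir = 2;
    else dir = 4;
    if (dir == 1) {
      ga.push_back(a[--i]); gb.push_back(b[--j]);
    } else if (dir == 2) {
      ga.push_back(a[--i]); gb.push_back('-');
    } else {
      ga.push_back('-'); gb.push_back(b[--j]);
    }
    last = dir;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return CharacterVector::create(ga, gb);
}

// Ungapped X-drop extension from a seed pair (0-based qpos/spos, both known
// to start a shared k-mer of length k). Extends left and right, trimming each
// side to its running score maximum. Returns (q_start, s_start, len, matches),
// 0-based.
// [[Rcpp::export]]
IntegerVector ungapped_extend_cpp(std::string q, std::string s,
                                  int qpos, int spos, int k,
                                  int match = 1, int mismatch = -2,
                                  int xdrop = 12) {
  const int nq = q.size(), ns = s.size();
  // right extension from end of seed
  int score = 0, best = 0, best_r = k - 1;
  int i = qpos + k, j = spos + k;
  while (i < nq && j < ns) {
    score += (q[i] == s[j]) ? match : mismatch;
    if (score > best) { best = score; best_r = i - qpos; }
    if (best - score > xdrop) break;
    ++i; ++j;
  }
  // left extension from start of seed
  score = 0; best = 0; int best_l = 0;
  i = qpos - 1; j = spos - 1;
  while (i >= 0 && j >= 0) {
    score += (q[i] == s[j]) ? match : mismatch;
    if (score > best) { best = score; best_l = qpos - i; }
    if (best - score > xdrop) break;
    --i; --j;
  }
  int q0 = qpos - best_l, s0 = spos - best_l;
  int len = best_l + best_r + 1;
  int matches = 0;
  for (int t = 0; t < len; ++t)
    if (q[q0 + t] == s[s0 + t]) ++matches;
  return IntegerVector::create(q0, s0, len, matches);
}

// Overlap statistics of a read placed on a target at a fixed diagonal:
// read position r aligns to target position diag + r. Returns (span, matches)
// over the in-bounds overlap.
// [[Rcpp::export]]
IntegerVector diag_overlap_cpp(std::string target, std::string read, int diag) {
  const int nt = target.size(), nr = read.size();
  int r0 = std::max(0, -diag);
  int r1 = std::min(nr, nt - diag);
  int span = r1 - r0;
  if (span <= 0) return IntegerVector::create(0, 0);
  int matches = 0;
  for (int r = r0; r < r1; ++r)
    if (read[r] == target[diag + r]) ++matches;
  return IntegerVector::create(span, matches);
}

// Vectorised diagonal overlap evaluation for read mapping: candidate i places
// read read_idx[i] (1-based into reads) on target tgt_idx[i] at diagonal
// diag[i]. Returns a 2-column matrix (span, matches).
// [[Rcpp::export]]
IntegerMatrix eval_candidates_cpp(CharacterVector targets, CharacterVector reads,
                                  IntegerVector tgt_idx, IntegerVector read_idx,
                                  IntegerVector diag) {
  const int n = tgt_idx.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    std::string t = as<std::string>(targets[tgt_idx[i] - 1]);
    std::string r = as<std::string>(reads[read_idx[i] - 1]);
    const int nt = t.size(), nr = r.size(), d = diag[i];
    int r0 = std::max(0, -d);
    int r1 = std::min(nr, nt - d);
    int span = r1 - r0, matches = 0;
    if (span < 0) span = 0;
    for (int p = r0; p < r1; ++p)
      if (r[p] == t[d + p]) ++matches;
    out(i, 0) = span;
    out(i, 1) = matches;
  }
  return out;
}

// Redundancy test between two baits: TRUE iff at some ungapped relative
// offset the overlap length is >= min_overlap and the identity over that
// overlap exceeds min_identity (strict).
// [[Rcpp::export]]
bool baits_redundant_cpp(std::string a, std::string b,
                         int min_overlap, double min_identity) {
  const int na = a.size(), nb = b.size();
  // offset = position of b[0] relative to a[0]
  for (int off = -(nb - min_overlap); off <= na - min_overlap; ++off) {
    int a0 = std::max(0, off);
    int a1 = std::min(na, off + nb);
    int span = a1 - a0;
    if (span < min_overlap) continue;
    int matches = 0;
    for (int i = a0; i < a1; ++i)
      if (a[i] == b[i - off]) ++matches;
    if ((double)matches / span > min_identity) return true;
  }
  return false;
}

// Longest span covered by an exact tandem repeat of period <= max_period.
// A run of t positions with s[i] == s[i - p] covers t + p bases.
// [[Rcpp::export]]
int max_tandem_span_cpp(std::string s, int max_period) {
  const int n = s.size();
  int best = 0;
  for (int p = 1; p <= max_period && p < n; ++p) {
    int run = 0;
    for (int i = p; i < n; ++i) {
      if (s[i] == s[i - p]) {
        ++run;
        int span = run + p;
        if (span > best) best = span;
      } else {
        run = 0;
      }
    }
  }
  return best;
}

// Canonical k-mers of a sequence: lexicographic min of each k-mer and its
// reverse complement. K-mers containing non-ACGT characters are skipped.
// [[Rcpp::export]]
CharacterVector canonical_kmers_cpp(std::string s, int k) {
  const int n = s.size();
  std::vector<std::string> out;
  if (n < k) return wrap(out);
  out.reserve(n - k + 1);
  auto comp = [](char c) -> char {
    switch (c) {
      case 'A': return 'T'; case 'C': return 'G';
      case 'G': return 'C'; case 'T': return 'A';
      default: return 0;
    }
  };
  for (int i = 0; i + k <= n; ++i) {
    std::string f = s.substr(i, k);
    std::string r(k, 'N');
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = comp(f[k - 1 - j]);
      if (!c) { ok = false; break; }
      r[j] = c;
    }
    if (!ok) continue;
    out.push_back(f < r ? f : r);
  }
  return wrap(out);
}

// Forward k-mers (no canonicalisation); k-mers with non-ACGT characters are
// returned as NA so positions stay aligned with the sequence.
// [[Rcpp::export]]
CharacterVector forward_kmers_cpp(std::string s, int k) {
  const int n = s.size();
  if (n < k) return CharacterVector(0);
  CharacterVector out(n - k + 1);
  for (int i = 0; i + k <= n; ++i) {
    bool ok = true;
    for (int j = i; j < i + k; ++j) {
      char c = s[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
    }
    if (ok) out[i] = s.substr(i, k); else out[i] = NA_STRING;
  }
  return out;
}

// Seed-and-extend pseudo-mapper. For each read (both strands) every shared
// k-mer with any target proposes a (target, diagonal) placement; the
// placement maximizing matches over the in-bounds ungapped overlap wins,
// subject to span >= min(min_span, read length) and identity >= min_identity.
// Ties prefer the plus strand, then the lowest ref_rank (lexicographic
// reference id). Returns 1-based target indices, NA for unmapped reads.
// [[Rcpp::export]]
IntegerVector map_reads_cpp(CharacterVector targets, CharacterVector reads,
                            IntegerVector ref_rank, int k,
                            double min_identity, int min_span) {
  const int nt = targets.size();
  std::vector<std::string> tg(nt);
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> index;
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    const std::string &s = tg[t];
    const int n = s.size();
    for (int i = 0; i + k <= n; ++i) {
      bool ok = true;
      for (int j = i; j < i + k; ++j) {
        char c = s[j];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
      }
      if (ok) index[s.substr(i, k)].push_back({t, i});
    }
  }
  auto rc = [](const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        default: break;
      }
    }
    return r;
  };
  const int nr = reads.size();
  IntegerVector out(nr, NA_INTEGER);
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int best_matches = -1, best_rank = INT_MAX, best_t = -1;
    for (int strand = 0; strand < 2; ++strand) {
      std::string rs = strand == 0 ? fwd : rc(fwd);
      const int n = rs.size();
      const int need = std::min(min_span, n);
      std::set<std::pair<int, int>> seen;
      int s_best = -1, s_rank = INT_MAX, s_t = -1;
      for (int i = 0; i + k <= n; ++i) {
        auto it = index.find(rs.substr(i, k));
        if (it == index.end()) continue;
        for (auto &hit : it->second) {
          int t = hit.first, diag = hit.second - i;
          if (!seen.insert({t, diag}).second) continue;
          const std::string &tgt = tg[t];
          int r0 = std::max(0, -diag);
          int r1 = std::min(n, (int)tgt.size() - diag);
          int span = r1 - r0;
          if (span < need) continue;
          int matches = 0;
          for (int p = r0; p < r1; ++p)
            if (rs[p] == tgt[diag + p]) ++matches;
          if ((double)matches / span < min_identity) continue;
          if (matches > s_best ||
              (matches == s_best && ref_rank[t] < s_rank)) {
            s_best = matches; s_rank = ref_rank[t]; s_t = t;
          }
        }
      }
      // across strands, only strictly more matches displaces the plus hit
      if (s_best > best_matches) {
        best_matches = s_best; best_rank = s_rank; best_t = s_t;
      }
    }
    if (best_t >= 0) out[r] = best_t + 1;
  }
  return out;
}
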