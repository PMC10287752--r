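// Constrained protospacer+PAM alignment within a short window.
//
// Model: the 20-nt protospacer is aligned, with substitutions anywhere and
// at most `max_gap_events` gap runs of at most `max_gap_len` bases each,
// to a window segment whose 3' end abuts a PAM placement; the PAM itself
// is aligned gaplessly under IUPAC semantics.  In strict mode a placement
// whose PAM carries any mismatch is inadmissible; in lenient mode PAM
// mismatches are counted into the distance.  Distance = substitutions +
// gapped bases.
//
// Two independent routes are provided: cpp_scan_strand enumerates gap
// configurations explicitly (the production scanner, with traceback);
// cpp_oracle_strand is a memoized dynamic program over alignment moves
// used as the exhaustive oracle in tests.

#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base_bit(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': return 8;
  }
  return 0;
}

struct Run {
  int k;    // placed after k pattern characters
  int dir;  // 0 = pattern base unaligned (deletion), 1 = window base unaligned (insertion)
  int g;    // run length in bases
};

// [[Rcpp::export]]
List cpp_scan_strand(std::string window, std::string proto,
                     IntegerVector pam_mask, bool strict, int max_gap_len,
                     int max_gap_events, bool forbid_seed_gaps,
                     int seed_start) {
  const int n = (int)window.size();
  const int m = (int)proto.size();
  const int lp = (int)pam_mask.size();

  // enumerate admissible gap configurations once
  std::vector<std::vector<Run>> configs;
  configs.push_back(std::vector<Run>());
  if (max_gap_events >= 1) {
    for (int dir = 0; dir < 2; ++dir)
      for (int g = 1; g <= max_gap_len; ++g)
        for (int k = 0; k <= (dir == 0 ? m - g : m); ++k)
          configs.push_back(std::vector<Run>{{k, dir, g}});
  }
  if (max_gap_events >= 2) {
    for (int d1 = 0; d1 < 2; ++d1)
      for (int g1 = 1; g1 <= max_gap_len; ++g1)
        for (int k1 = 0; k1 <= (d1 == 0 ? m - g1 : m); ++k1)
          for (int d2 = 0; d2 < 2; ++d2)
            for (int g2 = 1; g2 <= max_gap_len; ++g2) {
              int kmin;  // avoid merged runs (same direction, adjacent)
              if (d1 == 0 && d2 == 0) kmin = k1 + g1 + 1;
              else if (d1 == 0) kmin = k1 + g1;
              else if (d2 == 0) kmin = k1;
              else kmin = k1 + 1;
              for (int k2 = kmin; k2 <= (d2 == 0 ? m - g2 : m); ++k2)
                configs.push_back(std::vector<Run>{{k1, d1, g1}, {k2, d2, g2}});
            }
  }

  bool found = false;
  int best_dist = INT_MAX, best_gaps = 0, best_mm = 0, best_s = -1,
      best_p = -1, best_seed = 0;
  std::vector<Run> best_runs;

  for (int p = 0; p + lp <= n; ++p) {
    int pam_cost = 0;
    for (int q = 0; q < lp; ++q)
      if (!(pam_mask[q] & base_bit(window[p + q]))) ++pam_cost;
    if (strict && pam_cost > 0) continue;

    for (size_t ci = 0; ci < configs.size(); ++ci) {
      const std::vector<Run>& runs = configs[ci];
      int L = m;
      bool seed_gap = false;
      for (size_t r = 0; r < runs.size(); ++r) {
        if (runs[r].dir == 0) {
          L -= runs[r].g;
          if (runs[r].k + runs[r].g >= seed_start) seed_gap = true;
        } else {
          L += runs[r].g;
          if (runs[r].k >= seed_start - 1) seed_gap = true;
        }
      }
      if (forbid_seed_gaps && seed_gap) continue;
      int s = p - L;
      if (s < 0) continue;

      // walk the alignment: i over pattern, j over window
      int i = 0, j = s, mm = 0, seed_edits = 0, gap_bases = 0;
      for (size_t r = 0; r <= runs.size(); ++r) {
        int stop_k = (r < runs.size()) ? runs[r].k : m;
        for (; i < stop_k; ++i, ++j)
          if (proto[i] != window[j]) {
            ++mm;
            if (i + 1 >= seed_start) ++seed_edits;
          }
        if (r < runs.size()) {
          gap_bases += runs[r].g;
          bool in_seed = (runs[r].dir == 0)
                             ? (runs[r].k + runs[r].g >= seed_start)
                             : (runs[r].k >= seed_start - 1);
          if (in_seed) seed_edits += runs[r].g;
          if (runs[r].dir == 0) i += runs[r].g;
          else j += runs[r].g;
        }
      }
      int dist = mm + gap_bases + (strict ? 0 : pam_cost);
      int mm_total = mm + (strict ? 0 : pam_cost);
      bool better =
          !found || dist < best_dist ||
          (dist == best_dist &&
           (gap_bases < best_gaps ||
            (gap_bases == best_gaps && s < best_s)));
      if (better) {
        found = true;
        best_dist = dist;
        best_gaps = gap_bases;
        best_mm = mm_total;
        best_s = s;
        best_p = p;
        best_seed = seed_edits;
        best_runs = runs;
      }
    }
  }

  if (!found)
    return List::create(Named("valid") = false);

  // reconstruct gapped alignment strings for the best placement
  std::string ap, aw;
  {
    int i = 0, j = best_s;
    for (size_t r = 0; r <= best_runs.size(); ++r) {
      int stop_k = (r < best_runs.size()) ? best_runs[r].k : m;
      for (; i < stop_k; ++i, ++j) {
        ap.push_back(proto[i]);
        aw.push_back(window[j]);
      }
      if (r < best_runs.size()) {
        for (int q = 0; q < best_runs[r].g; ++q) {
          if (best_runs[r].dir == 0) {
            ap.push_back(proto[i]);
            aw.push_back('-');
            ++i;
          } else {
            ap.push_back('-');
            aw.push_back(window[j]);
            ++j;
          }
        }
      }
    }
    for (int q = 0; q < lp; ++q) {
      ap.push_back('.');  // PAM pattern position (gapless)
      aw.push_back(window[best_p + q]);
    }
  }

  return List::create(
      Named("valid") = true, Named("dist") = best_dist,
      Named("mismatches") = best_mm, Named("gaps") = best_gaps,
      Named("proto_start") = best_s, Named("pam_start") = best_p,
      Named("seed_edits") = best_seed, Named("aln_pattern") = ap,
      Named("aln_window") = aw);
}

// Exhaustive DP oracle: forward dynamic program over alignment moves with
// run-length/run-count bookkeeping in the state.  Returns the minimum
// distance over all placements, or -1 when no placement is admissible.
// [[Rcpp::export]]
int cpp_oracle_strand(std::string window, std::string proto,
                      IntegerVector pam_mask, bool strict, int max_gap_len,
                      int max_gap_events) {
  const int n = (int)window.size();
  const int m = (int)proto.size();
  const int lp = (int)pam_mask.size();
  const int E = max_gap_events, G = max_gap_len;
  int best = INT_MAX;

  // state: i pattern chars consumed, window position j (exclusive end),
  // e gap events used, dir of last move (0 match, 1 del, 2 ins), run len
  const int DIRS = 3, LEN = G + 1;
  std::vector<int> dp;

  for (int p = 0; p + lp <= n; ++p) {
    int pam_cost = 0;
    for (int q = 0; q < lp; ++q)
      if (!(pam_mask[q] & base_bit(window[p + q]))) ++pam_cost;
    if (strict && pam_cost > 0) continue;

    dp.assign((size_t)(m + 1) * (p + 1) * (E + 1) * DIRS * LEN, INT_MAX);
    auto id = [&](int i, int j, int e, int d, int l) {
      return (((((size_t)i * (p + 1) + j) * (E + 1) + e) * DIRS + d) * LEN + l);
    };
    for (int j = 0; j <= p; ++j) dp[id(0, j, 0, 0, 0)] = 0;

    for (int i = 0; i <= m; ++i)
      for (int j = 0; j <= p; ++j)
        for (int e = 0; e <= E; ++e)
          for (int d = 0; d < DIRS; ++d)
            for (int l = 0; l < LEN; ++l) {
              int cur = dp[id(i, j, e, d, l)];
              if (cur == INT_MAX) continue;
              // match / substitution
              if (i < m && j < p) {
                int c = cur + (proto[i] == window[j] ? 0 : 1);
                int& t = dp[id(i + 1, j + 1, e, 0, 0)];
                if (c < t) t = c;
              }
              // deletion: pattern base unaligned
              if (i < m) {
                if (d == 1 && l < G) {
                  int& t = dp[id(i + 1, j, e, 1, l + 1)];
                  if (cur + 1 < t) t = cur + 1;
                } else if (d != 1 && e < E && G >= 1) {
                  int& t = dp[id(i + 1, j, e + 1, 1, 1)];
                  if (cur + 1 < t) t = cur + 1;
                }
              }
              // insertion: window base unaligned
              if (j < p) {
                if (d == 2 && l < G) {
                  int& t = dp[id(i, j + 1, e, 2, l + 1)];
                  if (cur + 1 < t) t = cur + 1;
                } else if (d != 2 && e < E && G >= 1) {
                  int& t = dp[id(i, j + 1, e + 1, 2, 1)];
                  if (cur + 1 < t) t = cur + 1;
                }
              }
            }

    for (int e = 0; e <= E; ++e)
      for (int d = 0; d < DIRS; ++d)
        for (int l = 0; l < LEN; ++l) {
          int v = dp[id(m, p, e, d, l)];
          if (v != INT_MAX) {
            int tot = v + (strict ? 0 : pam_cost);
            if (tot < best) best = tot;
          }
        }
  }
  return best == INT_MAX ? -1 : best;
}
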