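#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Needleman-Wunsch / Gotoh) of an observed
// sequence against a reference, reporting indels in 1-based reference
// coordinates. A gap of length k scores gap_open + k * gap_ext. Ties are
// broken so that gaps are placed leftmost: during traceback from the end,
// the diagonal state is preferred, then reference-gap, then query-gap.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_indels")]]
List nw_indels_cpp(std::string obs, std::string ref,
                   double match = 2.0, double mismatch = -4.0,
                   double gap_open = -6.0, double gap_ext = -1.0) {
  const int n = (int)ref.size();   // reference along i
  const int m = (int)obs.size();   // observed along j
  // D: ends in (mis)match; P: gap in observed (ref base deleted);
  // Q: gap in reference (observed base inserted)
  std::vector<std::vector<double>> D(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> P(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Q(n + 1, std::vector<double>(m + 1, NEG_INF));
  D[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) P[i][0] = gap_open + i * gap_ext;
  for (int j = 1; j <= m; ++j) Q[0][j] = gap_open + j * gap_ext;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (ref[i - 1] == obs[j - 1]) ? match : mismatch;
      double d0 = std::max(D[i - 1][j - 1], std::max(P[i - 1][j - 1], Q[i - 1][j - 1]));
      if (d0 > NEG_INF) D[i][j] = d0 + s;
      double po = std::max(D[i - 1][j], Q[i - 1][j]);
      P[i][j] = std::max(po + gap_open + gap_ext, P[i - 1][j] + gap_ext);
      double qo = std::max(D[i][j - 1], P[i][j - 1]);
      Q[i][j] = std::max(qo + gap_open + gap_ext, Q[i][j - 1] + gap_ext);
    }
  }

  // traceback; state 0 = D, 1 = P, 2 = Q; prefer D > P > Q on ties
  double best = std::max(D[n][m], std::max(P[n][m], Q[n][m]));
  int state = (D[n][m] == best) ? 0 : (P[n][m] == best ? 1 : 2);
  int i = n, j = m;
  const double eps = 1e-9;

  std::vector<int> op_type;       // 0 = del, 1 = ins
  std::vector<int> op_start, op_end, op_len;
  std::vector<std::string> op_seq;
  // collect runs while walking backwards
  int run_type = -1, run_end = 0, run_len = 0;
  std::string run_seq;

  auto flush = [&](void) {
    if (run_type >= 0) {
      op_type.push_back(run_type);
      op_len.push_back(run_len);
      if (run_type == 0) {                 // deletion of ref positions
        op_start.push_back(run_end - run_len + 1);
        op_end.push_back(run_end);
        op_seq.push_back(std::string(ref, run_end - run_len, run_len));
      } else {                             // insertion after ref position
        op_start.push_back(run_end);
        op_end.push_back(run_end);
        std::string s = run_seq;
        std::reverse(s.begin(), s.end());
        op_seq.push_back(s);
      }
      run_type = -1; run_len = 0; run_seq.clear();
    }
  };

  while (i > 0 || j > 0) {
    if (state == 0) {
      flush();
      double target = D[i][j] - ((ref[i - 1] == obs[j - 1]) ? match : mismatch);
      int prev;
      if (std::abs(D[i - 1][j - 1] - target) < eps) prev = 0;
      else if (std::abs(P[i - 1][j - 1] - target) < eps) prev = 1;
      else prev = 2;
      --i; --j; state = prev;
    } else if (state == 1) {               // deletion of ref base i
      if (run_type != 0) { flush(); run_type = 0; run_end = i; }
      ++run_len;
      double v = P[i][j];
      int prev;
      if (i - 1 >= 0 && std::abs(D[i - 1][j] + gap_open + gap_ext - v) < eps) prev = 0;
      else if (std::abs(Q[i - 1][j] + gap_open + gap_ext - v) < eps) prev = 2;
      else prev = 1;
      --i; state = prev;
    } else {                               // insertion of obs base j
      if (run_type != 1) { flush(); run_type = 1; run_end = i; }
      ++run_len;
      run_seq.push_back(obs[j - 1]);
      double v = Q[i][j];
      int prev;
      if (std::abs(D[i][j - 1] + gap_open + gap_ext - v) < eps) prev = 0;
      else if (std::abs(P[i][j - 1] + gap_open + gap_ext - v) < eps) prev = 1;
      else prev = 2;
      --j; state = prev;
    }
  }
  flush();

  // runs were collected right-to-left; reverse to left-to-right order
  int k = (int)op_type.size();
  CharacterVector op(k), seq(k);
  IntegerVector start(k), end(k), len(k);
  for (int r = 0; r < k; ++r) {
    int src = k - 1 - r;
    op[r] = (op_type[src] == 0) ? "del" : "ins";
    start[r] = op_start[src];
    end[r] = op_end[src];
    len[r] = op_len[src];
    seq[r] = op_seq[src];
  }
  return List::create(_["op"] = op, _["start"] = start, _["end"] = end,
                      _["length"] = len, _["seq"] = seq, _["score"] = best);
}

static char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// Merge one read pair: r2 is reverse-complemented, then the best suffix(r1)/
// prefix(rc(r2)) overlap with >= min_overlap bases and mismatch fraction <=
// max_mismatch_frac is chosen (fewest mismatches, ties to the longest
// overlap). Disagreeing overlap bases take the higher-quality call.

// [[Rcpp::export(name = ".merge_pair")]]
List merge_pair_cpp(std::string s1, IntegerVector q1,
                    std::string s2, IntegerVector q2,
                    int min_overlap = 10, double max_mismatch_frac = 0.25) {
  const int n1 = (int)s1.size(), n2 = (int)s2.size();
  std::string r2(n2, 'N');
  std::vector<int> qr2(n2);
  for (int i = 0; i < n2; ++i) {
    r2[i] = comp(s2[n2 - 1 - i]);
    qr2[i] = q2[n2 - 1 - i];
  }
  int best_o = -1, best_mm = INT_MAX;
  int omax = std::min(n1, n2);
  for (int o = omax; o >= min_overlap; --o) {
    int mm = 0;
    int limit = (int)std::floor(max_mismatch_frac * o);
    for (int i = 0; i < o; ++i) {
      if (s1[n1 - o + i] != r2[i] && ++mm > limit) break;
    }
    if (mm > limit) continue;
    if (mm < best_mm) { best_mm = mm; best_o = o; }
  }
  if (best_o < 0) return List::create(_["merged"] = R_NilValue);

  int o = best_o;
  int mlen = n1 + n2 - o;
  std::string out(mlen, 'N');
  IntegerVector qout(mlen);
  for (int i = 0; i < n1 - o; ++i) { out[i] = s1[i]; qout[i] = q1[i]; }
  for (int i = 0; i < o; ++i) {
    int p1 = n1 - o + i;
    if (s1[p1] == r2[i]) {
      out[p1] = s1[p1];
      qout[p1] = std::max((int)q1[p1], qr2[i]);
    } else if (q1[p1] >= qr2[i]) {
      out[p1] = s1[p1]; qout[p1] = q1[p1];
    } else {
      out[p1] = r2[i]; qout[p1] = qr2[i];
    }
  }
  for (int i = o; i < n2; ++i) { out[n1 + i - o] = r2[i]; qout[n1 + i - o] = qr2[i]; }
  return List::create(_["merged"] = out, _["qual"] = qout,
                      _["overlap"] = o, _["mismatches"] = best_mm);
}
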