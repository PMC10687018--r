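#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Alignment op codes shared with the R layer:
// 0 = match, 1 = mismatch, 2 = insertion-in-read (read base absent from
// target), 3 = deletion-from-read (target base absent from read).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Alignment {
  double score;
  std::vector<int> ops;   // op codes
  std::vector<int> tpos;  // 1-based target coord (ins: left neighbour, may be 0)
  std::vector<int> rpos;  // 1-based read coord (del: left neighbour, may be 0)
  int t_start, t_end;     // aligned target span (1-based, inclusive); 0 if none
  int r_start, r_end;     // aligned read span
};

// Semi-global (overlap) alignment with affine gaps and free end gaps on both
// sequences.  A gap of length k costs gap_open + k * gap_ext.  Traceback
// tie-break prefers diagonal over deletion over insertion; indel placement is
// normalised afterwards by left-shifting within repeats, so the traceback
// order only needs to be deterministic.
static Alignment semiglobal(const std::string& read, const std::string& target,
                            double match, double mismatch,
                            double gap_open, double gap_ext) {
  const int m = read.size(), n = target.size();
  Alignment out;
  out.score = 0.0;
  out.t_start = out.t_end = out.r_start = out.r_end = 0;
  if (m == 0 || n == 0) return out;

  // M: diagonal; X: gap in read (consumes target); Y: gap in target (consumes read)
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { M(0, j) = 0.0; X(0, j) = NEG_INF; Y(0, j) = NEG_INF; }
  for (int i = 0; i <= m; ++i) { M(i, 0) = 0.0; X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF; }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = (read[i - 1] == target[j - 1]) ? match : mismatch;
      double d = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = d + s;
      X(i, j) = std::max(M(i, j - 1) - (gap_open + gap_ext), X(i, j - 1) - gap_ext);
      Y(i, j) = std::max(M(i - 1, j) - (gap_open + gap_ext), Y(i - 1, j) - gap_ext);
    }
  }

  // Best end cell over the last row and last column (free trailing end gaps).
  // Prefer larger j, then larger i, then matrix M > X > Y, deterministically.
  double best = NEG_INF;
  int bi = 0, bj = 0, bmat = 0; // 0=M,1=X,2=Y
  auto consider = [&](int i, int j, int k, double v) {
    bool better = v > best;
    bool tie = (v == best) &&
      (j > bj || (j == bj && (i > bi || (i == bi && k < bmat))));
    if (better || tie) { best = v; bi = i; bj = j; bmat = k; }
  };
  for (int j = 0; j <= n; ++j) {
    consider(m, j, 0, M(m, j)); consider(m, j, 1, X(m, j)); consider(m, j, 2, Y(m, j));
  }
  for (int i = 0; i <= m; ++i) {
    consider(i, n, 0, M(i, n)); consider(i, n, 1, X(i, n)); consider(i, n, 2, Y(i, n));
  }

  out.score = best;
  if (best <= 0.0) return out; // nothing aligned usefully

  // Traceback.  Paths start on the free boundary (i == 0 or j == 0), so the
  // walk simply continues until either sequence is exhausted.  For gap ops the
  // stored coordinate of the non-consumed sequence is the left neighbour
  // (number of bases consumed so far).
  std::vector<int> ops, tp, rp;
  int i = bi, j = bj, mat = bmat;
  while (i > 0 && j > 0) {
    if (mat == 0) {
      double s = (read[i - 1] == target[j - 1]) ? match : mismatch;
      double d = M(i, j) - s;
      ops.push_back(read[i - 1] == target[j - 1] ? 0 : 1);
      tp.push_back(j); rp.push_back(i);
      if (M(i - 1, j - 1) == d) mat = 0;       // prefer diagonal,
      else if (X(i - 1, j - 1) == d) mat = 1;  // then gap-in-read,
      else mat = 2;                            // then gap-in-target
      --i; --j;
    } else if (mat == 1) { // gap in read, consumes target j
      ops.push_back(3); tp.push_back(j); rp.push_back(i);
      if (M(i, j - 1) - (gap_open + gap_ext) == X(i, j)) mat = 0; else mat = 1;
      --j;
    } else { // gap in target, consumes read i
      ops.push_back(2); tp.push_back(j); rp.push_back(i);
      if (M(i - 1, j) - (gap_open + gap_ext) == Y(i, j)) mat = 0; else mat = 2;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(tp.begin(), tp.end());
  std::reverse(rp.begin(), rp.end());

  out.ops = ops; out.tpos = tp; out.rpos = rp;
  out.t_start = 0; out.t_end = 0; out.r_start = 0; out.r_end = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] != 2) { // consumes target
      if (out.t_start == 0) out.t_start = tp[k];
      out.t_end = tp[k];
    }
    if (ops[k] != 3) { // consumes read
      if (out.r_start == 0) out.r_start = rp[k];
      out.r_end = rp[k];
    }
  }
  return out;
}

// Left-shift indel runs within repeats so that equivalent gap placements give
// identical mutation calls.  Operates in place on the op/coordinate vectors.
static void left_align_indels(std::vector<int>& ops, std::vector<int>& tp,
                              std::vector<int>& rp,
                              const std::string& read, const std::string& target) {
  bool moved = true;
  while (moved) {
    moved = false;
    for (size_t k = 0; k < ops.size(); ++k) {
      if (ops[k] != 2 && ops[k] != 3) continue;
      // find run [k..e) of same op
      size_t e = k;
      while (e < ops.size() && ops[e] == ops[k]) ++e;
      if (k == 0) { k = e - 1; continue; }
      int prev = k - 1;
      if (ops[prev] != 0 && ops[prev] != 1) { k = e - 1; continue; }
      if (ops[k] == 3) {
        // deletion of target[a..b]; shift if target[a-1] == target[b]
        int a = tp[k], b = tp[e - 1];
        if (target[a - 2] == target[b - 1]) {
          // previous diagonal column (read r <-> target a-1) becomes
          // (read r <-> target b); statuses match because bases are equal.
          int r = rp[prev];
          // run shifts to target a-1..b-1; the diagonal column moves to its
          // right end, so the run's left read neighbour becomes r-1
          for (size_t q = k; q < e; ++q) { tp[q] -= 1; rp[q] = r - 1; }
          ops[prev] = (read[r - 1] == target[b - 1]) ? 0 : 1;
          tp[prev] = b; rp[prev] = r;
          // move the diagonal column to after the run
          // reorder: rows prev..e-1 become [del run, diag]
          std::rotate(ops.begin() + prev, ops.begin() + prev + 1, ops.begin() + e);
          std::rotate(tp.begin() + prev, tp.begin() + prev + 1, tp.begin() + e);
          std::rotate(rp.begin() + prev, rp.begin() + prev + 1, rp.begin() + e);
          moved = true;
        }
      } else {
        // insertion of read[a..b]; shift if read[a-1] == read[b]
        int a = rp[k], b = rp[e - 1];
        if (read[a - 2] == read[b - 1]) {
          int t = tp[prev];
          for (size_t q = k; q < e; ++q) { rp[q] -= 1; tp[q] = t - 1; }
          ops[prev] = (read[b - 1] == target[t - 1]) ? 0 : 1;
          tp[prev] = t; rp[prev] = b;
          std::rotate(ops.begin() + prev, ops.begin() + prev + 1, ops.begin() + e);
          std::rotate(tp.begin() + prev, tp.begin() + prev + 1, tp.begin() + e);
          std::rotate(rp.begin() + prev, rp.begin() + prev + 1, rp.begin() + e);
          moved = true;
        }
      }
      k = e - 1;
    }
  }
}

struct CallResult {
  std::vector<int> events;      // target positions of collapsed events
  std::vector<int> depth;       // target positions contributing depth
};

static CallResult call_from_alignment(std::vector<int> ops, std::vector<int> tp,
                                      std::vector<int> rp,
                                      const std::string& read,
                                      const std::string& qual,
                                      const std::string& target,
                                      int min_qual, int merge_gap) {
  left_align_indels(ops, tp, rp, read, target);
  const int n = target.size();
  auto q = [&](int r) { return (int)qual[r - 1] - 33; };

  std::vector<int> mutated;             // mutated target columns, ascending
  std::vector<bool> depth(n + 1, false);
  std::vector<bool> force_depth(n + 1, false);

  size_t K = ops.size();
  for (size_t k = 0; k < K; ++k) {
    if (ops[k] == 0) {
      if (q(rp[k]) >= min_qual) depth[tp[k]] = true;
    } else if (ops[k] == 1) {
      if (q(rp[k]) >= min_qual) { depth[tp[k]] = true; mutated.push_back(tp[k]); }
    } else if (ops[k] == 2) {
      // insertion run
      size_t e = k; bool pass = true;
      while (e < K && ops[e] == 2) { if (q(rp[e]) < min_qual) pass = false; ++e; }
      if (pass) {
        int anchor = std::min(tp[k] + 1, n);
        if (anchor >= 1) { mutated.push_back(anchor); force_depth[anchor] = true; }
      }
      k = e - 1;
    } else {
      // deletion run over target tp[k]..tp[e-1]
      size_t e = k;
      while (e < K && ops[e] == 3) ++e;
      int rl = rp[k];            // left read neighbour
      int rr = rl + 1;           // right read neighbour
      bool pass = rl >= 1 && rr <= (int)read.size() && q(rl) >= min_qual && q(rr) >= min_qual;
      if (pass) {
        for (size_t s = k; s < e; ++s) { mutated.push_back(tp[s]); depth[tp[s]] = true; }
      }
      k = e - 1;
    }
  }

  std::sort(mutated.begin(), mutated.end());
  mutated.erase(std::unique(mutated.begin(), mutated.end()), mutated.end());

  CallResult res;
  // collapse mutated columns separated by < merge_gap matching columns
  size_t i = 0;
  while (i < mutated.size()) {
    size_t j = i;
    while (j + 1 < mutated.size() && mutated[j + 1] - mutated[j] - 1 < merge_gap) ++j;
    res.events.push_back(mutated[j]); // 3'-most position of the collapsed event
    i = j + 1;
  }
  for (int p : res.events) force_depth[p] = true;
  for (int p = 1; p <= n; ++p)
    if (depth[p] || force_depth[p]) res.depth.push_back(p);
  return res;
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(std::string read, std::string target,
               double match, double mismatch, double gap_open, double gap_ext) {
  Alignment a = semiglobal(read, target, match, mismatch, gap_open, gap_ext);
  return List::create(_["score"] = a.score,
                      _["ops"] = wrap(a.ops),
                      _["tpos"] = wrap(a.tpos),
                      _["rpos"] = wrap(a.rpos),
                      _["t_start"] = a.t_start, _["t_end"] = a.t_end,
                      _["r_start"] = a.r_start, _["r_end"] = a.r_end);
}

// [[Rcpp::export(name = ".cpp_call_mutations")]]
List cpp_call_mutations(IntegerVector ops, IntegerVector tpos, IntegerVector rpos,
                        std::string read, std::string qual, std::string target,
                        int min_qual, int merge_gap) {
  std::vector<int> o(ops.begin(), ops.end());
  std::vector<int> t(tpos.begin(), tpos.end());
  std::vector<int> r(rpos.begin(), rpos.end());
  CallResult res = call_from_alignment(o, t, r, read, qual, target, min_qual, merge_gap);
  return List::create(_["events"] = wrap(res.events), _["depth"] = wrap(res.depth));
}

struct MergeResult {
  bool merged;
  std::string seq, qual;
};

// Merge the 5' piece (read 2 remainder) with the 3' piece (reverse-complemented
// read 1 remainder).  Offsets are scanned exhaustively; among qualifying
// overlaps the one with most matching bases wins, ties going to the longer
// overlap, then to the shorter insert.
static MergeResult merge_pieces(const std::string& s5, const std::string& q5,
                                const std::string& s3, const std::string& q3,
                                int min_overlap, double max_mm_frac) {
  const int n5 = s5.size(), n3 = s3.size();
  int best_matches = -1, best_olap = 0, best_L = 0;
  int max_olap = std::min(n5, n3);
  for (int o = min_overlap; o <= max_olap; ++o) {
    int L = n5 + n3 - o;
    int mm = 0, mat = 0;
    // overlap region: s5 positions n5-o.. n5-1 vs s3 positions 0..o-1
    for (int k = 0; k < o; ++k) {
      if (s5[n5 - o + k] == s3[k]) ++mat; else ++mm;
    }
    if ((double)mm / o > max_mm_frac) continue;
    if (mat > best_matches ||
        (mat == best_matches && (o > best_olap || (o == best_olap && L < best_L)))) {
      best_matches = mat; best_olap = o; best_L = L;
    }
  }
  MergeResult res; res.merged = false;
  if (best_matches < 0) return res;
  int o = best_olap, L = best_L;
  res.merged = true;
  res.seq.resize(L); res.qual.resize(L);
  for (int p = 0; p < n5 - o; ++p) { res.seq[p] = s5[p]; res.qual[p] = q5[p]; }
  for (int k = 0; k < o; ++k) {
    int p = n5 - o + k;
    char b5 = s5[p], b3 = s3[k];
    int Q5 = q5[p] - 33, Q3 = q3[k] - 33;
    if (b5 == b3) {
      res.seq[p] = b5; res.qual[p] = (char)(33 + std::max(Q5, Q3));
    } else if (Q5 >= Q3) {
      res.seq[p] = b5; res.qual[p] = (char)(33 + (Q5 - Q3));
    } else {
      res.seq[p] = b3; res.qual[p] = (char)(33 + (Q3 - Q5));
    }
  }
  for (int k = o; k < n3; ++k) { res.seq[n5 - o + k] = s3[k]; res.qual[n5 - o + k] = q3[k]; }
  return res;
}

// [[Rcpp::export(name = ".cpp_merge_pair")]]
List cpp_merge_pair(std::string seq5, std::string qual5,
                    std::string seq3, std::string qual3,
                    int min_overlap, double max_mm_frac) {
  MergeResult r = merge_pieces(seq5, qual5, seq3, qual3, min_overlap, max_mm_frac);
  return List::create(_["merged"] = r.merged, _["seq"] = r.seq, _["qual"] = r.qual);
}

// [[Rcpp::export(name = ".cpp_trim_adapter")]]
IntegerVector cpp_trim_adapter(CharacterVector seqs, std::string adapter,
                               int min_overlap, double max_mm_frac) {
  const int N = seqs.size();
  IntegerVector keep(N);
  const int alen = adapter.size();
  for (int r = 0; r < N; ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int m = s.size();
    int cut = m;
    int kmax = std::min(m, alen);
    for (int k = kmax; k >= min_overlap; --k) {
      int mm = 0;
      int allowed = (int)std::floor(max_mm_frac * k);
      bool ok = true;
      for (int p = 0; p < k; ++p) {
        if (s[m - k + p] != adapter[p] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { cut = m - k; break; } // longest qualifying suffix
    }
    keep[r] = cut;
  }
  return keep;
}

// Profile one (channel, length) bin: merge each pair, align the insert to the
// target, gate on the score floor, call mutations, and accumulate
// per-position effective depth and collapsed mutation events. caps gives the
// per-read counting limit (1-based target coordinate): a read believed to be
// from a shorter transcript never contributes beyond its own 3' end, which
// keeps read-pooled and count-pooled smoothing interchangeable.
// [[Rcpp::export(name = ".cpp_profile_bin")]]
List cpp_profile_bin(CharacterVector seq5, CharacterVector qual5,
                     CharacterVector seq3, CharacterVector qual3,
                     std::string target, IntegerVector caps,
                     int merge_min_overlap, double merge_max_mm_frac,
                     double match, double mismatch, double gap_open, double gap_ext,
                     double score_floor_frac, int min_qual, int merge_gap) {
  const int N = seq5.size();
  const int n = target.size();
  IntegerVector depth(n), events(n);
  int n_merged = 0, n_unmerged = 0, n_discarded = 0;
  for (int r = 0; r < N; ++r) {
    std::string s5 = as<std::string>(seq5[r]);
    std::string q5 = as<std::string>(qual5[r]);
    std::string s3 = as<std::string>(seq3[r]);
    std::string q3 = as<std::string>(qual3[r]);
    int cap = (caps.size() == 1) ? caps[0] : caps[r];
    if (cap > n) cap = n;
    std::string ins, insq;
    MergeResult mr = merge_pieces(s5, q5, s3, q3, merge_min_overlap, merge_max_mm_frac);
    if (mr.merged) { ins = mr.seq; insq = mr.qual; ++n_merged; }
    else { ins = s3; insq = q3; ++n_unmerged; } // fall back to the 3' piece
    if (ins.empty()) { ++n_discarded; continue; }
    Alignment a = semiglobal(ins, target, match, mismatch, gap_open, gap_ext);
    double floor = score_floor_frac * match * std::min((int)ins.size(), n);
    if (a.ops.empty() || a.score < floor) { ++n_discarded; continue; }
    CallResult cr = call_from_alignment(a.ops, a.tpos, a.rpos, ins, insq, target,
                                        min_qual, merge_gap);
    for (int p : cr.depth) if (p <= cap) depth[p - 1] += 1;
    for (int p : cr.events) if (p <= cap) events[p - 1] += 1;
  }
  return List::create(_["depth"] = depth, _["events"] = events,
                      _["n_reads"] = N, _["n_merged"] = n_merged,
                      _["n_unmerged"] = n_unmerged, _["n_discarded"] = n_discarded);
}
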