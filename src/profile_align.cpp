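#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment of a position-specific scoring profile against a
// protein sequence. Three-state DP (match / insert-in-sequence /
// delete-profile-column) with full traceback.
//
// Modes:
//   local:  best-scoring segment; the path may start and end at any
//           profile column and sequence position, and must start/end in a
//           match state.
//   global: the full profile is consumed (matches or deletions); the
//           sequence ends are free ("glocal"), so the profile is aligned
//           to its best-scoring sequence segment.
//
// Ties are broken by leftmost start, then shortest interval; transitions
// of equal score prefer the smaller recorded start so the reported
// interval is reproducible.

static const double NEG = -1e30;

struct Cell { double v; int start; };

static inline bool better(double v, int s, double bv, int bs) {
  if (v > bv + 1e-12) return true;
  if (v < bv - 1e-12) return false;
  return s < bs;
}

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix scores, NumericVector gap_open,
                       NumericVector gap_ext, IntegerVector seq,
                       bool local) {
  const int L = scores.nrow();
  const int N = seq.size();

  // DP matrices, (L+1) x (N+1), index [i][j] flattened
  std::vector<double> M((L + 1) * (N + 1), NEG), I(M), D(M);
  std::vector<int> Ms(M.size(), -1), Is(M.size(), -1), Ds(M.size(), -1);
  std::vector<signed char> Mt(M.size(), -1), It(M.size(), -1), Dt(M.size(), -1);
  // trace codes: 0 fresh start, 1 from M, 2 from I, 3 from D
  auto at = [N](int i, int j) { return i * (N + 1) + j; };

  for (int i = 1; i <= L; ++i) {
    const double go = gap_open[i - 1], ge = gap_ext[i - 1];
    for (int j = 0; j <= N; ++j) {
      const int ij = at(i, j);
      // deletions: skip profile column i without consuming sequence
      {
        double v = NEG; int s = -1; signed char t = -1;
        if (i == 1) { v = -go; s = j; t = 0; }  // open a leading deletion
        const int up = at(i - 1, j);
        if (i > 1 && better(M[up] - go, Ms[up], v, s)) { v = M[up] - go; s = Ms[up]; t = 1; }
        if (i > 1 && better(D[up] - ge, Ds[up], v, s)) { v = D[up] - ge; s = Ds[up]; t = 3; }
        D[ij] = v; Ds[ij] = s; Dt[ij] = t;
      }
      if (j == 0) continue;
      // match: profile column i consumes sequence position j
      {
        const int res = seq[j - 1];
        const double sij = (res >= 0) ? scores(i - 1, res) : 0.0;
        const int dg = at(i - 1, j - 1);
        double v = NEG; int s = -1; signed char t = -1;
        if (i == 1 || local) { v = 0.0; s = j - 1; t = 0; }  // fresh start
        if (i > 1) {
          if (better(M[dg], Ms[dg], v, s)) { v = M[dg]; s = Ms[dg]; t = 1; }
          if (better(I[dg], Is[dg], v, s)) { v = I[dg]; s = Is[dg]; t = 2; }
          if (better(D[dg], Ds[dg], v, s)) { v = D[dg]; s = Ds[dg]; t = 3; }
        }
        M[ij] = v + sij; Ms[ij] = s; Mt[ij] = t;
      }
      // insertion: sequence position j unaligned between columns i, i+1
      {
        const int lf = at(i, j - 1);
        double v = NEG; int s = -1; signed char t = -1;
        if (M[lf] > NEG / 2 && better(M[lf] - go, Ms[lf], v, s)) { v = M[lf] - go; s = Ms[lf]; t = 1; }
        if (I[lf] > NEG / 2 && better(I[lf] - ge, Is[lf], v, s)) { v = I[lf] - ge; s = Is[lf]; t = 2; }
        I[ij] = v; Is[ij] = s; It[ij] = t;
      }
    }
  }

  // pick the best end cell
  double best = NEG; int bs = INT_MAX, bi = -1, bj = -1; char bstate = 'M';
  auto consider = [&](double v, int s, int i, int j, char st) {
    if (v <= NEG / 2) return;
    int len = j - s;
    int blen = (bi < 0) ? INT_MAX : bj - bs;
    bool take = false;
    if (v > best + 1e-12) take = true;
    else if (v >= best - 1e-12) {
      if (s < bs) take = true;
      else if (s == bs && len < blen) take = true;
    }
    if (take) { best = v; bs = s; bi = i; bj = j; bstate = st; }
  };
  if (local) {
    for (int i = 1; i <= L; ++i)
      for (int j = 1; j <= N; ++j)
        consider(M[at(i, j)], Ms[at(i, j)], i, j, 'M');
  } else {
    for (int j = 0; j <= N; ++j) {
      if (j >= 1) consider(M[at(L, j)], Ms[at(L, j)], L, j, 'M');
      consider(D[at(L, j)], Ds[at(L, j)], L, j, 'D');
    }
  }

  IntegerVector match_pos(L, NA_INTEGER);
  if (bi < 0)
    return List::create(_["score"] = NEG, _["start"] = 0, _["end"] = 0,
                        _["match_pos"] = match_pos);

  // traceback
  int i = bi, j = bj; char st = bstate;
  while (true) {
    signed char t;
    if (st == 'M') {
      match_pos[i - 1] = j - 1;
      t = Mt[at(i, j)];
      if (t == 0) break;
      --i; --j;
    } else if (st == 'D') {
      t = Dt[at(i, j)];
      if (t == 0) break;
      --i;
    } else {  // 'I'
      t = It[at(i, j)];
      --j;
    }
    st = (t == 1) ? 'M' : (t == 2) ? 'I' : 'D';
  }

  return List::create(_["score"] = best, _["start"] = bs, _["end"] = bj,
                      _["match_pos"] = match_pos);
}
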