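#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Residues are encoded 1..21 at the R level (21 = X, outside the canonical
// alphabet).  Cost matrices passed down here are 21 x 21 with the X row/column
// already filled in, so the DP never needs a special case.

static inline double sub_cost(const NumericMatrix& C, int a, int b) {
  return C(a - 1, b - 1);
}

// Weighted edit distance (global alignment cost) between two encoded
// sequences: indels cost `indel`, substitutions cost C[a,b].
// [[Rcpp::export]]
double wed_cpp(IntegerVector a, IntegerVector b, NumericMatrix C, double indel) {
  const int la = a.size(), lb = b.size();
  std::vector<double> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j * indel;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i * indel;
    for (int j = 1; j <= lb; ++j) {
      double d = prev[j - 1] + sub_cost(C, a[i - 1], b[j - 1]);
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      cur[j] = std::min(d, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Full DP table of weighted edit distances between all prefixes of a and b.
// Row i+1 / column j+1 holds d(a[1..i], b[1..j]).  Used by the repeat
// extension step, which needs the last row (consensus vs. all prefixes of
// the lookahead window) and the diagonal (pro-rata partial units).
// [[Rcpp::export]]
NumericMatrix wed_table_cpp(IntegerVector a, IntegerVector b, NumericMatrix C,
                            double indel) {
  const int la = a.size(), lb = b.size();
  NumericMatrix D(la + 1, lb + 1);
  for (int j = 0; j <= lb; ++j) D(0, j) = j * indel;
  for (int i = 1; i <= la; ++i) {
    D(i, 0) = i * indel;
    for (int j = 1; j <= lb; ++j) {
      double d = D(i - 1, j - 1) + sub_cost(C, a[i - 1], b[j - 1]);
      double del = D(i - 1, j) + indel;
      double ins = D(i, j - 1) + indel;
      D(i, j) = std::min(d, std::min(del, ins));
    }
  }
  return D;
}

// Global alignment of `unit` against `center`; returns, for every center
// column, the unit residue aligned to it (0 when the unit has a gap there).
// Insertions relative to the center are dropped: the consensus keeps the
// center's coordinate system.
static std::vector<int> align_to_center(const IntegerVector& unit,
                                        const IntegerVector& center,
                                        const NumericMatrix& C, double indel) {
  const int la = unit.size(), lb = center.size();
  std::vector<std::vector<double> > D(la + 1, std::vector<double>(lb + 1));
  std::vector<std::vector<char> > P(la + 1, std::vector<char>(lb + 1));
  for (int j = 0; j <= lb; ++j) { D[0][j] = j * indel; P[0][j] = 'i'; }
  for (int i = 0; i <= la; ++i) { D[i][0] = i * indel; P[i][0] = 'd'; }
  P[0][0] = 's';
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double d = D[i - 1][j - 1] + sub_cost(C, unit[i - 1], center[j - 1]);
      double del = D[i - 1][j] + indel;   // consume unit residue (insertion vs center)
      double ins = D[i][j - 1] + indel;   // consume center column (gap in unit)
      if (d <= del && d <= ins) { D[i][j] = d; P[i][j] = 'm'; }
      else if (del <= ins)      { D[i][j] = del; P[i][j] = 'd'; }
      else                      { D[i][j] = ins; P[i][j] = 'i'; }
    }
  }
  std::vector<int> col(lb, 0);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    char p = P[i][j];
    if (p == 'm')      { col[j - 1] = unit[i - 1]; --i; --j; }
    else if (p == 'd') { --i; }
    else               { --j; }
  }
  return col;
}

// Column-wise minimum-total-cost consensus of a set of units aligned against
// a center string.  For each center column the residue minimizing the summed
// substitution/gap cost is kept, unless dropping the column (charging an
// indel to every unit with a residue there) is strictly cheaper.
// [[Rcpp::export]]
IntegerVector consensus_cpp(List units, IntegerVector center, NumericMatrix C,
                            double indel, int n_res) {
  const int lb = center.size(), t = units.size();
  std::vector<std::vector<int> > cols(t);
  for (int u = 0; u < t; ++u)
    cols[u] = align_to_center(as<IntegerVector>(units[u]), center, C, indel);
  std::vector<int> out;
  out.reserve(lb);
  for (int j = 0; j < lb; ++j) {
    double drop = 0.0;
    for (int u = 0; u < t; ++u) if (cols[u][j] > 0) drop += indel;
    double best = std::numeric_limits<double>::infinity();
    int best_r = center[j];
    for (int r = 1; r <= n_res; ++r) {
      double c = 0.0;
      for (int u = 0; u < t; ++u)
        c += (cols[u][j] > 0) ? sub_cost(C, r, cols[u][j]) : indel;
      if (c < best - 1e-12) { best = c; best_r = r; }
    }
    if (drop < best - 1e-12) continue;  // cheaper to delete this column
    out.push_back(best_r);
  }
  if (out.empty()) return center;
  return wrap(out);
}

// Optimal tandem segmentation of a repeat region against a consensus:
// global alignment of s to the unrolled repetition cons^m (m chosen to
// minimize total cost), returning the start position (1-based, in s) of
// every consensus copy.  This is the wraparound-style re-segmentation that
// replaces greedily grown unit boundaries with alignment-optimal ones.
// Returns m = 0 when the region is too large to segment.
// [[Rcpp::export]]
List tandem_segment_cpp(IntegerVector s, IntegerVector cons, NumericMatrix C,
                        double indel) {
  const int n = s.size(), p = cons.size();
  if (p < 1 || n < 1) return List::create(_["m"] = 0);
  const int mmax = n / p + 2;
  const long w = (long)mmax * p;
  if ((long)(n + 1) * (w + 1) > 8000000L) return List::create(_["m"] = 0);
  std::vector<std::vector<double> > D(n + 1, std::vector<double>(w + 1));
  std::vector<std::vector<char> > P(n + 1, std::vector<char>(w + 1));
  for (long j = 0; j <= w; ++j) { D[0][j] = j * indel; P[0][j] = 'i'; }
  for (int i = 0; i <= n; ++i) { D[i][0] = i * indel; P[i][0] = 'd'; }
  P[0][0] = 's';
  for (int i = 1; i <= n; ++i) {
    for (long j = 1; j <= w; ++j) {
      int cj = cons[(j - 1) % p];
      double d = D[i - 1][j - 1] + sub_cost(C, s[i - 1], cj);
      double del = D[i - 1][j] + indel;
      double ins = D[i][j - 1] + indel;
      if (d <= del && d <= ins) { D[i][j] = d; P[i][j] = 'm'; }
      else if (del <= ins)      { D[i][j] = del; P[i][j] = 'd'; }
      else                      { D[i][j] = ins; P[i][j] = 'i'; }
    }
  }
  int best_m = 0;
  double best = std::numeric_limits<double>::infinity();
  for (int m = 1; m <= mmax; ++m) {
    double c = D[n][(long)m * p];
    if (c < best - 1e-12) { best = c; best_m = m; }
  }
  if (best_m < 1) return List::create(_["m"] = 0);
  // traceback: record, for every consumed s position, which copy it belongs to
  std::vector<int> unit_of(n + 1, 0);
  int i = n;
  long j = (long)best_m * p;
  while (i > 0 || j > 0) {
    char q = P[i][j];
    if (q == 'm')      { unit_of[i] = (int)((j - 1) / p) + 1; --i; --j; }
    else if (q == 'd') { unit_of[i] = (int)((j > 0 ? (j - 1) : 0) / p) + 1; --i; }
    else               { --j; }
  }
  IntegerVector starts(best_m, NA_INTEGER);
  for (int pos = 1; pos <= n; ++pos) {
    int u = unit_of[pos];
    if (u >= 1 && u <= best_m && starts[u - 1] == NA_INTEGER)
      starts[u - 1] = pos;
  }
  return List::create(_["m"] = best_m, _["cost"] = best,
                      _["starts"] = starts);
}

// Scan one sequence block for homologous gapped q-gram pairs.  For every
// shape and every start position i, the next h_next positions j > i carrying
// a homologous gram are recorded as hits (i, k = j - i, shape).  Hits are
// emitted in scan order: outer loop over i, inner over shapes, then
// increasing j — the order the anti-smear queue consumes them in.
// zok is a symmetric logical matrix: zok[a,b] is true when residues a and b
// are mutually within ranking z of each other; the X row is all false, so a
// gram touching X never matches anything (including itself).
// [[Rcpp::export]]
List scan_block_cpp(IntegerVector seq, List shapes, int h_next,
                    LogicalMatrix zok, int x_code) {
  const int n = seq.size(), ns = shapes.size();
  std::vector<std::vector<int> > off(ns);
  std::vector<int> span(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector o = shapes[s];
    off[s] = as<std::vector<int> >(o);
    span[s] = off[s].back();
  }
  std::vector<int> hp, hk, hs;
  const int* sq = INTEGER(seq);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < ns; ++s) {
      if (i + span[s] >= n) continue;
      const std::vector<int>& o = off[s];
      const int q = (int)o.size();
      int found = 0;
      for (int j = i + 1; j + span[s] < n; ++j) {
        int diff = -1;
        bool ok = true;
        for (int t = 0; t < q; ++t) {
          int a = sq[i + o[t]], b = sq[j + o[t]];
          if (a == b && a != x_code) continue;
          if (diff >= 0) { ok = false; break; }
          diff = t;
        }
        if (ok && diff >= 0) {
          if (q < 3) ok = false;  // 2-grams require both positions identical
          else {
            int a = sq[i + o[diff]], b = sq[j + o[diff]];
            ok = (a != x_code && b != x_code && zok(a - 1, b - 1) && zok(b - 1, a - 1));
          }
        }
        if (ok) {
          hp.push_back(i + 1);  // 1-based for R
          hk.push_back(j - i);
          hs.push_back(s + 1);
          if (++found == h_next) break;
        }
      }
    }
  }
  return List::create(_["pos"] = wrap(hp), _["k"] = wrap(hk),
                      _["shape"] = wrap(hs));
}

// Anti-smear weight accumulation over a scan-ordered hit stream, grouped by
// probe.  Mirrors the R-level anti_smear_update() semantics exactly: all
// increments for one probe are evaluated against the queue state before that
// probe's enqueues, then the queue keeps the last H detected distances.
// probe_id must be non-decreasing.
// [[Rcpp::export]]
NumericVector weight_accumulate_cpp(IntegerVector probe_id, IntegerVector ks,
                                    int H, int max_k) {
  NumericVector w0(max_k);
  std::vector<int> Q;
  Q.reserve(H);
  const int n = ks.size();
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && probe_id[j] == probe_id[i]) ++j;
    for (int m = i; m < j; ++m) {
      int kg = ks[m];
      // extended-precision accumulation, matching R's sum()
      long double inc = 0.0L;
      for (size_t t = 0; t < Q.size(); ++t)
        inc += std::pow(2.0, -std::abs(kg - Q[t]));
      if (kg >= 1 && kg <= max_k) w0[kg - 1] += (double)inc;
    }
    for (int m = i; m < j; ++m) Q.push_back(ks[m]);
    if ((int)Q.size() > H) Q.erase(Q.begin(), Q.end() - H);
    i = j;
  }
  return w0;
}
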