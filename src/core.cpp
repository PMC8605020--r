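#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) between a query and a reference.
// A gap run of length L costs gap_open + gap_extend * L, i.e. the first gap
// character already pays the opening penalty. Sequences arrive as 1-based
// indices into `submat`. Traceback tie order is fixed: diagonal, then gap in
// query (consume reference), then gap in reference (consume query), so the
// reported alignment is deterministic.
//
// States: M = column aligns q[i] to r[j]; GQ = column is a gap in the query
// (consumes r[j]); GR = column is a gap in the reference (consumes q[i]).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector q, IntegerVector r, NumericMatrix submat,
                   double gap_open, double gap_extend) {
  const int n = q.size(), m = r.size();
  const double go = gap_open + gap_extend, ge = gap_extend;

  NumericMatrix M(n + 1, m + 1), GQ(n + 1, m + 1), GR(n + 1, m + 1);
  // pointer codes: 0 = came from M, 1 = from GQ, 2 = from GR, -1 = unset
  IntegerMatrix PM(n + 1, m + 1), PQ(n + 1, m + 1), PR(n + 1, m + 1);

  M(0, 0) = 0.0; GQ(0, 0) = NEG_INF; GR(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; GR(0, j) = NEG_INF;
    GQ(0, j) = -(gap_open + ge * j);
    PQ(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; GQ(i, 0) = NEG_INF;
    GR(i, 0) = -(gap_open + ge * i);
    PR(i, 0) = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = submat(q[i - 1] - 1, r[j - 1] - 1);
      // M: predecessor at (i-1, j-1); precedence M > GQ > GR
      double best = M(i - 1, j - 1); int ptr = 0;
      if (GQ(i - 1, j - 1) > best) { best = GQ(i - 1, j - 1); ptr = 1; }
      if (GR(i - 1, j - 1) > best) { best = GR(i - 1, j - 1); ptr = 2; }
      M(i, j) = best + s; PM(i, j) = ptr;
      // GQ: gap in query, predecessor at (i, j-1)
      best = M(i, j - 1) - go; ptr = 0;
      if (GQ(i, j - 1) - ge > best) { best = GQ(i, j - 1) - ge; ptr = 1; }
      if (GR(i, j - 1) - go > best) { best = GR(i, j - 1) - go; ptr = 2; }
      GQ(i, j) = best; PQ(i, j) = ptr;
      // GR: gap in reference, predecessor at (i-1, j)
      best = M(i - 1, j) - go; ptr = 0;
      if (GQ(i - 1, j) - go > best) { best = GQ(i - 1, j) - go; ptr = 1; }
      if (GR(i - 1, j) - ge > best) { best = GR(i - 1, j) - ge; ptr = 2; }
      GR(i, j) = best; PR(i, j) = ptr;
    }
  }

  double score = M(n, m); int state = 0;
  if (GQ(n, m) > score) { score = GQ(n, m); state = 1; }
  if (GR(n, m) > score) { score = GR(n, m); state = 2; }

  // traceback; emit columns back-to-front as (query index | 0, ref index | 0)
  std::vector<int> qa, ra;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {        // diagonal column
      qa.push_back(i); ra.push_back(j);
      state = PM(i, j); --i; --j;
    } else if (state == 1) { // gap in query
      qa.push_back(0); ra.push_back(j);
      state = PQ(i, j); --j;
    } else {                 // gap in reference
      qa.push_back(i); ra.push_back(0);
      state = PR(i, j); --i;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());

  return List::create(_["score"] = score,
                      _["query_idx"] = wrap(qa),
                      _["ref_idx"] = wrap(ra));
}

// Brute-force oracle: enumerate every global alignment (all interleavings of
// diagonal / gap-in-query / gap-in-reference columns, no gap-gap column) and
// return the maximum affine score. Deliberately independent of the DP above;
// only feasible for short sequences.
struct EnumCtx {
  const int *q, *r; int n, m;
  const double *sm; int nrow;
  double go, ge; double best;
};

static void enum_rec(EnumCtx &ctx, int i, int j, int last, double acc) {
  if (i == ctx.n && j == ctx.m) {
    if (acc > ctx.best) ctx.best = acc;
    return;
  }
  if (i < ctx.n && j < ctx.m) {
    double s = ctx.sm[(ctx.q[i] - 1) + ctx.nrow * (ctx.r[j] - 1)];
    enum_rec(ctx, i + 1, j + 1, 0, acc + s);
  }
  if (j < ctx.m) { // gap in query
    double c = ctx.ge + (last == 1 ? 0.0 : ctx.go);
    enum_rec(ctx, i, j + 1, 1, acc - c);
  }
  if (i < ctx.n) { // gap in reference
    double c = ctx.ge + (last == 2 ? 0.0 : ctx.go);
    enum_rec(ctx, i + 1, j, 2, acc - c);
  }
}

// [[Rcpp::export]]
double enum_align_score_cpp(IntegerVector q, IntegerVector r,
                            NumericMatrix submat,
                            double gap_open, double gap_extend) {
  EnumCtx ctx;
  ctx.q = INTEGER(q); ctx.r = INTEGER(r);
  ctx.n = q.size(); ctx.m = r.size();
  ctx.sm = REAL(submat); ctx.nrow = submat.nrow();
  ctx.go = gap_open; ctx.ge = gap_extend;
  ctx.best = NEG_INF;
  enum_rec(ctx, 0, 0, -1, 0.0);
  return ctx.best;
}

// Ungapped scan of a position-specific scoring profile along a protein.
// `profile` is alphabet x columns (bits); `prot` holds 1-based alphabet
// indices, 0 for unknown residues (scored 0 bits). Returns the best placement
// sum and its 1-based start; ties go to the smallest start. Proteins shorter
// than the profile admit no placement.
// [[Rcpp::export]]
List pssm_scan_cpp(IntegerVector prot, NumericMatrix profile) {
  const int n = prot.size(), L = profile.ncol();
  if (n < L)
    return List::create(_["score"] = NA_REAL, _["start"] = NA_INTEGER,
                        _["n_placements"] = 0);
  const int np = n - L + 1;
  double best = NEG_INF; int best_start = 1;
  for (int s = 0; s < np; ++s) {
    double acc = 0.0;
    for (int j = 0; j < L; ++j) {
      int a = prot[s + j];
      if (a > 0) acc += profile(a - 1, j);
    }
    if (acc > best) { best = acc; best_start = s + 1; }
  }
  return List::create(_["score"] = best, _["start"] = best_start,
                      _["n_placements"] = np);
}
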