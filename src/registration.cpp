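// Compiled core: RSIF construction/ranking, interval bounds, and the two
// best-first branch-and-bound searches (translation over R^3, rotation over
// the axis-angle ball). All angles are radians; all indices crossing the R
// boundary are 1-based.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline double clamp11(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

static inline double norm3(const double* u) {
  return std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
}

// angular distance between two nonzero 3-vectors; NaN if either is zero
static inline double ang3(const double* u, const double* v) {
  double nu = norm3(u), nv = norm3(v);
  if (nu <= 0.0 || nv <= 0.0) return NA_REAL;
  return std::acos(clamp11((u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv)));
}

// [[Rcpp::export]]
double cpp_angular_distance(NumericVector u, NumericVector v) {
  return ang3(REAL(u), REAL(v));
}

// ---------------------------------------------------------------------------
// RSIF construction
// ---------------------------------------------------------------------------

// Canonical order of a point triple: sort so the side length opposite each
// point is ascending; ties broken by the sorted pair of adjacent side
// lengths, then by original position (stable).
struct CanonKey {
  double opp, adj_lo, adj_hi;
  int pos;
};

static void canonical_perm(const double pts[3][3], int perm[3]) {
  double d01 = 0, d02 = 0, d12 = 0;
  for (int k = 0; k < 3; ++k) {
    double a = pts[0][k] - pts[1][k];
    double b = pts[0][k] - pts[2][k];
    double c = pts[1][k] - pts[2][k];
    d01 += a * a; d02 += b * b; d12 += c * c;
  }
  d01 = std::sqrt(d01); d02 = std::sqrt(d02); d12 = std::sqrt(d12);
  CanonKey keys[3] = {
    {d12, std::min(d01, d02), std::max(d01, d02), 0},
    {d02, std::min(d01, d12), std::max(d01, d12), 1},
    {d01, std::min(d02, d12), std::max(d02, d12), 2}};
  std::stable_sort(keys, keys + 3, [](const CanonKey& a, const CanonKey& b) {
    if (a.opp != b.opp) return a.opp < b.opp;
    if (a.adj_lo != b.adj_lo) return a.adj_lo < b.adj_lo;
    if (a.adj_hi != b.adj_hi) return a.adj_hi < b.adj_hi;
    return a.pos < b.pos;
  });
  for (int k = 0; k < 3; ++k) perm[k] = keys[k].pos;
}

// p: pairwise angles of the position vectors; g: pairwise angles of the
// difference vectors (x1-x2, x1-x3, x2-x3). Returns false when degenerate
// (zero-norm position or difference vector, or any g component within
// tol_collinear of 0 or pi).
static bool triple_feature(const double pts[3][3], double tol_norm,
                           double tol_collinear, double p[3], double g[3]) {
  for (int i = 0; i < 3; ++i)
    if (norm3(pts[i]) < tol_norm) return false;
  double d12[3], d13[3], d23[3];
  for (int k = 0; k < 3; ++k) {
    d12[k] = pts[0][k] - pts[1][k];
    d13[k] = pts[0][k] - pts[2][k];
    d23[k] = pts[1][k] - pts[2][k];
  }
  if (norm3(d12) < tol_norm || norm3(d13) < tol_norm || norm3(d23) < tol_norm)
    return false;
  p[0] = ang3(pts[0], pts[1]);
  p[1] = ang3(pts[0], pts[2]);
  p[2] = ang3(pts[1], pts[2]);
  g[0] = ang3(d12, d13);
  g[1] = ang3(d12, d23);
  g[2] = ang3(d13, d23);
  for (int k = 0; k < 3; ++k)
    if (g[k] < tol_collinear || g[k] > M_PI - tol_collinear) return false;
  return true;
}

static void gather_triple(const NumericMatrix& pts, const int idx[3],
                          double out[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k) out[i][k] = pts(idx[i], k);
}

// Features for explicitly given triples (rows of `triples`, 1-based).
// [[Rcpp::export]]
List cpp_triple_features(NumericMatrix pts, IntegerMatrix triples,
                         double tol_norm, double tol_collinear) {
  int m = triples.nrow();
  IntegerMatrix idx(m, 3);
  NumericMatrix p(m, 3), g(m, 3);
  LogicalVector ok(m);
  for (int r = 0; r < m; ++r) {
    int raw[3] = {triples(r, 0) - 1, triples(r, 1) - 1, triples(r, 2) - 1};
    double tri[3][3];
    gather_triple(pts, raw, tri);
    int perm[3];
    canonical_perm(tri, perm);
    double ord[3][3];
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) ord[i][k] = tri[perm[i]][k];
    double pv[3], gv[3];
    bool keep = triple_feature(ord, tol_norm, tol_collinear, pv, gv);
    ok[r] = keep;
    for (int k = 0; k < 3; ++k) {
      idx(r, k) = raw[perm[k]] + 1;
      p(r, k) = keep ? pv[k] : NA_REAL;
      g(r, k) = keep ? gv[k] : NA_REAL;
    }
  }
  return List::create(_["idx"] = idx, _["p"] = p, _["g"] = g, _["ok"] = ok);
}

// Enumerate all C(n,3) index triples, or a seeded uniform sample of `cap`
// distinct ones (uses R's RNG; caller sets the seed).
// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_triples(int n, double cap) {
  double total = (double)n * (n - 1) * (n - 2) / 6.0;
  if (total <= cap) {
    int m = (int)(total + 0.5);
    IntegerMatrix out(m, 3);
    int r = 0;
    for (int i = 0; i < n - 2; ++i)
      for (int j = i + 1; j < n - 1; ++j)
        for (int k = j + 1; k < n; ++k) {
          out(r, 0) = i + 1; out(r, 1) = j + 1; out(r, 2) = k + 1;
          ++r;
        }
    return out;
  }
  int m = (int)cap;
  IntegerMatrix out(m, 3);
  std::unordered_set<int64_t> seen;
  seen.reserve((size_t)(m * 1.4));
  int r = 0;
  while (r < m) {
    int a = (int)(unif_rand() * n);
    int b = (int)(unif_rand() * n);
    int c = (int)(unif_rand() * n);
    if (a >= n) a = n - 1;
    if (b >= n) b = n - 1;
    if (c >= n) c = n - 1;
    if (a == b || a == c || b == c) continue;
    int i = std::min({a, b, c}), k = std::max({a, b, c});
    int j = a + b + c - i - k;
    int64_t key = ((int64_t)i * n + j) * n + k;
    if (!seen.insert(key).second) continue;
    out(r, 0) = i + 1; out(r, 1) = j + 1; out(r, 2) = k + 1;
    ++r;
  }
  return out;
}

// Enumerate (or sample) triples, drop degenerate ones, rank by the sum of the
// three difference-angle components, and return the top `k` features with
// canonically ordered indices. Single pass; only scores are stored for the
// full enumeration.
// [[Rcpp::export]]
List cpp_rsif_topk(NumericMatrix pts, double cap, int topk, double tol_norm,
                   double tol_collinear) {
  int n = pts.nrow();
  IntegerMatrix triples = cpp_enumerate_triples(n, cap);
  int m = triples.nrow();
  std::vector<double> score(m, -1.0);
  int n_ok = 0;
  for (int r = 0; r < m; ++r) {
    int raw[3] = {triples(r, 0) - 1, triples(r, 1) - 1, triples(r, 2) - 1};
    double tri[3][3];
    gather_triple(pts, raw, tri);
    int perm[3];
    canonical_perm(tri, perm);
    double ord[3][3];
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) ord[i][k] = tri[perm[i]][k];
    double pv[3], gv[3];
    if (triple_feature(ord, tol_norm, tol_collinear, pv, gv)) {
      score[r] = gv[0] + gv[1] + gv[2];
      ++n_ok;
    }
  }
  std::vector<int> order;
  order.reserve(n_ok);
  for (int r = 0; r < m; ++r)
    if (score[r] >= 0) order.push_back(r);
  int keep = std::min<int>(topk, (int)order.size());
  auto cmp = [&](int a, int b) {
    if (score[a] != score[b]) return score[a] > score[b];
    for (int k = 0; k < 3; ++k)
      if (triples(a, k) != triples(b, k)) return triples(a, k) < triples(b, k);
    return a < b;
  };
  std::partial_sort(order.begin(), order.begin() + keep, order.end(), cmp);

  IntegerMatrix idx(keep, 3);
  NumericMatrix p(keep, 3), g(keep, 3);
  NumericVector sc(keep);
  for (int out = 0; out < keep; ++out) {
    int r = order[out];
    int raw[3] = {triples(r, 0) - 1, triples(r, 1) - 1, triples(r, 2) - 1};
    double tri[3][3];
    gather_triple(pts, raw, tri);
    int perm[3];
    canonical_perm(tri, perm);
    double ord3[3][3];
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) ord3[i][k] = tri[perm[i]][k];
    double pv[3], gv[3];
    triple_feature(ord3, tol_norm, tol_collinear, pv, gv);
    for (int k = 0; k < 3; ++k) {
      idx(out, k) = raw[perm[k]] + 1;
      p(out, k) = pv[k];
      g(out, k) = gv[k];
    }
    sc[out] = score[r];
  }
  return List::create(_["idx"] = idx, _["p"] = p, _["g"] = g,
                      _["score"] = sc, _["n_enumerated"] = m,
                      _["n_nondegenerate"] = n_ok);
}

// All (i, j) with ||gP[i,] - gQ[j,]|| <= eps_f. 1-based rows.
// [[Rcpp::export]]
IntegerMatrix cpp_screen_pairs(NumericMatrix gP, NumericMatrix gQ,
                               double eps_f) {
  int m = gP.nrow(), n = gQ.nrow();
  double e2 = eps_f * eps_f;
  std::vector<int> pi, qi;
  for (int i = 0; i < m; ++i) {
    double a = gP(i, 0), b = gP(i, 1), c = gP(i, 2);
    for (int j = 0; j < n; ++j) {
      double d0 = a - gQ(j, 0), d1 = b - gQ(j, 1), d2 = c - gQ(j, 2);
      if (d0 * d0 + d1 * d1 + d2 * d2 <= e2) {
        pi.push_back(i + 1);
        qi.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    out(r, 0) = pi[r];
    out(r, 1) = qi[r];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Translation search: objective, interval bounds, BnB
// ---------------------------------------------------------------------------

// F(p, t): pairwise angles of the translated source triple. Points given as
// a 9-vector (three canonical points, row-major). NaN components signal a
// degenerate translation (a translated point at the origin).
static inline void eval_F9(const double* p9, const double* t, double out[3]) {
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = p9[k] + t[k];
    b[k] = p9[3 + k] + t[k];
    c[k] = p9[6 + k] + t[k];
  }
  out[0] = ang3(a, b);
  out[1] = ang3(a, c);
  out[2] = ang3(b, c);
}

// [[Rcpp::export]]
NumericVector cpp_eval_F(NumericVector p9, NumericVector t) {
  double out[3];
  eval_F9(REAL(p9), REAL(t), out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// Uncertainty angle bound beta(x, T) for a cube centered at t0 with half
// space diagonal delta.
static inline double beta_bound_c(const double* x, const double* t0,
                                  double delta) {
  double v[3] = {x[0] + t0[0], x[1] + t0[1], x[2] + t0[2]};
  double nv = norm3(v);
  if (nv <= 0.0) return M_PI;
  if (delta <= nv) return std::asin(delta / nv);
  return M_PI;
}

// [[Rcpp::export]]
double cpp_beta_bound(NumericVector x, NumericVector t0, double delta) {
  return beta_bound_c(REAL(x), REAL(t0), delta);
}

static inline void angle_interval_c(const double* x1, const double* x2,
                                    const double* t0, double delta,
                                    double* lo, double* hi) {
  double a[3] = {x1[0] + t0[0], x1[1] + t0[1], x1[2] + t0[2]};
  double b[3] = {x2[0] + t0[0], x2[1] + t0[1], x2[2] + t0[2]};
  double ctr = ang3(a, b);
  if (ISNAN(ctr)) {  // degenerate center: no information
    *lo = 0.0;
    *hi = M_PI;
    return;
  }
  double bsum = beta_bound_c(x1, t0, delta) + beta_bound_c(x2, t0, delta);
  *lo = std::max(ctr - bsum, 0.0);
  *hi = std::min(ctr + bsum, M_PI);
}

// [[Rcpp::export]]
NumericVector cpp_angle_interval(NumericVector x1, NumericVector x2,
                                 NumericVector t0, double delta) {
  double lo, hi;
  angle_interval_c(REAL(x1), REAL(x2), REAL(t0), delta, &lo, &hi);
  return NumericVector::create(lo, hi);
}

// Component intervals of F(p, t) over the cube, as 3 x (lo, hi).
static inline void F_intervals(const double* p9, const double* t0,
                               double delta, double lo[3], double hi[3]) {
  angle_interval_c(p9, p9 + 3, t0, delta, &lo[0], &hi[0]);
  angle_interval_c(p9, p9 + 6, t0, delta, &lo[1], &hi[1]);
  angle_interval_c(p9 + 3, p9 + 6, t0, delta, &lo[2], &hi[2]);
}

static inline double dlb_from_intervals(const double lo[3], const double hi[3],
                                        const double* q) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double gap = 0.0;
    if (q[k] < lo[k]) gap = lo[k] - q[k];
    else if (q[k] > hi[k]) gap = q[k] - hi[k];
    s += gap * gap;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
double cpp_distance_lower_bound(NumericVector p9, NumericVector q,
                                NumericVector t0, double delta) {
  double lo[3], hi[3];
  F_intervals(REAL(p9), REAL(t0), delta, lo, hi);
  return dlb_from_intervals(lo, hi, REAL(q));
}

// Per-feature candidate lists: qlist[i] holds the 0-based rows of Q that
// feature i may match (screened candidates), or all rows when unrestricted.
typedef std::vector<std::vector<int> > QLists;

// row-major copy of an Rcpp matrix (R stores column-major)
static std::vector<double> rowmajor(const NumericMatrix& m) {
  std::vector<double> out((size_t)m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      out[(size_t)i * m.ncol() + j] = m(i, j);
  return out;
}

static QLists make_qlists(List qlist, int M, int N) {
  QLists out(M);
  if (qlist.size() == 0) {
    for (int i = 0; i < M; ++i) {
      out[i].resize(N);
      for (int j = 0; j < N; ++j) out[i][j] = j;
    }
    return out;
  }
  for (int i = 0; i < M; ++i) {
    IntegerVector v = qlist[i];
    out[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < out[i].size(); ++k) out[i][k] -= 1;  // to 0-based
  }
  return out;
}

static int objective_Et_c(const std::vector<double>& P,
                          const std::vector<double>& Q, const QLists& ql,
                          const double* t, double eps_t) {
  int M = (int)(P.size() / 9);
  double e2 = eps_t * eps_t;
  int cnt = 0;
  for (int i = 0; i < M; ++i) {
    double f[3];
    eval_F9(&P[(size_t)i * 9], t, f);
    if (ISNAN(f[0]) || ISNAN(f[1]) || ISNAN(f[2])) continue;
    for (size_t k = 0; k < ql[i].size(); ++k) {
      const double* q = &Q[(size_t)ql[i][k] * 3];
      double d0 = f[0] - q[0], d1 = f[1] - q[1], d2 = f[2] - q[2];
      if (d0 * d0 + d1 * d1 + d2 * d2 <= e2) {
        ++cnt;
        break;
      }
    }
  }
  return cnt;
}

static int upper_bound_Et_c(const std::vector<double>& P,
                            const std::vector<double>& Q, const QLists& ql,
                            const double* t0, double delta, double eps_t) {
  int M = (int)(P.size() / 9);
  int cnt = 0;
  for (int i = 0; i < M; ++i) {
    double lo[3], hi[3];
    F_intervals(&P[(size_t)i * 9], t0, delta, lo, hi);
    for (size_t k = 0; k < ql[i].size(); ++k) {
      if (dlb_from_intervals(lo, hi, &Q[(size_t)ql[i][k] * 3]) <= eps_t) {
        ++cnt;
        break;
      }
    }
  }
  return cnt;
}

// Ppts: M x 9 canonical triple coordinates; Q: N x 3 reference angle triples.
// qlist: per-feature candidate Q rows (1-based), or empty list for all-vs-all.
// [[Rcpp::export]]
int cpp_objective_Et(NumericMatrix Ppts, NumericMatrix Q, List qlist,
                     NumericVector t, double eps_t) {
  QLists ql = make_qlists(qlist, Ppts.nrow(), Q.nrow());
  return objective_Et_c(rowmajor(Ppts), rowmajor(Q), ql, REAL(t), eps_t);
}

// [[Rcpp::export]]
int cpp_upper_bound_Et(NumericMatrix Ppts, NumericMatrix Q, List qlist,
                       NumericVector t0, double half_side, double eps_t) {
  QLists ql = make_qlists(qlist, Ppts.nrow(), Q.nrow());
  double delta = half_side * std::sqrt(3.0);
  return upper_bound_Et_c(rowmajor(Ppts), rowmajor(Q), ql, REAL(t0), delta,
                          eps_t);
}

struct BnBNode {
  double ub;
  double hs;
  double c[3];
  int64_t id;
};

struct NodeCmp {  // max-heap: higher ub first, then larger cube, then FIFO
  bool operator()(const BnBNode& a, const BnBNode& b) const {
    if (a.ub != b.ub) return a.ub < b.ub;
    if (a.hs != b.hs) return a.hs < b.hs;
    return a.id > b.id;
  }
};

// Best-first branch and bound for the translation consensus objective.
// [[Rcpp::export]]
List cpp_bnb_translation(NumericMatrix Ppts, NumericMatrix Q, List qlist,
                         NumericVector center, double half_side,
                         double eps_t, double min_half_side,
                         double max_nodes, double time_limit) {
  QLists ql = make_qlists(qlist, Ppts.nrow(), Q.nrow());
  int M = Ppts.nrow();
  std::vector<double> P = rowmajor(Ppts);
  std::vector<double> Qv = rowmajor(Q);
  std::priority_queue<BnBNode, std::vector<BnBNode>, NodeCmp> pq;
  int64_t next_id = 0;
  double sqrt3 = std::sqrt(3.0);

  BnBNode root;
  root.hs = half_side;
  for (int k = 0; k < 3; ++k) root.c[k] = center[k];
  root.ub = upper_bound_Et_c(P, Qv, ql, root.c, root.hs * sqrt3, eps_t);
  root.id = next_id++;
  pq.push(root);

  int best = -1;
  double best_t[3] = {center[0], center[1], center[2]};
  double nodes = 0;
  bool hit_resolution = false, timed_out = false;
  std::string reason = "queue_exhausted";
  clock_t start = clock();

  while (!pq.empty()) {
    BnBNode nd = pq.top();
    pq.pop();
    if (nd.ub <= best) {
      reason = "gap_closed";
      break;
    }
    nodes += 1;
    if (((int64_t)nodes & 63) == 0) {
      Rcpp::checkUserInterrupt();
      if ((double)(clock() - start) / CLOCKS_PER_SEC > time_limit) {
        timed_out = true;
        reason = "timed_out";
        break;
      }
    }
    if (nodes > max_nodes) {
      timed_out = true;
      reason = "node_budget";
      break;
    }
    int val = objective_Et_c(P, Qv, ql, nd.c, eps_t);
    if (val > best) {
      best = val;
      for (int k = 0; k < 3; ++k) best_t[k] = nd.c[k];
      if (best >= M) {  // objective cannot exceed M; certificate immediate
        reason = "gap_closed";
        break;
      }
    }
    double chs = nd.hs / 2.0;
    if (chs < min_half_side) {
      hit_resolution = true;
      continue;
    }
    for (int oct = 0; oct < 8; ++oct) {
      BnBNode ch;
      ch.hs = chs;
      ch.c[0] = nd.c[0] + ((oct & 1) ? chs : -chs);
      ch.c[1] = nd.c[1] + ((oct & 2) ? chs : -chs);
      ch.c[2] = nd.c[2] + ((oct & 4) ? chs : -chs);
      ch.ub = upper_bound_Et_c(P, Qv, ql, ch.c, chs * sqrt3, eps_t);
      if (ch.ub > best) {
        ch.id = next_id++;
        pq.push(ch);
      }
    }
  }
  if (reason == "queue_exhausted" && hit_resolution) reason = "resolution_reached";
  double remaining_ub = pq.empty() ? (double)best : pq.top().ub;
  return List::create(
      _["t"] = NumericVector::create(best_t[0], best_t[1], best_t[2]),
      _["consensus"] = best, _["nodes_expanded"] = nodes,
      _["termination"] = reason, _["remaining_upper_bound"] = remaining_ub,
      _["timed_out"] = timed_out);
}

// ---------------------------------------------------------------------------
// Rotation search
// ---------------------------------------------------------------------------

static void rodrigues(const double* r, double R[3][3]) {
  double th = norm3(r);
  if (th < 1e-14) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = (i == j) ? 1.0 : 0.0;
    return;
  }
  double kx = r[0] / th, ky = r[1] / th, kz = r[2] / th;
  double ct = std::cos(th), st = std::sin(th), v = 1.0 - ct;
  R[0][0] = ct + kx * kx * v;
  R[0][1] = kx * ky * v - kz * st;
  R[0][2] = kx * kz * v + ky * st;
  R[1][0] = ky * kx * v + kz * st;
  R[1][1] = ct + ky * ky * v;
  R[1][2] = ky * kz * v - kx * st;
  R[2][0] = kz * kx * v - ky * st;
  R[2][1] = kz * ky * v + kx * st;
  R[2][2] = ct + kz * kz * v;
}

// [[Rcpp::export]]
NumericMatrix cpp_axis_angle_to_matrix(NumericVector r) {
  double R[3][3];
  rodrigues(REAL(r), R);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = R[i][j];
  return out;
}

// Consensus count with angular threshold `th` (radians) at rotation r.
// Xd, Yd are unit direction matrices (rows).
static int consensus_rot(const NumericMatrix& Xd, const NumericMatrix& Yd,
                         const double* r, double th) {
  double R[3][3];
  rodrigues(r, R);
  int n = Xd.nrow(), m = Yd.nrow();
  double cth = (th >= M_PI) ? -1.0 : std::cos(th);
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    double x0 = Xd(i, 0), x1 = Xd(i, 1), x2 = Xd(i, 2);
    double z0 = R[0][0] * x0 + R[0][1] * x1 + R[0][2] * x2;
    double z1 = R[1][0] * x0 + R[1][1] * x1 + R[1][2] * x2;
    double z2 = R[2][0] * x0 + R[2][1] * x1 + R[2][2] * x2;
    for (int j = 0; j < m; ++j) {
      if (z0 * Yd(j, 0) + z1 * Yd(j, 1) + z2 * Yd(j, 2) >= cth) {
        ++cnt;
        break;
      }
    }
  }
  return cnt;
}

// [[Rcpp::export]]
int cpp_objective_Er(NumericMatrix Xdir, NumericMatrix Ydir, NumericVector r,
                     double eps_r) {
  return consensus_rot(Xdir, Ydir, REAL(r), eps_r);
}

// [[Rcpp::export]]
int cpp_upper_bound_Er(NumericMatrix Xdir, NumericMatrix Ydir,
                       NumericVector r_center, double half_side,
                       double eps_r) {
  double mu = std::min(half_side * std::sqrt(3.0), M_PI);
  return consensus_rot(Xdir, Ydir, REAL(r_center),
                       std::min(eps_r + mu, M_PI));
}

// Best-first BnB over the axis-angle cube [-pi, pi]^3; cubes wholly outside
// the pi-ball are discarded. `exclude` (k x 3 axis-angle rows) removes
// geodesic balls of radius `exclude_radius` around previously rejected
// rotations: a cube is dropped when it lies entirely inside a ball
// (center distance + cube uncertainty <= radius), and centers inside a
// ball never become incumbents.
// [[Rcpp::export]]
List cpp_bnb_rotation(NumericMatrix Xdir, NumericMatrix Ydir, double eps_r,
                      double min_half_side, double max_nodes,
                      double time_limit, NumericMatrix exclude,
                      double exclude_radius) {
  int n = Xdir.nrow();
  int n_ex = exclude.nrow();
  std::vector<double> exR((size_t)n_ex * 9);
  for (int e = 0; e < n_ex; ++e) {
    double r[3] = {exclude(e, 0), exclude(e, 1), exclude(e, 2)};
    double R[3][3];
    rodrigues(r, R);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) exR[e * 9 + i * 3 + j] = R[i][j];
  }
  // geodesic distance from the rotation at c to the nearest excluded one
  auto min_excl_dist = [&](const double* c) -> double {
    double Rc[3][3];
    rodrigues(c, Rc);
    double best = R_PosInf;
    for (int e = 0; e < n_ex; ++e) {
      double tr = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) tr += Rc[i][j] * exR[e * 9 + i * 3 + j];
      double d = std::acos(clamp11((tr - 1.0) / 2.0));
      if (d < best) best = d;
    }
    return best;
  };
  std::priority_queue<BnBNode, std::vector<BnBNode>, NodeCmp> pq;
  int64_t next_id = 0;
  double sqrt3 = std::sqrt(3.0);

  BnBNode root;
  root.hs = M_PI;
  root.c[0] = root.c[1] = root.c[2] = 0.0;
  root.ub = n;  // mu >= pi at the root: bound is vacuous there
  root.id = next_id++;
  pq.push(root);

  int best = -1;
  double best_r[3] = {0, 0, 0};
  double nodes = 0;
  bool hit_resolution = false, timed_out = false;
  std::string reason = "queue_exhausted";
  clock_t start = clock();

  while (!pq.empty()) {
    BnBNode nd = pq.top();
    pq.pop();
    if (nd.ub <= best) {
      reason = "gap_closed";
      break;
    }
    nodes += 1;
    if (((int64_t)nodes & 63) == 0) {
      Rcpp::checkUserInterrupt();
      if ((double)(clock() - start) / CLOCKS_PER_SEC > time_limit) {
        timed_out = true;
        reason = "timed_out";
        break;
      }
    }
    if (nodes > max_nodes) {
      timed_out = true;
      reason = "node_budget";
      break;
    }
    bool center_ok = n_ex == 0 || min_excl_dist(nd.c) > exclude_radius;
    if (center_ok) {
      int val = consensus_rot(Xdir, Ydir, nd.c, eps_r);
      if (val > best) {
        best = val;
        for (int k = 0; k < 3; ++k) best_r[k] = nd.c[k];
        if (best >= n) {
          reason = "gap_closed";
          break;
        }
      }
    }
    double chs = nd.hs / 2.0;
    if (chs < min_half_side) {
      hit_resolution = true;
      continue;
    }
    for (int oct = 0; oct < 8; ++oct) {
      BnBNode ch;
      ch.hs = chs;
      ch.c[0] = nd.c[0] + ((oct & 1) ? chs : -chs);
      ch.c[1] = nd.c[1] + ((oct & 2) ? chs : -chs);
      ch.c[2] = nd.c[2] + ((oct & 4) ? chs : -chs);
      if (norm3(ch.c) - chs * sqrt3 > M_PI) continue;  // outside the pi-ball
      double mu = std::min(chs * sqrt3, M_PI);
      // cube entirely inside an excluded ball: drop
      if (n_ex > 0 && min_excl_dist(ch.c) + mu <= exclude_radius) continue;
      ch.ub = consensus_rot(Xdir, Ydir, ch.c, std::min(eps_r + mu, M_PI));
      if (ch.ub > best) {
        ch.id = next_id++;
        pq.push(ch);
      }
    }
  }
  if (reason == "queue_exhausted" && hit_resolution) reason = "resolution_reached";
  double remaining_ub = pq.empty() ? (double)best : pq.top().ub;
  return List::create(
      _["r"] = NumericVector::create(best_r[0], best_r[1], best_r[2]),
      _["consensus"] = best, _["nodes_expanded"] = nodes,
      _["termination"] = reason, _["remaining_upper_bound"] = remaining_ub,
      _["timed_out"] = timed_out);
}

// Angularly nearest reference row for each moving row (on unit directions,
// after rotating by r). Returns 1-based indices and the angles.
// [[Rcpp::export]]
List cpp_nearest_angular(NumericMatrix Xdir, NumericMatrix Ydir,
                         NumericVector r) {
  double R[3][3];
  rodrigues(REAL(r), R);
  int n = Xdir.nrow(), m = Ydir.nrow();
  IntegerVector jbest(n);
  NumericVector abest(n);
  for (int i = 0; i < n; ++i) {
    double x0 = Xdir(i, 0), x1 = Xdir(i, 1), x2 = Xdir(i, 2);
    double z0 = R[0][0] * x0 + R[0][1] * x1 + R[0][2] * x2;
    double z1 = R[1][0] * x0 + R[1][1] * x1 + R[1][2] * x2;
    double z2 = R[2][0] * x0 + R[2][1] * x1 + R[2][2] * x2;
    double bestdot = -2.0;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double d = z0 * Ydir(j, 0) + z1 * Ydir(j, 1) + z2 * Ydir(j, 2);
      if (d > bestdot) {
        bestdot = d;
        bj = j;
      }
    }
    jbest[i] = bj + 1;
    abest[i] = std::acos(clamp11(bestdot));
  }
  return List::create(_["j"] = jbest, _["angle"] = abest);
}
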