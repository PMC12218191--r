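#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Robust-ish orientation sign of the triangle (a, b, c).
// Cross products whose magnitude is below a relative epsilon are treated as
// exactly collinear; the caller decides whether that is degenerate.
static const double REL_EPS = 1e-12;

static inline int orient(double ax, double ay, double bx, double by,
                         double cx, double cy) {
  double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  double scale = (std::abs(bx - ax) + std::abs(by - ay)) *
                 (std::abs(cx - ax) + std::abs(cy - ay));
  if (std::abs(det) <= REL_EPS * scale) return 0;
  return det > 0 ? 1 : -1;
}

// Does [lo1, hi1] overlap [lo2, hi2] on more than a point?
static inline bool interval_overlap(double lo1, double hi1, double lo2,
                                    double hi2) {
  return std::min(hi1, hi2) - std::max(lo1, lo2) > 0;
}

// Classify the pair (p, q) of segments given by endpoint indices.
// Returns 1 = proper crossing, 0 = none, -1 = collinear overlap (degenerate).
// Segments sharing an endpoint never cross.
static inline int pair_cross(const double* x, const double* y, int a1, int a2,
                             int b1, int b2) {
  if (a1 == b1 || a1 == b2 || a2 == b1 || a2 == b2) return 0;
  int o1 = orient(x[a1], y[a1], x[a2], y[a2], x[b1], y[b1]);
  int o2 = orient(x[a1], y[a1], x[a2], y[a2], x[b2], y[b2]);
  int o3 = orient(x[b1], y[b1], x[b2], y[b2], x[a1], y[a1]);
  int o4 = orient(x[b1], y[b1], x[b2], y[b2], x[a2], y[a2]);
  if (o1 == 0 && o2 == 0 && o3 == 0 && o4 == 0) {
    // all four points collinear: degenerate iff the segments overlap
    double lo1 = std::min(x[a1], x[a2]), hi1 = std::max(x[a1], x[a2]);
    double lo2 = std::min(x[b1], x[b2]), hi2 = std::max(x[b1], x[b2]);
    double mlo1 = std::min(y[a1], y[a2]), mhi1 = std::max(y[a1], y[a2]);
    double mlo2 = std::min(y[b1], y[b2]), mhi2 = std::max(y[b1], y[b2]);
    bool span = (hi1 - lo1 > mhi1 - mlo1)
                    ? interval_overlap(lo1, hi1, lo2, hi2)
                    : interval_overlap(mlo1, mhi1, mlo2, mhi2);
    return span ? -1 : 0;
  }
  // proper interior crossing requires strict straddling on both sides;
  // touching (any zero orientation) is not a crossing
  if (o1 * o2 < 0 && o3 * o4 < 0) return 1;
  return 0;
}

struct Seg {
  double xmin, xmax, ymin, ymax;
  int a, b;
};

static std::vector<Seg> make_segs(const NumericVector& x,
                                  const NumericVector& y,
                                  const IntegerMatrix& edges) {
  int L = edges.nrow();
  std::vector<Seg> segs(L);
  for (int e = 0; e < L; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    segs[e].a = a;
    segs[e].b = b;
    segs[e].xmin = std::min(x[a], x[b]);
    segs[e].xmax = std::max(x[a], x[b]);
    segs[e].ymin = std::min(y[a], y[b]);
    segs[e].ymax = std::max(y[a], y[b]);
  }
  return segs;
}

// [[Rcpp::export]]
double cpp_count_crossings_brute(NumericVector x, NumericVector y,
                                 IntegerMatrix edges) {
  int L = edges.nrow();
  const double* px = REAL(x);
  const double* py = REAL(y);
  double count = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      int r = pair_cross(px, py, edges(i, 0) - 1, edges(i, 1) - 1,
                         edges(j, 0) - 1, edges(j, 1) - 1);
      if (r < 0) stop("degenerate geometry: collinear overlapping segments");
      count += r;
    }
  }
  return count;
}

// Sweep over x: segments sorted by left endpoint, an active list pruned by
// right endpoint, candidate pairs rejected early by bounding-box overlap.
// [[Rcpp::export]]
double cpp_count_crossings_sweep(NumericVector x, NumericVector y,
                                 IntegerMatrix edges) {
  int L = edges.nrow();
  const double* px = REAL(x);
  const double* py = REAL(y);
  std::vector<Seg> segs = make_segs(x, y, edges);
  std::sort(segs.begin(), segs.end(),
            [](const Seg& s, const Seg& t) { return s.xmin < t.xmin; });
  std::vector<int> active;
  active.reserve(L);
  double count = 0;
  for (int e = 0; e < L; ++e) {
    const Seg& s = segs[e];
    size_t keep = 0;
    for (size_t k = 0; k < active.size(); ++k) {
      const Seg& t = segs[active[k]];
      if (t.xmax < s.xmin) continue;  // left the sweep window
      active[keep++] = active[k];
      if (t.ymin > s.ymax || t.ymax < s.ymin) continue;
      int r = pair_cross(px, py, s.a, s.b, t.a, t.b);
      if (r < 0) stop("degenerate geometry: collinear overlapping segments");
      count += r;
    }
    active.resize(keep);
    active.push_back(e);
  }
  return count;
}

// Cumulative crossing counts for the prefixes of an edge ranking: entry L is
// the number of crossings among the first L edges. O(L^2) pair tests total.
// [[Rcpp::export]]
NumericVector cpp_crossing_increments(NumericVector x, NumericVector y,
                                      IntegerMatrix edges) {
  int L = edges.nrow();
  const double* px = REAL(x);
  const double* py = REAL(y);
  NumericVector cum(L + 1);
  cum[0] = 0;
  double total = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < i; ++j) {
      int r = pair_cross(px, py, edges(i, 0) - 1, edges(i, 1) - 1,
                         edges(j, 0) - 1, edges(j, 1) - 1);
      if (r < 0) stop("degenerate geometry: collinear overlapping segments");
      total += r;
    }
    cum[i + 1] = total;
  }
  return cum;
}
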