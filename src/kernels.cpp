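#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information between
// two multivariate series, Chebyshev (max-norm) metric in every space.
// I = psi(k) + psi(n) - < psi(nx+1) + psi(ny+1) >
// Brute-force neighbour search with early-exit distance evaluation; n of a
// few thousand per pair is the intended regime.
namespace {

// Compact static k-d tree with Chebyshev metric: median split on the
// widest dimension, points held row-major in a reordered buffer.
struct KdTree {
  int n, d, leaf_size;
  std::vector<double> pts;    // n * d, row-major, tree order
  std::vector<int> idx;       // tree order -> original index (unused by MI)
  struct Node { int lo, hi, dim, left, right; double split; };
  std::vector<Node> nodes;

  KdTree(const std::vector<double> &data, int n_, int d_, int leaf = 16)
      : n(n_), d(d_), leaf_size(leaf), pts(data), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    nodes.reserve(2 * n / leaf_size + 4);
    build(perm, 0, n);
    // reorder points into tree order
    std::vector<double> out(n * d);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < d; ++c) out[i * d + c] = data[perm[i] * d + c];
    pts.swap(out);
    idx = perm;
  }

  int build(std::vector<int> &perm, int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1; nd.dim = -1;
    nd.split = 0.0;
    int me = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= leaf_size) return me;
    // widest dimension over this slab
    int best_dim = 0; double best_w = -1.0;
    for (int c = 0; c < d; ++c) {
      double mn = pts[perm[lo] * d + c], mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = pts[perm[i] * d + c];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx - mn > best_w) { best_w = mx - mn; best_dim = c; }
    }
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid,
                     perm.begin() + hi, [&](int a, int b) {
                       return pts[a * d + best_dim] < pts[b * d + best_dim];
                     });
    nodes[me].dim = best_dim;
    nodes[me].split = pts[perm[mid] * d + best_dim];
    int lc = build(perm, lo, mid);
    int rc = build(perm, mid, hi);
    nodes[me].left = lc;
    nodes[me].right = rc;
    return me;
  }

  // k smallest Chebyshev distances to q (self included if q is a point)
  void knn(const double *q, int k, std::priority_queue<double> &heap) const {
    knn_rec(0, q, k, heap);
  }

  void knn_rec(int node, const double *q, int k,
               std::priority_queue<double> &heap) const {
    const Node &nd = nodes[node];
    const double inf = std::numeric_limits<double>::infinity();
    if (nd.dim < 0) {   // leaf
      for (int i = nd.lo; i < nd.hi; ++i) {
        double bound = ((int)heap.size() == k) ? heap.top() : inf;
        double dist = 0.0;
        const double *p = &pts[i * d];
        for (int c = 0; c < d; ++c) {
          double a = std::fabs(p[c] - q[c]);
          if (a > dist) dist = a;
          if (dist >= bound) break;
        }
        if (dist < bound) {
          if ((int)heap.size() == k) heap.pop();
          heap.push(dist);
        }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    knn_rec(near, q, k, heap);
    double bound = ((int)heap.size() == k) ? heap.top() : inf;
    if (std::fabs(diff) < bound) knn_rec(far, q, k, heap);
  }

  // number of points with Chebyshev distance strictly < eps from q
  int count_within(const double *q, double eps) const {
    return count_rec(0, q, eps);
  }

  int count_rec(int node, const double *q, double eps) const {
    const Node &nd = nodes[node];
    if (nd.dim < 0) {
      int cnt = 0;
      for (int i = nd.lo; i < nd.hi; ++i) {
        double dist = 0.0;
        const double *p = &pts[i * d];
        bool in = true;
        for (int c = 0; c < d; ++c) {
          double a = std::fabs(p[c] - q[c]);
          if (a > dist) dist = a;
          if (dist >= eps) { in = false; break; }
        }
        if (in) ++cnt;
      }
      return cnt;
    }
    double diff = q[nd.dim] - nd.split;
    int cnt = 0;
    if (diff < eps) cnt += count_rec(nd.left, q, eps);
    if (-diff < eps) cnt += count_rec(nd.right, q, eps);
    return cnt;
  }
};

}  // namespace

// [[Rcpp::export]]
double ksg_mi(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow(), dx = x.ncol(), dy = y.ncol();
  if (y.nrow() != n) stop("series length mismatch");
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");

  // row-major copies: joint [x y], and the two marginals
  std::vector<double> xj(n * dx), yj(n * dy), joint(n * (dx + dy));
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dx; ++c) {
      xj[i * dx + c] = x(i, c);
      joint[i * (dx + dy) + c] = x(i, c);
    }
    for (int c = 0; c < dy; ++c) {
      yj[i * dy + c] = y(i, c);
      joint[i * (dx + dy) + dx + c] = y(i, c);
    }
  }
  KdTree tx(xj, n, dx), ty(yj, n, dy), tj(joint, n, dx + dy);

  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *q = &joint[i * (dx + dy)];
    std::priority_queue<double> heap;
    tj.knn(q, k + 1, heap);   // k+1: the query point itself is in the tree
    const double eps = heap.top();
    // counts include the point itself (distance 0 < eps); subtract it
    int nx = tx.count_within(&xj[i * dx], eps);
    int ny = ty.count_within(&yj[i * dy], eps);
    if (eps > 0.0) { --nx; --ny; }
    if (nx < 0) nx = 0;
    if (ny < 0) ny = 0;
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi;
}

// Metropolis sampler for a 1-D coordinate under
//   W(xi) = U(xi) + 0.5 * k_bias * (xi - center)^2
// where U is a quartic double well with minima at m +- a and barrier h:
//   U(xi) = h * ((xi - m)^2 - a^2)^2 / a^4     (h = 0 gives a flat U)
// Uses R's RNG so results follow set.seed(). Returns the thinned chain;
// attribute "acceptance" carries the acceptance rate.
// [[Rcpp::export]]
NumericVector metropolis_biased(int n_keep, int burn_in, int thin,
                                double step, double beta,
                                double h, double m, double a,
                                double k_bias, double center, double x0) {
  if (n_keep < 1 || thin < 1 || burn_in < 0) stop("bad chain layout");
  const double a4 = a * a * a * a;
  auto energy = [&](double xi) {
    double q = (xi - m) * (xi - m) - a * a;
    double u = (h != 0.0 && a4 > 0.0) ? h * q * q / a4 : 0.0;
    double dc = xi - center;
    return u + 0.5 * k_bias * dc * dc;
  };
  double x = x0, e = energy(x0);
  long total = (long)burn_in + (long)n_keep * thin;
  long accepted = 0;
  NumericVector out(n_keep);
  int kept = 0;
  for (long t = 1; t <= total; ++t) {
    double prop = x + step * (2.0 * R::unif_rand() - 1.0);
    double ep = energy(prop);
    if (ep <= e || R::unif_rand() < std::exp(-beta * (ep - e))) {
      x = prop;
      e = ep;
      ++accepted;
    }
    if (t > burn_in && ((t - burn_in) % thin == 0)) out[kept++] = x;
  }
  out.attr("acceptance") = (double)accepted / (double)total;
  return out;
}
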