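#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Accessible-volume grid for one dye radius.
//
// A cubic grid of the given spacing is centred on the attachment point and
// spans +/- L in each direction.  Two occupancy maps are built: one for the
// dye centre (atoms inflated by the dye radius) and one for the linker
// (atoms inflated by half the linker width).  The geodesic distance from
// the attachment point through linker-free space is computed by Dijkstra on
// the 26-neighbour grid graph; nodes with a clear straight line of sight to
// the attachment point are seeded with their exact Euclidean distance, so
// the metric is exact in open space and the graph approximation only enters
// behind obstacles.  A node belongs to the AV if it is dye-free,
// linker-free and its geodesic distance is at most L.
// [[Rcpp::export]]
List av_grid_cpp(NumericMatrix coords, NumericVector radii,
                 NumericVector attach, double L, double linker_radius,
                 double dye_radius, double spacing) {
  const int half = (int)std::ceil(L / spacing);
  const int dim = 2 * half + 1;
  const long nn = (long)dim * dim * dim;
  const int na = coords.nrow();
  std::vector<char> occL(nn, 0), occD(nn, 0);  // 1 = blocked

  auto idx = [&](int i, int j, int k) -> long {
    return ((long)i * dim + j) * dim + k;
  };
  auto pos = [&](int i, int d) -> double { return attach[d] + spacing * (i - half); };

  for (int a = 0; a < na; ++a) {
    double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    for (int m = 0; m < 2; ++m) {
      double r = radii[a] + (m == 0 ? linker_radius : dye_radius);
      std::vector<char> &occ = (m == 0) ? occL : occD;
      int i0 = std::max(0, (int)std::floor((ax - r - attach[0]) / spacing) + half);
      int i1 = std::min(dim - 1, (int)std::ceil((ax + r - attach[0]) / spacing) + half);
      int j0 = std::max(0, (int)std::floor((ay - r - attach[1]) / spacing) + half);
      int j1 = std::min(dim - 1, (int)std::ceil((ay + r - attach[1]) / spacing) + half);
      int k0 = std::max(0, (int)std::floor((az - r - attach[2]) / spacing) + half);
      int k1 = std::min(dim - 1, (int)std::ceil((az + r - attach[2]) / spacing) + half);
      double r2 = r * r;
      for (int i = i0; i <= i1; ++i) {
        double dx = pos(i, 0) - ax;
        for (int j = j0; j <= j1; ++j) {
          double dy = pos(j, 1) - ay;
          for (int k = k0; k <= k1; ++k) {
            double dz = pos(k, 2) - az;
            if (dx * dx + dy * dy + dz * dz < r2) occ[idx(i, j, k)] = 1;
          }
        }
      }
    }
  }
  // the attachment node itself must be traversable
  occL[idx(half, half, half)] = 0;

  const double INF = 1e300;
  std::vector<double> dist(nn, INF);
  typedef std::pair<double, long> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  // line-of-sight seeding: sample the segment at spacing/2 steps and test
  // the nearest grid node of each sample against the linker occupancy map
  for (int i = 0; i < dim; ++i) {
    for (int j = 0; j < dim; ++j) {
      for (int k = 0; k < dim; ++k) {
        long id = idx(i, j, k);
        if (occL[id]) continue;
        double dx = spacing * (i - half), dy = spacing * (j - half),
               dz = spacing * (k - half);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d > L) continue;
        int ns = std::max(1, (int)std::ceil(d / (spacing * 0.5)));
        bool clear = true;
        for (int s = 1; s < ns; ++s) {
          double f = (double)s / ns;
          // nearest node along the continuous segment
          double px = f * dx, py = f * dy, pz = f * dz;
          int ii = half + (int)std::lround(px / spacing);
          int jj = half + (int)std::lround(py / spacing);
          int kk = half + (int)std::lround(pz / spacing);
          if (occL[idx(ii, jj, kk)]) { clear = false; break; }
        }
        if (clear) { dist[id] = d; pq.push(QN(d, id)); }
      }
    }
  }
  // 26-neighbour offsets with Euclidean edge weights
  std::vector<int> di, dj, dk; std::vector<double> wt;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
        wt.push_back(spacing * std::sqrt((double)(a * a + b * b + c * c)));
      }
  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    double d = top.first; long id = top.second;
    if (d > dist[id]) continue;
    if (d > L) continue;
    int i = (int)(id / ((long)dim * dim));
    int j = (int)((id / dim) % dim);
    int k = (int)(id % dim);
    for (size_t m = 0; m < di.size(); ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= dim || jj >= dim || kk >= dim)
        continue;
      long id2 = idx(ii, jj, kk);
      if (occL[id2]) continue;
      double nd = d + wt[m];
      if (nd < dist[id2]) { dist[id2] = nd; pq.push(QN(nd, id2)); }
    }
  }
  // collect accessible nodes
  std::vector<double> px, py, pz, pd;
  for (int i = 0; i < dim; ++i)
    for (int j = 0; j < dim; ++j)
      for (int k = 0; k < dim; ++k) {
        long id = idx(i, j, k);
        if (occD[id] || occL[id]) continue;
        if (dist[id] <= L) {
          px.push_back(pos(i, 0)); py.push_back(pos(j, 1));
          pz.push_back(pos(k, 2)); pd.push_back(dist[id]);
        }
      }
  NumericMatrix pts(px.size(), 3);
  NumericVector dd(px.size());
  for (size_t m = 0; m < px.size(); ++m) {
    pts(m, 0) = px[m]; pts(m, 1) = py[m]; pts(m, 2) = pz[m];
    dd[m] = pd[m];
  }
  return List::create(_["points"] = pts, _["dist"] = dd,
                      _["spacing"] = spacing);
}
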