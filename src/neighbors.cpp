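#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatial-hash neighbor searches for the agent field. Both kernels bucket
// agents into square cells of side `radius` and scan the 3x3 block around a
// query, so cost is O(n * local density) rather than O(n^2).

typedef std::unordered_map<long long, std::vector<int> > Grid;

static inline long long cell_key(double v, double w, double cell) {
  // offset keeps keys positive for coordinates within +/- 1e6 patches
  long long ix = (long long)std::floor(v / cell) + 2000000LL;
  long long iy = (long long)std::floor(w / cell) + 2000000LL;
  return ix * 4000003LL + iy;
}

static Grid build_grid(const NumericVector& x, const NumericVector& y,
                       double cell) {
  Grid g;
  for (int i = 0; i < x.size(); ++i)
    g[cell_key(x[i], y[i], cell)].push_back(i);
  return g;
}

// [[Rcpp::export]]
IntegerMatrix count_neighbor_states(NumericVector x, NumericVector y,
                                    IntegerVector state, int n_states,
                                    double radius) {
  if (radius <= 0) stop("radius must be positive");
  const int n = x.size();
  IntegerMatrix out(n, n_states);
  if (n == 0) return out;
  Grid grid = build_grid(x, y, radius);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        Grid::const_iterator it =
            grid.find(cell_key(x[i] + dx * radius, y[i] + dy * radius, radius));
        if (it == grid.end()) continue;
        const std::vector<int>& bucket = it->second;
        for (size_t b = 0; b < bucket.size(); ++b) {
          const int j = bucket[b];
          if (j == i) continue;  // exclude self
          const double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= r2) out(i, state[j] - 1) += 1;
        }
      }
    }
  }
  return out;
}

// Density-driven spreading sweeps. Agents are visited sequentially in a
// freshly shuffled order each sweep and move immediately (the grid is
// updated in place), so decompression waves can propagate outward within a
// sweep. Order shuffling and ties among equally empty directions use R's
// RNG, so runs stay reproducible under set.seed.
static int disc_count(const Grid& grid, const std::vector<double>& cx,
                      const std::vector<double>& cy, double px, double py) {
  int cnt = 0;
  for (int gx = -1; gx <= 1; ++gx) {
    for (int gy = -1; gy <= 1; ++gy) {
      Grid::const_iterator it = grid.find(cell_key(px + gx, py + gy, 1.0));
      if (it == grid.end()) continue;
      const std::vector<int>& bucket = it->second;
      for (size_t b = 0; b < bucket.size(); ++b) {
        const double ddx = cx[bucket[b]] - px, ddy = cy[bucket[b]] - py;
        if (ddx * ddx + ddy * ddy <= 1.0) ++cnt;
      }
    }
  }
  return cnt;
}

// [[Rcpp::export]]
NumericMatrix redistribute_crowded(NumericVector x, NumericVector y,
                                   double max_count, double xmin, double xmax,
                                   double ymin, double ymax, int max_sweeps) {
  const int n = x.size();
  NumericMatrix out(n, 2);
  std::vector<double> cx(x.begin(), x.end()), cy(y.begin(), y.end());
  static const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const double SQ2 = 1.4142135623730951;
  Grid grid;
  for (int i = 0; i < n; ++i) grid[cell_key(cx[i], cy[i], 1.0)].push_back(i);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    // Fisher-Yates shuffle of the visiting order
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)(unif_rand() * (i + 1));
      std::swap(order[i], order[j > i ? i : j]);
    }
    bool moved = false;
    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi];
      if (disc_count(grid, cx, cy, cx[i], cy[i]) <= max_count) continue;
      int best = -1, nbest = 0, pick = -1;
      for (int k = 0; k < 8; ++k) {
        const int c = disc_count(grid, cx, cy, cx[i] + DX[k], cy[i] + DY[k]);
        if (best < 0 || c < best) {
          best = c;
          nbest = 1;
          pick = k;
        } else if (c == best) {
          // reservoir sampling over tied directions
          if (unif_rand() * (++nbest) < 1.0) pick = k;
        }
      }
      const double nrm = (DX[pick] != 0 && DY[pick] != 0) ? SQ2 : 1.0;
      const double newx = std::min(std::max(cx[i] + DX[pick] / nrm, xmin), xmax);
      const double newy = std::min(std::max(cy[i] + DY[pick] / nrm, ymin), ymax);
      if (newx == cx[i] && newy == cy[i]) continue;
      // move immediately: update the live grid
      const long long oldk = cell_key(cx[i], cy[i], 1.0);
      const long long newk = cell_key(newx, newy, 1.0);
      if (oldk != newk) {
        std::vector<int>& ob = grid[oldk];
        for (size_t b = 0; b < ob.size(); ++b) {
          if (ob[b] == i) {
            ob[b] = ob.back();
            ob.pop_back();
            break;
          }
        }
        grid[newk].push_back(i);
      }
      cx[i] = newx;
      cy[i] = newy;
      moved = true;
    }
    if (!moved) break;
  }
  for (int i = 0; i < n; ++i) {
    out(i, 0) = cx[i];
    out(i, 1) = cy[i];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector count_points_within(NumericVector x, NumericVector y,
                                  NumericVector qx, NumericVector qy,
                                  double radius) {
  if (radius <= 0) stop("radius must be positive");
  const int nq = qx.size();
  IntegerVector out(nq);
  if (x.size() == 0 || nq == 0) return out;
  Grid grid = build_grid(x, y, radius);
  const double r2 = radius * radius;
  for (int i = 0; i < nq; ++i) {
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        Grid::const_iterator it = grid.find(
            cell_key(qx[i] + dx * radius, qy[i] + dy * radius, radius));
        if (it == grid.end()) continue;
        const std::vector<int>& bucket = it->second;
        for (size_t b = 0; b < bucket.size(); ++b) {
          const int j = bucket[b];
          const double ddx = x[j] - qx[i], ddy = y[j] - qy[i];
          if (ddx * ddx + ddy * ddy <= r2) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}
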