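#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <deque>
using namespace Rcpp;

// Euclidean distance from each source point to its nearest target point.
// Squared distances are minimised and a single sqrt taken at the end; sqrt
// is monotone and correctly rounded, so the result is bitwise identical to
// taking sqrt first and then the minimum (the brute-force oracle).
// [[Rcpp::export]]
NumericVector cpp_nn_mindist(NumericVector sx, NumericVector sy,
                             NumericVector tx, NumericVector ty) {
  const int n = sx.size(), m = tx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double xi = sx[i], yi = sy[i];
    for (int j = 0; j < m; ++j) {
      const double dx = xi - tx[j], dy = yi - ty[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Self nearest-neighbour distance: nearest OTHER point by index, so
// coincident duplicates are legitimate neighbours at distance zero.
// [[Rcpp::export]]
NumericVector cpp_nn_self(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static double median_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// Monte-Carlo null for the median NN distance. Each round draws n_source
// points uniformly over the valid pixels (uniform pixel choice + uniform
// jitter in [-0.5, 0.5] per axis, three unif_rand() draws per point in the
// order index, x-jitter, y-jitter), recomputes the NN summary and records
// the round's median. mode 0: fixed targets (point_to_point and
// point_to_region, targets being region pixel centers); mode 1: self, the
// whole set is re-placed and self-excluded NN recomputed. Uses R's RNG, so
// results are reproducible from set.seed().
// [[Rcpp::export]]
NumericVector cpp_mc_medians(int n_source,
                             NumericVector tx, NumericVector ty,
                             NumericVector vx, NumericVector vy,
                             int n_rounds, int mode) {
  const int nv = vx.size(), m = tx.size();
  NumericVector out(n_rounds);
  std::vector<double> px(n_source), py(n_source), d(n_source);
  std::vector<double> txv(tx.begin(), tx.end()), tyv(ty.begin(), ty.end());
  std::vector<double> vxv(vx.begin(), vx.end()), vyv(vy.begin(), vy.end());
  const double *tpx = txv.data(), *tpy = tyv.data();
  for (int r = 0; r < n_rounds; ++r) {
    for (int i = 0; i < n_source; ++i) {
      int idx = (int)(nv * unif_rand());
      if (idx >= nv) idx = nv - 1;
      px[i] = vxv[idx] + (unif_rand() - 0.5);
      py[i] = vyv[idx] + (unif_rand() - 0.5);
    }
    if (mode == 0) {
      for (int i = 0; i < n_source; ++i) {
        double best = R_PosInf;
        const double xi = px[i], yi = py[i];
        for (int j = 0; j < m; ++j) {
          const double dx = xi - tpx[j], dy = yi - tpy[j];
          const double d2 = dx * dx + dy * dy;
          best = d2 < best ? d2 : best;
        }
        d[i] = std::sqrt(best);
      }
    } else {
      for (int i = 0; i < n_source; ++i) {
        double best = R_PosInf;
        for (int j = 0; j < n_source; ++j) {
          if (j == i) continue;
          const double dx = px[i] - px[j], dy = py[i] - py[j];
          const double d2 = dx * dx + dy * dy;
          if (d2 < best) best = d2;
        }
        d[i] = std::sqrt(best);
      }
    }
    out[r] = median_inplace(d);
  }
  return out;
}

// 8-connected component labeling of a logical matrix by breadth-first
// search. Components are numbered in row-major scan order of their first
// encountered pixel, making detection output order deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop_front();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
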