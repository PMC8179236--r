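#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct QRFit {
  double slope, intercept, loss;
};

// Profile the check loss over the slope: for a fixed slope the optimal
// intercept is the lower weighted tau-quantile of the residuals (the exact
// minimiser of the weighted check loss over a constant), and the profiled
// objective is convex in the slope, so golden-section search finds the
// global minimum.
static QRFit qr_fit(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& w, double tau,
                    double blo, double bhi, double tol) {
  const int n = (int)x.size();
  std::vector<std::pair<double, double>> rw(n);
  double W = 0.0;
  for (int i = 0; i < n; ++i) W += w[i];
  const double target = tau * W;
  double a_tmp = 0.0;
  auto g = [&](double b, double& a_out) {
    for (int i = 0; i < n; ++i) rw[i] = {y[i] - b * x[i], w[i]};
    std::sort(rw.begin(), rw.end());
    double c = 0.0, a = rw[n - 1].first;
    for (int i = 0; i < n; ++i) {
      c += rw[i].second;
      if (c >= target) { a = rw[i].first; break; }
    }
    a_out = a;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      const double u = rw[i].first - a;
      s += rw[i].second * (u >= 0.0 ? tau * u : (tau - 1.0) * u);
    }
    return s;
  };
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double lo = blo, hi = bhi;
  double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
  double fc = g(c, a_tmp), fd = g(d, a_tmp);
  while (hi - lo > tol) {
    if (fc < fd) {
      hi = d; d = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = g(c, a_tmp);
    } else {
      lo = c; c = d; fc = fd;
      d = lo + gr * (hi - lo);
      fd = g(d, a_tmp);
    }
  }
  QRFit out;
  out.slope = (lo + hi) / 2.0;
  out.loss = g(out.slope, a_tmp);
  out.intercept = a_tmp;
  return out;
}

// [[Rcpp::export]]
List cpp_qr_fit(NumericVector x, NumericVector y, NumericVector w,
                double tau, double blo, double bhi, double tol) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> wv(w.begin(), w.end());
  QRFit f = qr_fit(xv, yv, wv, tau, blo, bhi, tol);
  return List::create(_["slope"] = f.slope, _["intercept"] = f.intercept,
                      _["loss"] = f.loss);
}

// Year-block bootstrap of the quantile-regression slope: years are resampled
// with replacement and all of a year's (elevation, weight) points come along.
// Uses the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_qr_boot(NumericVector x, NumericVector y, NumericVector w,
                          IntegerVector yearIdx, int nYears, double tau,
                          double blo, double bhi, double tol, int nBoot) {
  const int n = x.size();
  std::vector<std::vector<int>> byYear(nYears);
  for (int i = 0; i < n; ++i) byYear[yearIdx[i] - 1].push_back(i);

  NumericVector slopes(nBoot);
  std::vector<double> xb, yb, wb;
  xb.reserve(n); yb.reserve(n); wb.reserve(n);
  std::vector<int> pick(nYears);

  for (int rep = 0; rep < nBoot; ++rep) {
    bool ok = false;
    for (int attempt = 0; attempt < 100 && !ok; ++attempt) {
      double first = NA_REAL;
      ok = false;
      for (int t = 0; t < nYears; ++t) {
        pick[t] = (int)std::floor(unif_rand() * nYears);
        if (pick[t] >= nYears) pick[t] = nYears - 1;
        const std::vector<int>& cells = byYear[pick[t]];
        if (!cells.empty()) {
          const double xv = x[cells[0]];
          if (ISNA(first)) first = xv;
          else if (xv != first) ok = true;
        }
      }
    }
    xb.clear(); yb.clear(); wb.clear();
    for (int t = 0; t < nYears; ++t) {
      for (int i : byYear[pick[t]]) {
        xb.push_back(x[i]); yb.push_back(y[i]); wb.push_back(w[i]);
      }
    }
    if (!ok || xb.empty()) {
      slopes[rep] = NA_REAL;
      continue;
    }
    QRFit f = qr_fit(xb, yb, wb, tau, blo, bhi, tol);
    slopes[rep] = f.slope;
  }
  return slopes;
}

// Grow one fire from an ignition cell (0-based) by breadth-first region
// growing on the 4-neighbour lattice: each forest neighbour not yet offered
// joins the fire with its own probability pjoin. Returns 0-based cell indices.
static std::vector<int> grow_fire(int nrow, int ncol, const int* forest,
                                  const double* pjoin, int ignition,
                                  std::vector<char>& offered) {
  std::vector<int> fire;
  std::vector<int> frontier;
  std::fill(offered.begin(), offered.end(), 0);
  offered[ignition] = 1;
  fire.push_back(ignition);
  frontier.push_back(ignition);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!frontier.empty()) {
    std::vector<int> next;
    for (int cell : frontier) {
      const int r = cell % nrow, c = cell / nrow;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
        const int nb = cc * nrow + rr;
        if (offered[nb] || !forest[nb]) continue;
        offered[nb] = 1;
        if (unif_rand() < pjoin[nb]) {
          fire.push_back(nb);
          next.push_back(nb);
        }
      }
    }
    frontier.swap(next);
  }
  return fire;
}

// One fire season: draw ignition cells among forest cells with probability
// proportional to the logistic flammability (without replacement), grow each
// fire, discard fires smaller than minFireCells, return the union burn mask.
// [[Rcpp::export]]
LogicalVector cpp_simulate_year(int nrow, int ncol, LogicalVector forest,
                                NumericVector pjoin, int nIgnitions,
                                int minFireCells) {
  const int n = nrow * ncol;
  LogicalVector burn(n, false);
  if (nIgnitions <= 0) return burn;

  std::vector<double> wt(n, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (forest[i]) {
      wt[i] = pjoin[i];
      total += wt[i];
    }
  }
  if (total <= 0.0) return burn;

  std::vector<char> offered(n, 0);
  std::vector<int> forestInt(n);
  for (int i = 0; i < n; ++i) forestInt[i] = forest[i] ? 1 : 0;

  for (int f = 0; f < nIgnitions; ++f) {
    if (total <= 0.0) break;
    const double u = unif_rand() * total;
    double c = 0.0;
    int ign = -1;
    for (int i = 0; i < n; ++i) {
      if (wt[i] > 0.0) {
        c += wt[i];
        if (c >= u) { ign = i; break; }
      }
    }
    if (ign < 0) break;
    total -= wt[ign];
    wt[ign] = 0.0;  // without replacement
    std::vector<int> fire = grow_fire(nrow, ncol, forestInt.data(),
                                      REAL(pjoin), ign, offered);
    if ((int)fire.size() >= minFireCells) {
      for (int cell : fire) burn[cell] = true;
    }
  }
  return burn;
}
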