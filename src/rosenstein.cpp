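#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rosenstein nearest-neighbour divergence tracking.
//
// emb: M x d matrix of delay-embedded points. For every reference point i
// (with i + horizon still inside the record) the nearest neighbour j is
// found under the Theiler exclusion |i - j| > theiler (j likewise limited so
// the pair can be tracked over the horizon). The mean of ln(distance) over
// all tracked pairs is returned for lags k = 0..horizon. Distances are
// floored at 1e-12 so exactly periodic orbits give a flat finite curve.

// [[Rcpp::export]]
List rosenstein_divergence_cpp(NumericMatrix emb, int theiler, int horizon) {
  const int m = emb.nrow();
  const int d = emb.ncol();
  const int last = m - horizon; // points 0..last-1 can be tracked
  if (last < 2) stop("series too short for the requested horizon");

  std::vector<double> sum_log(horizon + 1, 0.0);
  std::vector<int> n_pairs(horizon + 1, 0);
  const double floor_d = 1e-12;

  for (int i = 0; i < last; ++i) {
    double best = R_PosInf;
    int best_j = -1;
    for (int j = 0; j < last; ++j) {
      int lag = i - j;
      if (lag < 0) lag = -lag;
      if (lag <= theiler) continue;
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = emb(i, c) - emb(j, c);
        dist2 += diff * diff;
        if (dist2 >= best) break;
      }
      if (dist2 < best) { best = dist2; best_j = j; }
    }
    if (best_j < 0) continue;
    for (int k = 0; k <= horizon; ++k) {
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = emb(i + k, c) - emb(best_j + k, c);
        dist2 += diff * diff;
      }
      double dist = std::sqrt(dist2);
      if (dist < floor_d) dist = floor_d;
      sum_log[k] += std::log(dist);
      n_pairs[k] += 1;
    }
  }

  NumericVector curve(horizon + 1);
  IntegerVector np(horizon + 1);
  for (int k = 0; k <= horizon; ++k) {
    curve[k] = n_pairs[k] > 0 ? sum_log[k] / n_pairs[k] : NA_REAL;
    np[k] = n_pairs[k];
  }
  return List::create(_["mean_log_div"] = curve, _["n_pairs"] = np);
}

// Connected-component labelling of suprathreshold points of a t-map under
// 4-connectivity; positive (t > thresh) and negative (t < -thresh) points
// form separate clusters. Returns labels (0 = subthreshold) and per-cluster
// signed mass (sum of t).

// [[Rcpp::export]]
List label_clusters_cpp(NumericMatrix t, double thresh) {
  const int nr = t.nrow(), nc = t.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> mass;
  std::vector<int> stack;
  int next_label = 0;

  for (int start = 0; start < nr * nc; ++start) {
    const int r0 = start % nr, c0 = start / nr;
    if (lab(r0, c0) != 0) continue;
    const double v0 = t(r0, c0);
    if (!(v0 > thresh) && !(v0 < -thresh)) continue;
    const int sign = v0 > 0 ? 1 : -1;
    ++next_label;
    double msum = 0.0;
    stack.clear();
    stack.push_back(start);
    lab(r0, c0) = next_label;
    while (!stack.empty()) {
      const int cur = stack.back(); stack.pop_back();
      const int r = cur % nr, c = cur / nr;
      msum += t(r, c);
      const int nbr[4][2] = {{r - 1, c}, {r + 1, c}, {r, c - 1}, {r, c + 1}};
      for (auto &nb : nbr) {
        const int rr = nb[0], cc = nb[1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (lab(rr, cc) != 0) continue;
        const double v = t(rr, cc);
        if ((sign > 0 && v > thresh) || (sign < 0 && v < -thresh)) {
          lab(rr, cc) = next_label;
          stack.push_back(rr + nr * cc);
        }
      }
    }
    mass.push_back(msum);
  }
  return List::create(_["labels"] = lab, _["mass"] = wrap(mass));
}

// Maximum |cluster mass| of a t-map (the permutation-null statistic).

// [[Rcpp::export]]
double max_cluster_mass_cpp(NumericMatrix t, double thresh) {
  List res = label_clusters_cpp(t, thresh);
  NumericVector mass = res["mass"];
  double best = 0.0;
  for (double m : mass) if (std::fabs(m) > best) best = std::fabs(m);
  return best;
}
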