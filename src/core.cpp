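#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// x * log2(x), 0 at 0
static inline double plogp2(double x) { return x > 0.0 ? x * std::log2(x) : 0.0; }

// Pearson chi-squared on an r x 2 count table, all-zero rows dropped first.
// Yates continuity correction (|O-E|-0.5, unclamped) when exactly 2 rows
// survive; df = rows - 1.  df < 1 or an empty column => stat 0 / df 0.
static void chi2_two_col(const std::vector<double>& c1, const std::vector<double>& c2,
                         double& stat, int& df) {
  const std::size_t r = c1.size();
  double t1 = 0.0, t2 = 0.0;
  int rows = 0;
  for (std::size_t j = 0; j < r; ++j) {
    t1 += c1[j]; t2 += c2[j];
    if (c1[j] + c2[j] > 0.0) ++rows;
  }
  const double N = t1 + t2;
  df = rows - 1;
  stat = 0.0;
  if (N <= 0.0 || df < 1 || t1 <= 0.0 || t2 <= 0.0) { df = 0; return; }
  const double yates = (rows == 2) ? 0.5 : 0.0;
  for (std::size_t j = 0; j < r; ++j) {
    const double rowm = c1[j] + c2[j];
    if (rowm <= 0.0) continue;
    const double e1 = t1 * rowm / N, e2 = t2 * rowm / N;
    const double d1 = std::fabs(c1[j] - e1) - yates;
    const double d2 = std::fabs(c2[j] - e2) - yates;
    if (e1 > 0.0) stat += d1 * d1 / e1;
    if (e2 > 0.0) stat += d2 * d2 / e2;
  }
}

// [[Rcpp::export]]
List cpp_chi2_area(NumericMatrix area) {
  const int r = area.nrow();
  std::vector<double> c1(r), c2(r);
  for (int j = 0; j < r; ++j) { c1[j] = area(j, 0); c2[j] = area(j, 1); }
  double stat; int df;
  chi2_two_col(c1, c2, stat, df);
  const double p = (df >= 1) ? R::pchisq(stat, (double)df, 0, 0) : 1.0;
  return List::create(_["statistic"] = stat, _["df"] = df, _["p_value"] = p);
}

// Greedy chi-squared-gated refinement of one axis.
//
// row_bins_border: bin index (1..n_rows) on the fixed axis for each point,
//   listed in increasing rank order of the *searched* axis.
// admissible: rank positions (1..n-1) where a cut may sit (never inside a
//   run of tied values).
// At each step every unused admissible cut is scored by the mutual-
// information gain of the grid it induces; the best one (smallest rank on
// ties) is tested on its detection area and committed iff p < threshold.
// Stops at the first rejection.  Returns the committed cuts, sorted.
// When require_gain is true a committed cut must also raise the normalized
// score I / log2(min(n_rows, n_cols)) of the working grid — the back-search
// maximizes the final normalized score, so a cut that lowers it cannot be
// part of the argmax.
// [[Rcpp::export]]
IntegerVector cpp_gated_search(IntegerVector row_bins_border, int n_rows,
                               IntegerVector admissible, double threshold,
                               int free_cuts = 1, bool require_gain = false) {
  const int n = row_bins_border.size();
  const int na = admissible.size();
  // cum[j][t] = points among the first t (searched-axis order) in row j+1
  std::vector< std::vector<int> > cum(n_rows, std::vector<int>(n + 1, 0));
  for (int t = 1; t <= n; ++t) {
    for (int j = 0; j < n_rows; ++j) cum[j][t] = cum[j][t - 1];
    cum[row_bins_border[t - 1] - 1][t] += 1;
  }
  std::vector<int> cuts;
  std::vector<bool> used(na, false);
  double I_cur = 0.0, score_cur = 0.0;
  for (;;) {
    std::vector<int> bnd;
    bnd.push_back(0);
    for (std::size_t i = 0; i < cuts.size(); ++i) bnd.push_back(cuts[i]);
    bnd.push_back(n);
    double best_delta = -1e300;
    int best_idx = -1, best_lo = 0, best_hi = n;
    for (int a = 0; a < na; ++a) {
      if (used[a]) continue;
      const int t = admissible[a];
      const int k = (int)(std::upper_bound(bnd.begin(), bnd.end(), t) - bnd.begin());
      const int lo = bnd[k - 1], hi = bnd[k];
      if (t <= lo || t >= hi) continue;
      // delta MI * n (positive scale): d(col entropy) - d(joint entropy)
      double dcol = -(plogp2((double)(t - lo)) + plogp2((double)(hi - t))
                      - plogp2((double)(hi - lo)));
      double djoint = 0.0;
      for (int j = 0; j < n_rows; ++j) {
        const double l = (double)(cum[j][t] - cum[j][lo]);
        const double v = (double)(cum[j][hi] - cum[j][lo]);
        djoint += plogp2(l) + plogp2(v - l) - plogp2(v);
      }
      djoint = -djoint;
      const double delta = dcol - djoint;
      if (delta > best_delta + 1e-12) {
        best_delta = delta; best_idx = a; best_lo = lo; best_hi = hi;
      }
    }
    if (best_idx < 0) break;
    const int t = admissible[best_idx];
    const double I_new = I_cur + best_delta / (double)n;
    if (require_gain && (int)cuts.size() + 1 >= free_cuts) {
      const int cols_new = (int)cuts.size() + 2;
      const int mn = n_rows < cols_new ? n_rows : cols_new;
      const double score_new = (mn >= 2) ? I_new / std::log2((double)mn) : 0.0;
      if (score_new <= score_cur + 1e-12) break;
      if ((int)cuts.size() >= free_cuts) {
        std::vector<double> c1(n_rows), c2(n_rows);
        for (int j = 0; j < n_rows; ++j) {
          c1[j] = (double)(cum[j][t] - cum[j][best_lo]);
          c2[j] = (double)(cum[j][best_hi] - cum[j][t]);
        }
        double stat; int df;
        chi2_two_col(c1, c2, stat, df);
        const double p = (df >= 1) ? R::pchisq(stat, (double)df, 0, 0) : 1.0;
        if (p >= threshold) break;
      }
      cuts.insert(std::lower_bound(cuts.begin(), cuts.end(), t), t);
      used[best_idx] = true;
      I_cur = I_new;
      score_cur = score_new;
      continue;
    }
    if ((int)cuts.size() < free_cuts) {
      // structural cut: a grid needs >= 2 bins per axis before the gate
      // has anything to arbitrate
      cuts.insert(std::lower_bound(cuts.begin(), cuts.end(), t), t);
      used[best_idx] = true;
      I_cur = I_new;
      continue;
    }
    std::vector<double> c1(n_rows), c2(n_rows);
    for (int j = 0; j < n_rows; ++j) {
      c1[j] = (double)(cum[j][t] - cum[j][best_lo]);
      c2[j] = (double)(cum[j][best_hi] - cum[j][t]);
    }
    double stat; int df;
    chi2_two_col(c1, c2, stat, df);
    const double p = (df >= 1) ? R::pchisq(stat, (double)df, 0, 0) : 1.0;
    if (p < threshold) {
      cuts.insert(std::lower_bound(cuts.begin(), cuts.end(), t), t);
      used[best_idx] = true;
    } else {
      break;
    }
  }
  return wrap(cuts);
}

// Dynamic program of the ApproxMaxMI column optimisation.
//
// bounds: candidate column boundaries in increasing rank order, last == n
//   (clump / superclump endpoints).  For l = 1..L columns the DP maximises
//   G = sum_ij plogp(c_ij) - sum_j plogp(m_j)  (n * (H_col - H_joint) up to
//   the log2(n) terms, which cancel), with column boundaries on `bounds`.
// Returns G per l (NA where infeasible) and the argmax choice matrix for
// partition reconstruction.
// [[Rcpp::export]]
List cpp_optimize_axis(IntegerVector row_bins_border, int n_rows,
                       IntegerVector bounds, int L) {
  const int n = row_bins_border.size();
  const int k = bounds.size();
  std::vector<int> pos(k + 1);
  pos[0] = 0;
  for (int i = 0; i < k; ++i) pos[i + 1] = bounds[i];
  // cumulative row counts at each boundary
  std::vector< std::vector<double> > cum(n_rows, std::vector<double>(k + 1, 0.0));
  {
    std::vector<double> run(n_rows, 0.0);
    int pi = 1;
    for (int t = 1; t <= n; ++t) {
      run[row_bins_border[t - 1] - 1] += 1.0;
      while (pi <= k && pos[pi] == t) {
        for (int j = 0; j < n_rows; ++j) cum[j][pi] = run[j];
        ++pi;
      }
    }
  }
  // column weight w(s,t), 0 <= s < t <= k
  std::vector<double> W((std::size_t)(k + 1) * (k + 1), 0.0);
  for (int t = 1; t <= k; ++t) {
    for (int s = 0; s < t; ++s) {
      double w = -plogp2((double)(pos[t] - pos[s]));
      for (int j = 0; j < n_rows; ++j) w += plogp2(cum[j][t] - cum[j][s]);
      W[(std::size_t)s * (k + 1) + t] = w;
    }
  }
  const double NEG = -1e300;
  NumericMatrix F(L + 1, k + 1);
  IntegerMatrix C(L + 1, k + 1);
  std::fill(F.begin(), F.end(), NEG);
  std::fill(C.begin(), C.end(), -1);
  for (int t = 1; t <= k; ++t) F(1, t) = W[t];  // s = 0
  for (int l = 2; l <= L; ++l) {
    for (int t = l; t <= k; ++t) {
      double best = NEG; int arg = -1;
      for (int s = l - 1; s < t; ++s) {
        const double v = F(l - 1, s) + W[(std::size_t)s * (k + 1) + t];
        if (v > best) { best = v; arg = s; }
      }
      F(l, t) = best; C(l, t) = arg;
    }
  }
  NumericVector G(L);
  for (int l = 1; l <= L; ++l) G[l - 1] = (l <= k) ? F(l, k) : NA_REAL;
  return List::create(_["G"] = G, _["choice"] = C);
}

// Brute-force maximum of I / log2(min(nx, ny)) over all supplied partition
// pairs; xb / yb hold one bin-assignment vector per column.  Partitions whose
// smaller side has a single bin contribute 0.  Test oracle for tiny n.
// [[Rcpp::export]]
double cpp_exhaustive_best(IntegerMatrix xb, IntegerMatrix yb,
                           IntegerVector nxv, IntegerVector nyv) {
  const int n = xb.nrow();
  const int Px = xb.ncol(), Py = yb.ncol();
  double best = 0.0;
  std::vector<double> cell;
  for (int a = 0; a < Px; ++a) {
    const int nx = nxv[a];
    for (int b = 0; b < Py; ++b) {
      const int ny = nyv[b];
      const int m = std::min(nx, ny);
      if (m < 2) continue;
      cell.assign((std::size_t)nx * ny, 0.0);
      for (int i = 0; i < n; ++i)
        cell[(std::size_t)(xb(i, a) - 1) * ny + (yb(i, b) - 1)] += 1.0;
      std::vector<double> rm(ny, 0.0), cm(nx, 0.0);
      double sj = 0.0;
      for (int ci = 0; ci < nx; ++ci)
        for (int rj = 0; rj < ny; ++rj) {
          const double v = cell[(std::size_t)ci * ny + rj];
          rm[rj] += v; cm[ci] += v;
          sj += plogp2(v);
        }
      double sr = 0.0, sc = 0.0;
      for (int rj = 0; rj < ny; ++rj) sr += plogp2(rm[rj]);
      for (int ci = 0; ci < nx; ++ci) sc += plogp2(cm[ci]);
      const double I = (plogp2((double)n) + sj - sr - sc) / (double)n;
      const double score = I / std::log2((double)m);
      if (score > best) best = score;
    }
  }
  return best;
}
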