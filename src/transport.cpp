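// Exact transportation solve used for the SADIE distance to regularity.
//
// Classic transportation simplex: north-west-corner starting basis, MODI
// (u-v) potentials, Bland's rule for the entering cell and lexicographic
// tie-breaking for the leaving cell.  Bland's rule guarantees finite
// termination under degeneracy; all tie-breaks are deterministic so the
// solver returns identical output for identical input.  Supplies and
// demands are continuous (count surpluses are not integerized).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct TPResult {
  double cost;
  std::vector<double> flow; // m x n, row-major
};

// Solve min sum f_ij c_ij  s.t. rowSums(f) = supply, colSums(f) = demand,
// f >= 0.  supply/demand must be positive and balanced.
TPResult tp_solve(const std::vector<double>& cost, int m, int n,
                  std::vector<double> s, std::vector<double> d) {
  std::vector<double> flow(static_cast<size_t>(m) * n, 0.0);
  std::vector<char> basic(static_cast<size_t>(m) * n, 0);

  double cmax = 0.0;
  for (double c : cost) cmax = std::max(cmax, std::fabs(c));
  const double tol = 1e-10 * (1.0 + cmax);

  // North-west corner starting basis: exactly m + n - 1 basic cells and a
  // connected (spanning-tree) basis graph, zero flows allowed.
  {
    int i = 0, j = 0;
    while (true) {
      double q = std::min(s[i], d[j]);
      flow[static_cast<size_t>(i) * n + j] = q;
      basic[static_cast<size_t>(i) * n + j] = 1;
      s[i] -= q;
      d[j] -= q;
      if (i == m - 1 && j == n - 1) break;
      if (s[i] <= d[j] && i < m - 1) ++i;
      else if (j < n - 1) ++j;
      else ++i;
    }
  }

  std::vector<double> u(m), v(n);
  std::vector<int> parent(m + n), parent_edge(m + n);
  const long max_iter = 1000000L;
  bool bland_mode = false;
  long degenerate_run = 0;
  const long stall_limit = 20L * (m + n);

  for (long iter = 0; iter < max_iter; ++iter) {
    // Potentials by BFS over the basis tree (nodes: rows 0..m-1, cols
    // m..m+n-1), u[0] = 0.
    std::vector<char> seen(m + n, 0);
    std::queue<int> q;
    u[0] = 0.0;
    seen[0] = 1;
    q.push(0);
    while (!q.empty()) {
      int node = q.front();
      q.pop();
      if (node < m) {
        int i = node;
        for (int j = 0; j < n; ++j) {
          if (basic[static_cast<size_t>(i) * n + j] && !seen[m + j]) {
            v[j] = cost[static_cast<size_t>(i) * n + j] - u[i];
            seen[m + j] = 1;
            q.push(m + j);
          }
        }
      } else {
        int j = node - m;
        for (int i = 0; i < m; ++i) {
          if (basic[static_cast<size_t>(i) * n + j] && !seen[i]) {
            u[i] = cost[static_cast<size_t>(i) * n + j] - v[j];
            seen[i] = 1;
            q.push(i);
          }
        }
      }
    }

    // Entering cell. Normal mode: most negative reduced cost with
    // lexicographic tie-break (fast). After a long run of degenerate
    // pivots, switch permanently to Bland's rule (first negative in
    // row-major order), which cannot cycle, guaranteeing termination.
    int ei = -1, ej = -1;
    if (!bland_mode) {
      double best_red = -tol;
      for (int i = 0; i < m; ++i) {
        for (int j = 0; j < n; ++j) {
          size_t idx = static_cast<size_t>(i) * n + j;
          if (!basic[idx]) {
            double red = cost[idx] - u[i] - v[j];
            if (red < best_red) {
              best_red = red;
              ei = i;
              ej = j;
            }
          }
        }
      }
    } else {
      for (int i = 0; i < m && ei < 0; ++i) {
        for (int j = 0; j < n; ++j) {
          if (!basic[static_cast<size_t>(i) * n + j] &&
              cost[static_cast<size_t>(i) * n + j] - u[i] - v[j] < -tol) {
            ei = i;
            ej = j;
            break;
          }
        }
      }
    }
    if (ei < 0) break; // optimal

    // Unique path from row ei to col ej through the basis tree.
    std::fill(parent.begin(), parent.end(), -1);
    std::vector<char> vis(m + n, 0);
    std::queue<int> bq;
    vis[ei] = 1;
    bq.push(ei);
    while (!bq.empty() && !vis[m + ej]) {
      int node = bq.front();
      bq.pop();
      if (node < m) {
        int i = node;
        for (int j = 0; j < n; ++j) {
          if (basic[static_cast<size_t>(i) * n + j] && !vis[m + j]) {
            vis[m + j] = 1;
            parent[m + j] = node;
            bq.push(m + j);
          }
        }
      } else {
        int j = node - m;
        for (int i = 0; i < m; ++i) {
          if (basic[static_cast<size_t>(i) * n + j] && !vis[i]) {
            vis[i] = 1;
            parent[i] = node;
            bq.push(i);
          }
        }
      }
    }
    if (!vis[m + ej]) stop("transportation basis disconnected (internal error)");

    // Collect path edges from col ej back to row ei; alternate signs with
    // the first path edge taking '-'.
    std::vector<std::pair<int, int> > minus_cells, plus_cells;
    {
      int node = m + ej;
      int sign = -1; // first edge leaving col ej
      while (parent[node] != -1) {
        int p = parent[node];
        int i = (node < m) ? node : p;
        int j = (node < m) ? p - m : node - m;
        if (sign < 0) minus_cells.push_back(std::make_pair(i, j));
        else plus_cells.push_back(std::make_pair(i, j));
        sign = -sign;
        node = p;
      }
    }

    // theta and leaving cell (lexicographically smallest among ties).
    double theta = std::numeric_limits<double>::infinity();
    for (size_t k = 0; k < minus_cells.size(); ++k) {
      double f = flow[static_cast<size_t>(minus_cells[k].first) * n +
                      minus_cells[k].second];
      if (f < theta) theta = f;
    }
    int li = -1, lj = -1;
    for (size_t k = 0; k < minus_cells.size(); ++k) {
      int i = minus_cells[k].first, j = minus_cells[k].second;
      double f = flow[static_cast<size_t>(i) * n + j];
      if (f <= theta + tol * (1.0 + theta)) {
        if (li < 0 || i < li || (i == li && j < lj)) {
          li = i;
          lj = j;
        }
      }
    }

    if (theta <= tol) {
      if (++degenerate_run > stall_limit) bland_mode = true;
    } else {
      degenerate_run = 0;
    }

    for (size_t k = 0; k < plus_cells.size(); ++k)
      flow[static_cast<size_t>(plus_cells[k].first) * n + plus_cells[k].second] += theta;
    for (size_t k = 0; k < minus_cells.size(); ++k)
      flow[static_cast<size_t>(minus_cells[k].first) * n + minus_cells[k].second] -= theta;
    flow[static_cast<size_t>(ei) * n + ej] = theta;
    basic[static_cast<size_t>(ei) * n + ej] = 1;
    basic[static_cast<size_t>(li) * n + lj] = 0;
    flow[static_cast<size_t>(li) * n + lj] = 0.0;

    if (iter == max_iter - 1) stop("transportation simplex did not converge");
  }

  TPResult res;
  res.cost = 0.0;
  for (size_t k = 0; k < flow.size(); ++k) res.cost += flow[k] * cost[k];
  res.flow = flow;
  return res;
}

} // namespace

// [[Rcpp::export]]
List tp_solve_cpp(NumericMatrix cost, NumericVector supply, NumericVector demand) {
  int m = cost.nrow(), n = cost.ncol();
  if (supply.size() != m || demand.size() != n)
    stop("supply/demand dimensions do not match the cost matrix");
  std::vector<double> c(static_cast<size_t>(m) * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) c[static_cast<size_t>(i) * n + j] = cost(i, j);
  std::vector<double> s(supply.begin(), supply.end());
  std::vector<double> d(demand.begin(), demand.end());
  double ssum = 0.0, dsum = 0.0;
  for (double x : s) {
    if (x <= 0) stop("supplies must be positive");
    ssum += x;
  }
  for (double x : d) {
    if (x <= 0) stop("demands must be positive");
    dsum += x;
  }
  if (dsum <= 0) stop("total demand must be positive");
  if (std::fabs(ssum - dsum) > 1e-6 * (1.0 + ssum))
    stop("supplies and demands are not balanced");
  for (double& x : d) x *= ssum / dsum; // remove rounding drift exactly

  TPResult res = tp_solve(c, m, n, s, d);
  NumericMatrix flow(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) flow(i, j) = res.flow[static_cast<size_t>(i) * n + j];
  return List::create(_["cost"] = res.cost, _["flow"] = flow);
}

// Batch SADIE engine: for each column of `counts` (one configuration of the
// same spatial units), solve the distance-to-regularity transportation
// problem and return the optimal cost D plus, per unit, the mean transport
// distance per unit of surplus (donors) or deficit (receivers); NA for
// units whose count equals the mean.
// [[Rcpp::export]]
List sadie_batch_cpp(NumericMatrix dist, NumericMatrix counts) {
  int nu = dist.nrow();
  if (dist.ncol() != nu) stop("distance matrix must be square");
  if (counts.nrow() != nu) stop("counts rows must match distance matrix");
  int K = counts.ncol();

  NumericVector D(K);
  NumericMatrix W(nu, K);
  std::fill(W.begin(), W.end(), NA_REAL);

  for (int k = 0; k < K; ++k) {
    double mean = 0.0;
    for (int i = 0; i < nu; ++i) mean += counts(i, k);
    mean /= nu;
    const double eps = 1e-9 * (1.0 + std::fabs(mean));

    std::vector<int> donors, receivers;
    for (int i = 0; i < nu; ++i) {
      double diff = counts(i, k) - mean;
      if (diff > eps) donors.push_back(i);
      else if (diff < -eps) receivers.push_back(i);
    }
    if (donors.empty() || receivers.empty()) {
      D[k] = 0.0;
      continue;
    }
    int m = static_cast<int>(donors.size());
    int n = static_cast<int>(receivers.size());
    std::vector<double> c(static_cast<size_t>(m) * n);
    std::vector<double> s(m), d(n);
    double ssum = 0.0, dsum = 0.0;
    for (int a = 0; a < m; ++a) {
      s[a] = counts(donors[a], k) - mean;
      ssum += s[a];
    }
    for (int b = 0; b < n; ++b) {
      d[b] = mean - counts(receivers[b], k);
      dsum += d[b];
    }
    for (double& x : d) x *= ssum / dsum;
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < n; ++b)
        c[static_cast<size_t>(a) * n + b] = dist(donors[a], receivers[b]);

    TPResult res = tp_solve(c, m, n, s, d);
    D[k] = res.cost;

    for (int a = 0; a < m; ++a) {
      double w = 0.0;
      for (int b = 0; b < n; ++b)
        w += res.flow[static_cast<size_t>(a) * n + b] *
             c[static_cast<size_t>(a) * n + b];
      W(donors[a], k) = w / s[a];
    }
    for (int b = 0; b < n; ++b) {
      double w = 0.0;
      for (int a = 0; a < m; ++a)
        w += res.flow[static_cast<size_t>(a) * n + b] *
             c[static_cast<size_t>(a) * n + b];
      W(receivers[b], k) = w / d[b];
    }
  }
  return List::create(_["D"] = D, _["W"] = W);
}
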