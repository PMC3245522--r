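#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-Hastings chain over conformations with single-point
// spherical proposals.  Modes:
//   0 : 5C, fixed psi      -- per-pair Gaussian terms, O(deg(i)) update
//   1 : Hi-C               -- beta-normalized counts, var = mu + kappa
//   2 : 5C, psi-normalized -- psi refit per evaluation (scale-invariant),
//                             used by the LOOCV fitting procedure
// The RNG is R's own (seeded via set.seed on the R side).

static inline double log2pi() { return 1.8378770664093454836; }

struct Model {
  int mode;
  double alpha, psi, kappa;
  const std::vector<int> *pi, *pj;
  const std::vector<double> *value, *sigma;
  double vsum;
};

// Gaussian log density with variance var
static inline double ldens(double x, double mu, double var) {
  double z = x - mu;
  return -0.5 * (log2pi() + std::log(var)) - z * z / (2.0 * var);
}

// d^(-alpha) with fast paths for the common integer exponents
static inline double dpow(double d, double alpha) {
  if (alpha == 2.0) return 1.0 / (d * d);
  if (alpha == 1.0) return 1.0 / d;
  if (alpha == 3.0) return 1.0 / (d * d * d);
  return std::pow(d, -alpha);
}

// total log posterior in normalized modes, given q = d^(-alpha)
static double total_normalized(const Model &M, const std::vector<double> &q) {
  double S = 0.0;
  size_t m = q.size();
  for (size_t p = 0; p < m; ++p) {
    if (!R_FINITE(q[p])) return R_NegInf;
    S += q[p];
  }
  double beta = M.vsum / S;
  double tot = 0.0;
  for (size_t p = 0; p < m; ++p) {
    double mu = beta * q[p];
    double var = (M.mode == 1) ? (mu + M.kappa)
                               : (*M.sigma)[p] * (*M.sigma)[p];
    tot += ldens((*M.value)[p], mu, var);
  }
  return tot;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericMatrix points0,
                   IntegerVector pair_i, IntegerVector pair_j,
                   NumericVector value, NumericVector sigma,
                   double alpha, double psi, double kappa, int mode,
                   double radius,
                   double iter_from, double iter_to,
                   NumericVector snap_iters,
                   bool greedy) {
  const int n = points0.nrow();
  const int m = pair_i.size();
  if (m == 0) stop("dataset has no measured pairs");

  std::vector<double> X(n), Y(n), Z(n);
  for (int k = 0; k < n; ++k) {
    X[k] = points0(k, 0); Y[k] = points0(k, 1); Z[k] = points0(k, 2);
  }
  std::vector<int> pi(m), pj(m);
  std::vector<double> val(m), sig(m);
  double vsum = 0.0;
  for (int p = 0; p < m; ++p) {
    pi[p] = pair_i[p] - 1; pj[p] = pair_j[p] - 1;
    val[p] = value[p];
    sig[p] = (sigma.size() == m) ? sigma[p] : 1.0;
    vsum += val[p];
  }

  // adjacency: pairs touching each point
  std::vector<std::vector<int> > adj(n);
  for (int p = 0; p < m; ++p) { adj[pi[p]].push_back(p); adj[pj[p]].push_back(p); }

  Model M; M.mode = mode; M.alpha = alpha; M.psi = psi; M.kappa = kappa;
  M.pi = &pi; M.pj = &pj; M.value = &val; M.sigma = &sig; M.vsum = vsum;

  // initialize caches
  std::vector<double> terms(m), q(m), lconst(m);
  double total = 0.0;
  for (int p = 0; p < m; ++p) {
    double dx = X[pi[p]] - X[pj[p]], dy = Y[pi[p]] - Y[pj[p]],
           dz = Z[pi[p]] - Z[pj[p]];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (mode == 0) {
      lconst[p] = -0.5 * (log2pi() + 2.0 * std::log(sig[p]));
      if (d <= 0.0) { terms[p] = R_NegInf; }
      else {
        double mu = psi * dpow(d, alpha);
        double z = (val[p] - mu) / sig[p];
        terms[p] = lconst[p] - 0.5 * z * z;
      }
      total += terms[p];
    } else {
      q[p] = (d > 0.0) ? dpow(d, alpha) : R_PosInf;
    }
  }
  if (mode != 0) total = total_normalized(M, q);

  const long long t_from = (long long) iter_from;
  const long long t_to = (long long) iter_to;
  const int nsnap = snap_iters.size();
  std::vector<long long> snaps(nsnap);
  for (int s = 0; s < nsnap; ++s) snaps[s] = (long long) snap_iters[s];
  List snap_points(nsnap);
  NumericVector snap_lp(nsnap);
  int sp = 0;

  std::vector<double> tnew, qnew;
  tnew.reserve(n); qnew.reserve(n);
  long long accepted = 0;

  for (long long t = t_from + 1; t <= t_to; ++t) {
    // pick a point and a displacement uniform in the ball of radius r
    int i = (int) (unif_rand() * n);
    if (i >= n) i = n - 1;
    double ux, uy, uz;
    do {
      ux = 2.0 * unif_rand() - 1.0;
      uy = 2.0 * unif_rand() - 1.0;
      uz = 2.0 * unif_rand() - 1.0;
    } while (ux * ux + uy * uy + uz * uz > 1.0);
    double nx = X[i] + radius * ux, ny = Y[i] + radius * uy,
           nz = Z[i] + radius * uz;

    const std::vector<int> &touch = adj[i];
    double total_new;
    if (mode == 0) {
      tnew.resize(touch.size());
      double delta_terms = 0.0;
      bool bad = false;
      for (size_t a = 0; a < touch.size(); ++a) {
        int p = touch[a];
        int o = (pi[p] == i) ? pj[p] : pi[p];
        double dx = X[o] - nx, dy = Y[o] - ny, dz = Z[o] - nz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d <= 0.0) { tnew[a] = R_NegInf; bad = true; }
        else {
          double mu = psi * dpow(d, alpha);
          double z = (val[p] - mu) / sig[p];
          tnew[a] = lconst[p] - 0.5 * z * z;
        }
        delta_terms += tnew[a] - terms[p];
      }
      total_new = bad ? R_NegInf : total + delta_terms;
      if (!R_FINITE(total)) {
        // recover exactly if the running total ever became non-finite
        total_new = 0.0;
        for (int p = 0; p < m; ++p) total_new += terms[p];
        for (size_t a = 0; a < touch.size(); ++a)
          total_new += tnew[a] - terms[touch[a]];
        if (bad) total_new = R_NegInf;
      }
    } else {
      qnew.resize(touch.size());
      for (size_t a = 0; a < touch.size(); ++a) {
        int p = touch[a];
        int o = (pi[p] == i) ? pj[p] : pi[p];
        double dx = X[o] - nx, dy = Y[o] - ny, dz = Z[o] - nz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        qnew[a] = (d > 0.0) ? dpow(d, alpha) : R_PosInf;
      }
      for (size_t a = 0; a < touch.size(); ++a) q[touch[a]] = qnew[a];
      total_new = total_normalized(M, q);
      // roll back; re-applied below on acceptance
      for (size_t a = 0; a < touch.size(); ++a) {
        int p = touch[a];
        int o = (pi[p] == i) ? pj[p] : pi[p];
        double dx = X[o] - X[i], dy = Y[o] - Y[i], dz = Z[o] - Z[i];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        q[p] = (d > 0.0) ? dpow(d, alpha) : R_PosInf;
      }
    }

    double delta = total_new - total;
    bool accept;
    if (R_FINITE(total_new) && delta >= 0.0) accept = true;
    else if (greedy || !R_FINITE(total_new)) accept = false;
    else accept = (unif_rand() < std::exp(delta));

    if (accept) {
      X[i] = nx; Y[i] = ny; Z[i] = nz;
      if (mode == 0) {
        for (size_t a = 0; a < touch.size(); ++a) terms[touch[a]] = tnew[a];
      } else {
        for (size_t a = 0; a < touch.size(); ++a) q[touch[a]] = qnew[a];
      }
      total = total_new;
      ++accepted;
    }

    while (sp < nsnap && t == snaps[sp]) {
      NumericMatrix P(n, 3);
      for (int k = 0; k < n; ++k) { P(k,0)=X[k]; P(k,1)=Y[k]; P(k,2)=Z[k]; }
      // exact resummation of the cached terms avoids incremental drift
      if (mode == 0) {
        double tt = 0.0;
        for (int p = 0; p < m; ++p) tt += terms[p];
        total = tt;
      }
      snap_points[sp] = P;
      snap_lp[sp] = total;
      ++sp;
    }
  }

  if (mode == 0) {           // final exact resummation
    double tt = 0.0;
    for (int p = 0; p < m; ++p) tt += terms[p];
    total = tt;
  }
  NumericMatrix P(n, 3);
  for (int k = 0; k < n; ++k) { P(k,0)=X[k]; P(k,1)=Y[k]; P(k,2)=Z[k]; }
  return List::create(_["points"] = P,
                      _["log_posterior"] = total,
                      _["snapshots"] = snap_points,
                      _["snapshot_lp"] = snap_lp,
                      _["accepted"] = (double) accepted);
}
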