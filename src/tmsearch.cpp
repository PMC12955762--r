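// Iterative fragment-seed TM-score maximization kernel.
// For each contiguous seed window: Kabsch superposition on the seed, then
// refinement sweeps over distance cutoffs (keep pairs with d < d_cut,
// re-superpose, until the kept set is stable). Both normalizations are
// scored at every visited superposition and their maxima tracked.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// proper rotation R (applied as X * R) and translation minimizing |X*R + t - Y|
static void kabsch3(const arma::mat &X, const arma::mat &Y,
                    arma::mat &R, arma::rowvec &t, double &rmsd) {
  arma::rowvec cx = arma::mean(X, 0);
  arma::rowvec cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx;
  arma::mat Yc = Y.each_row() - cy;
  arma::mat H = Xc.t() * Yc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U) * arma::det(V) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  R = U * D * V.t();
  t = cy - cx * R;
  arma::mat dev = Xc * R - Yc;
  rmsd = std::sqrt(arma::accu(dev % dev) / X.n_rows);
}

// [[Rcpp::export(name = ".tm_refine")]]
List tm_refine(const arma::mat &P, const arma::mat &Q,
               const IntegerMatrix &seeds, // columns: start (0-based), length
               double d0q, double d0t, int Lq, int Lt,
               const arma::vec &d_cuts, int max_iter) {
  const int n = P.n_rows;
  double best_q = -1.0, best_t = -1.0;
  arma::mat best_R_q(3, 3, arma::fill::eye), best_R_t(3, 3, arma::fill::eye);
  arma::rowvec best_tr_q(3, arma::fill::zeros), best_tr_t(3, arma::fill::zeros);
  double best_rmsd_q = 0.0, best_rmsd_t = 0.0;
  const double inv_d0q2 = 1.0 / (d0q * d0q);
  const double inv_d0t2 = 1.0 / (d0t * d0t);

  arma::vec d2(n);
  auto consider = [&](const arma::mat &R, const arma::rowvec &t, double rmsd) {
    arma::mat Pt = P * R;
    Pt.each_row() += t;
    arma::mat dev = Pt - Q;
    d2 = arma::sum(dev % dev, 1);
    double sq = 0.0, st = 0.0;
    for (int i = 0; i < n; ++i) {
      sq += 1.0 / (1.0 + d2(i) * inv_d0q2);
      st += 1.0 / (1.0 + d2(i) * inv_d0t2);
    }
    sq /= Lq;
    st /= Lt;
    if (sq > best_q) {
      best_q = sq; best_R_q = R; best_tr_q = t; best_rmsd_q = rmsd;
    }
    if (st > best_t) {
      best_t = st; best_R_t = R; best_tr_t = t; best_rmsd_t = rmsd;
    }
  };

  arma::mat R;
  arma::rowvec t;
  double rmsd;
  arma::uvec sel, keep;

  for (int si = 0; si < seeds.nrow(); ++si) {
    int start = seeds(si, 0), len = seeds(si, 1);
    if (len < 3) continue;
    arma::uvec seed_idx = arma::regspace<arma::uvec>(start, start + len - 1);
    kabsch3(P.rows(seed_idx), Q.rows(seed_idx), R, t, rmsd);
    consider(R, t, rmsd);
    arma::vec d2_seed = d2; // distances at the seed superposition
    for (arma::uword ci = 0; ci < d_cuts.n_elem; ++ci) {
      sel = seed_idx;
      double dc = d_cuts(ci);
      arma::vec d2_cur = d2_seed;
      for (int it = 0; it < max_iter; ++it) {
        keep = arma::find(d2_cur < dc * dc);
        while (keep.n_elem < 3) {
          dc += 0.5;
          keep = arma::find(d2_cur < dc * dc);
        }
        if (keep.n_elem == sel.n_elem && arma::all(keep == sel)) break;
        sel = keep;
        kabsch3(P.rows(sel), Q.rows(sel), R, t, rmsd);
        consider(R, t, rmsd);
        d2_cur = d2;
      }
    }
  }

  bool q_wins = best_q >= best_t;
  return List::create(
    _["tm_query"] = best_q, _["tm_target"] = best_t,
    _["rotation"] = q_wins ? best_R_q : best_R_t,
    _["translation"] = q_wins ? NumericVector(best_tr_q.begin(), best_tr_q.end())
                              : NumericVector(best_tr_t.begin(), best_tr_t.end()),
    _["rmsd"] = q_wins ? best_rmsd_q : best_rmsd_t);
}
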