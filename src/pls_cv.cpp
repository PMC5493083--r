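// Cross-validated PLS1 (NIPALS) PRESS kernel.
//
// For each held-out fold: autoscale the training block (center, unit
// variance), extract up to max_comp latent components by the PLS1 NIPALS
// recursion (w = X'y / ||X'y||, t = Xw, p = X't/t't, q = y't/t't,
// deflate X), and accumulate the squared prediction error of the held-out
// rows cumulatively per component count. Test rows are deflated with the
// training loadings, which gives exactly the prediction of a model
// refitted without the fold. Columns constant within a training block
// contribute nothing (scale forced to 1, centered values ~0).
//
// Used as the genetic-algorithm fitness kernel and for PLS component
// selection; its agreement with the pure-R per-fold refit path is tested.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::NumericVector pls1_cv_press(const arma::mat& X, const arma::vec& y,
                                  const arma::ivec& fold, int max_comp) {
  const arma::uword n = X.n_rows, k = X.n_cols;
  if (y.n_elem != n || fold.n_elem != n)
    Rcpp::stop("X, y and fold must have matching rows");
  if (max_comp < 1) Rcpp::stop("max_comp must be >= 1");

  arma::ivec ids = arma::unique(fold);
  arma::vec press(static_cast<arma::uword>(max_comp), arma::fill::zeros);

  for (arma::uword f = 0; f < ids.n_elem; ++f) {
    arma::uvec test = arma::find(fold == ids(f));
    arma::uvec train = arma::find(fold != ids(f));
    if (train.n_elem < 3) Rcpp::stop("training fold too small");

    arma::mat Xtr = X.rows(train);
    arma::mat Xte = X.rows(test);
    arma::vec ytr = y.elem(train);

    arma::rowvec mu = arma::mean(Xtr, 0);
    arma::rowvec sdv = arma::stddev(Xtr, 0, 0);  // denominator n-1
    sdv.elem(arma::find(sdv < 1e-12)).ones();
    Xtr.each_row() -= mu;  Xtr.each_row() /= sdv;
    Xte.each_row() -= mu;  Xte.each_row() /= sdv;

    double ybar = arma::mean(ytr);
    arma::vec yc = ytr - ybar;

    arma::vec pred(test.n_elem, arma::fill::zeros);
    int a_done = 0;
    for (int a = 0; a < max_comp; ++a) {
      arma::vec w = Xtr.t() * yc;
      double wn = arma::norm(w);
      if (wn < 1e-12) break;  // variance exhausted
      w /= wn;
      arma::vec t = Xtr * w;
      double tt = arma::dot(t, t);
      if (tt < 1e-12) break;
      arma::vec p = (Xtr.t() * t) / tt;
      double q = arma::dot(yc, t) / tt;

      arma::vec t_te = Xte * w;
      pred += q * t_te;

      double sq = 0.0;
      for (arma::uword m = 0; m < test.n_elem; ++m) {
        double e = y(test(m)) - (ybar + pred(m));
        sq += e * e;
      }
      press(a) += sq;

      Xtr -= t * p.t();
      Xte -= t_te * p.t();
      yc -= q * t;
      a_done = a + 1;
    }
    // rank exhausted before max_comp: later counts predict like the last
    for (int a = a_done; a < max_comp; ++a) {
      double sq = 0.0;
      for (arma::uword m = 0; m < test.n_elem; ++m) {
        double e = y(test(m)) - (ybar + pred(m));
        sq += e * e;
      }
      press(a) += sq;
    }
    (void)k;
  }
  return Rcpp::wrap(press);
}
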