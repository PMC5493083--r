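#' Cross-validated Q2 and RMSE
#'
#' Leave-`leave_out`-out cross-validation of any refittable model.
#' With `leave_out = 1` (deterministic) each compound is predicted by a
#' model refit without it; `PRESS = sum((y_i - yhat_(i))^2)`,
#' `Q2 = 1 - PRESS / sum((y_i - ybar)^2)` with `ybar` the mean of the
#' full calibration set (the standard QSAR convention), and
#' `RMSE_CV = sqrt(PRESS / n)`. With `leave_out = 3` the compounds are
#' randomly partitioned into disjoint triplets covering the set (a
#' non-divisible remainder forms one smaller group), repeated `n_rounds`
#' times with the statistics averaged.
#'
#' @param fit_fun function `(X, y) -> model` where the model answers
#'   [predict()]; e.g. `function(X, y) fit_ols(X, y)` or a PLS refitter
#'   with fixed component count.
#' @param X numeric descriptor matrix (the columns the model uses).
#' @param y activity vector; must not be constant.
#' @param leave_out fold size; 1 and 3 are the conventional choices.
#' @param n_rounds rounds of random coverings when `leave_out > 1`
#'   (default 10).
#' @param seed seed for the random coverings (ignored for
#'   `leave_out = 1`).
#' @return List with `q2`, `rmse_cv`, `press`, `leave_out`, `n_rounds`
#'   (1 for LOO).
#' @export
q2_cv <- function(fit_fun, X, y, leave_out = 1, n_rounds = 10, seed = 1) {
  X <- as_descriptor_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (var(y) <= 0) stop("zero-variance activity vector")
  if (leave_out < 1 || leave_out >= n) stop("leave_out must be in [1, n)")
  tss <- sum((y - mean(y))^2)
  press_for <- function(fold) {
    pred <- numeric(n)
    for (f in unique(fold)) {
      test <- which(fold == f)
      m <- tryCatch(fit_fun(X[-test, , drop = FALSE], y[-test]),
                    error = function(e) {
                      stop("refit failed in fold ", f, ": ",
                           conditionMessage(e))
                    })
      pred[test] <- predict(m, X[test, , drop = FALSE])
    }
    sum((y - pred)^2)
  }
  if (leave_out == 1) {
    press <- press_for(seq_len(n))
    return(list(q2 = 1 - press / tss, rmse_cv = sqrt(press / n),
                press = press, leave_out = 1L, n_rounds = 1L))
  }
  res <- with_seed(seed, {
    vapply(seq_len(n_rounds), function(r) press_for(make_lno_folds(n, leave_out)),
           numeric(1))
  })
  list(q2 = mean(1 - res / tss), rmse_cv = mean(sqrt(res / n)),
       press = mean(res), leave_out = as.integer(leave_out),
       n_rounds = as.integer(n_rounds))
}

#' External prediction statistics
#'
#' Computes `R2p`, the squared product-moment correlation between
#' observed and predicted activities on an external validation set. By
#' construction this convention is shift- and scale-invariant: systematic
#' bias does not lower it (a known weakness, documented rather than
#' hidden). When the calibration mean `y_cal_mean` is supplied, the
#' stricter external `Q2_F1 = 1 - PRESS_ext / sum((y_val - y_cal_mean)^2)`
#' is reported alongside.
#'
#' @param model a fitted `qsar_model`.
#' @param X_val validation descriptor matrix (disjoint from training).
#' @param y_val observed validation activities (length >= 3).
#' @param y_cal_mean mean calibration activity, for `q2_ext` (optional).
#' @return List with `r2_p` and `q2_ext` (`NA` unless `y_cal_mean`
#'   given).
#' @export
r2_prediction <- function(model, X_val, y_val, y_cal_mean = NULL) {
  y_val <- as.numeric(y_val)
  if (length(y_val) < 3) stop("need at least 3 validation compounds")
  pred <- predict(model, X_val)
  if (sd(pred) <= 0) stop("constant predictions on the validation set")
  if (sd(y_val) <= 0) stop("constant observed validation activities")
  q2_ext <- NA_real_
  if (!is.null(y_cal_mean)) {
    q2_ext <- 1 - sum((y_val - pred)^2) / sum((y_val - y_cal_mean)^2)
  }
  list(r2_p = cor(y_val, pred)^2, q2_ext = q2_ext)
}

#' Y-randomization (response scrambling) test
#'
#' Permutes the activity vector `n_iter` times, refits the model each
#' time, and records the calibration R2 and leave-one-out Q2 of every
#' scrambled model next to the original. A sound model's statistics must
#' exceed all the scrambled ones; on pure-noise data original and
#' scrambled R2 are indistinguishable. By default the refit keeps the
#' descriptor subset fixed (pass a selecting `fit_fun`, e.g. a
#' [stepwise_mlr()] wrapper, for the stricter full re-selection variant).
#'
#' @param fit_fun function `(X, y) -> qsar_model`.
#' @param X descriptor matrix handed to `fit_fun`.
#' @param y activity vector.
#' @param n_iter permutations (default 10).
#' @param seed integer seed.
#' @param q2 if `FALSE`, skip the (costlier) Q2 of each scrambled model.
#' @return Object of class `y_randomization`: `iterations` data frame
#'   (`iteration`, `r2`, `q2`), `original` (list `r2`, `q2`),
#'   `permutations` (n_iter x n matrix of scrambled activities), `seed`.
#' @export
y_randomization <- function(fit_fun, X, y, n_iter = 10, seed = 1, q2 = TRUE) {
  X <- as_descriptor_matrix(X)
  y <- as.numeric(y)
  if (n_iter < 1) stop("n_iter must be >= 1")
  orig_model <- fit_fun(X, y)
  orig <- list(r2 = orig_model$r2_c,
               q2 = if (q2) q2_cv(fit_fun, X, y, leave_out = 1)$q2 else NA_real_)
  perms <- matrix(NA_real_, n_iter, length(y))
  r2v <- numeric(n_iter); q2v <- rep(NA_real_, n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      yp <- sample(y)
      perms[i, ] <- yp
      m <- fit_fun(X, yp)
      r2v[i] <- m$r2_c
      if (q2) q2v[i] <- q2_cv(fit_fun, X, yp, leave_out = 1)$q2
    }
  })
  structure(list(iterations = data.frame(iteration = seq_len(n_iter),
                                         r2 = r2v, q2 = q2v),
                 original = orig, permutations = perms, seed = seed),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, digits = 3, ...) {
  cat(sprintf("Y-randomization: %d permutations\n", nrow(x$iterations)))
  cat(sprintf("  original:  R2 = %.*f, Q2(LOO) = %.*f\n",
              digits, x$original$r2, digits, x$original$q2))
  cat(sprintf("  scrambled: max R2 = %.*f, max Q2 = %.*f\n",
              digits, max(x$iterations$r2), digits,
              suppressWarnings(max(x$iterations$q2, na.rm = TRUE))))
  invisible(x)
}
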