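#' Partial least squares regression (NIPALS)
#'
#' Fits a PLS1 regression by the NIPALS algorithm: descriptors are
#' autoscaled internally (centered, unit variance; constant columns are
#' rejected), the activity is centered, and latent components are
#' extracted one at a time (weights, scores, loadings, y-loading, with
#' deflation of both blocks after each round). The final model is
#' expressed back in original descriptor units as an intercept plus a
#' named coefficient vector, so [predict.qsar_model()] works on raw
#' descriptor tables.
#'
#' When `n_components` is `NULL` the component count is chosen to
#' maximize leave-one-out Q2, capped at `min(6, rank(X))` — the same rule
#' used inside the GA fitness.
#'
#' @param X numeric descriptor matrix (named columns, at least one).
#' @param y numeric activity vector; must not be constant.
#' @param n_components number of latent components, at most the rank of
#'   the scaled design; `NULL` (default) selects by LOO Q2.
#' @param tol convergence tolerance on the relative change of the score
#'   vector inside each NIPALS round (with a single response the
#'   recursion converges on the second pass).
#' @param max_iter maximum NIPALS iterations per component; exceeding it
#'   is an error.
#' @return A `qsar_model` (method `"PLS"`) with `n_components` set.
#' @export
fit_pls <- function(X, y, n_components = NULL, tol = 1e-9, max_iter = 200) {
  X <- as_descriptor_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(X)
  if (k < 1) stop("PLS needs at least one descriptor column")
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (var(y) <= 0) stop("zero-variance activity vector")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv < 1e-12)) {
    stop("constant descriptor column(s): ",
         paste(colnames(X)[sdv < 1e-12], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  rank_x <- qr(Xs)$rank
  if (is.null(n_components)) {
    a_max <- min(6L, rank_x)
    q2 <- pls_cv_q2(X, y, fold = seq_len(n), max_comp = a_max)
    n_components <- which.max(q2)
  }
  if (n_components < 1 || n_components > rank_x) {
    stop("n_components must be between 1 and rank(X) = ", rank_x)
  }
  ybar <- mean(y)
  yc <- y - ybar
  W <- matrix(0, k, n_components)
  P <- matrix(0, k, n_components)
  qv <- numeric(n_components)
  Xd <- Xs
  for (a in seq_len(n_components)) {
    u <- yc
    t_old <- rep(0, n)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) {
        stop("NIPALS failed to converge within max_iter = ", max_iter,
             " iterations (component ", a, ")")
      }
      w <- drop(crossprod(Xd, u))
      wn <- sqrt(sum(w^2))
      if (wn < 1e-12) stop("descriptor variance exhausted at component ", a)
      w <- w / wn
      tt <- drop(Xd %*% w)
      qa <- sum(u * tt) / sum(tt^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(sqrt(sum(tt^2)), 1e-300)) break
      t_old <- tt
      u <- yc * qa / max(qa^2, 1e-300)  # single response: direction of yc
    }
    pa <- drop(crossprod(Xd, tt)) / sum(tt^2)
    qa <- sum(yc * tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pa; qv[a] <- qa
    Xd <- Xd - tcrossprod(tt, pa)
    yc <- yc - qa * tt
  }
  b_scaled <- drop(W %*% solve(crossprod(P, W), qv))
  b <- b_scaled / sdv
  intercept <- ybar - sum(b * mu)
  fitted <- drop(intercept + X %*% b)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - ybar)^2)
  new_qsar_model(
    intercept = intercept,
    coefficients = stats::setNames(b, colnames(X)),
    n_train = n,
    r2_c = 1 - rss / tss,
    se = sqrt(rss / max(n - n_components - 1, 1)),
    method = "PLS",
    fitted = fitted,
    residuals = res,
    n_components = as.integer(n_components)
  )
}

# Cross-validated Q2 per component count (1..max_comp) from the compiled
# PLS1 kernel. `fold` assigns each row to a held-out group. The Q2
# denominator uses the full-set mean (QSAR convention).
pls_cv_q2 <- function(X, y, fold, max_comp) {
  press <- pls1_cv_press(as.matrix(X), as.numeric(y),
                         as.integer(fold), as.integer(max_comp))
  1 - press / sum((y - mean(y))^2)
}
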