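#' Stepwise multiple linear regression (partial-F entry/removal)
#'
#' Classic forward-entry / backward-removal stepwise selection on
#' partial-F p-values, the "stepwise MLR" used on each calibration split.
#' At each iteration the excluded descriptor with the smallest partial-F
#' p-value enters if that p-value is below `p_enter`; then any included
#' descriptor whose partial-F p-value exceeds `p_remove` is removed
#' (largest first). Iteration stops when nothing changes; entry stops
#' once `max_terms` descriptors are in the model. The procedure is
#' deterministic given `X` and `y`; p-value ties are broken by column
#' order.
#'
#' Defaults `p_enter = 0.05`, `p_remove = 0.10` are the conventional
#' probability-of-F criteria; `max_terms = 7` matches the largest elected
#' split model.
#'
#' @param X numeric descriptor matrix (named columns).
#' @param y numeric activity vector.
#' @param p_enter entry threshold on the partial-F p-value; must be
#'   strictly less than `p_remove` (oscillation guard).
#' @param p_remove removal threshold on the partial-F p-value.
#' @param max_terms maximum number of descriptors in the model; must be
#'   below `n - 2`.
#' @return A `qsar_model` (method `"STEPWISE_MLR"`) fit by [fit_ols()] on
#'   the selected descriptors, in order of entry. May be intercept-only
#'   if nothing passes `p_enter`.
#' @export
stepwise_mlr <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                         max_terms = 7) {
  X <- as_descriptor_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (p_enter >= p_remove) {
    stop("p_enter must be < p_remove (risk of entry/removal oscillation)")
  }
  if (max_terms >= n - 2) stop("max_terms must be < n - 2")
  rss0_fun <- function(idx) {
    f <- .lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    list(rss = sum(f$residuals^2), rank = f$rank)
  }
  included <- integer(0)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero-variance activity vector")
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 200L) break  # safety; p_enter < p_remove precludes cycling
    changed <- FALSE
    cur <- rss0_fun(included)
    # forward entry
    if (length(included) < max_terms) {
      cand <- setdiff(seq_len(ncol(X)), included)
      pvals <- vapply(cand, function(j) {
        f <- .lm.fit(cbind(1, X[, c(included, j), drop = FALSE]), y)
        if (f$rank < length(included) + 2L) return(NA_real_)  # collinear
        rss1 <- sum(f$residuals^2)
        df2 <- n - length(included) - 2L
        Fj <- (cur$rss - rss1) / (rss1 / df2)
        pf(Fj, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (any(!is.na(pvals))) {
        best <- which.min(pvals)  # first minimum: column-order tie-break
        if (pvals[best] < p_enter) {
          included <- c(included, cand[best])
          changed <- TRUE
          cur <- rss0_fun(included)
        }
      }
    }
    # backward removal
    while (length(included) > 0) {
      k <- length(included)
      df2 <- n - k - 1L
      pvals <- vapply(seq_along(included), function(m) {
        rss_wo <- rss0_fun(included[-m])$rss
        Fm <- (rss_wo - cur$rss) / (cur$rss / df2)
        pf(Fm, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] > p_remove) {
        included <- included[-worst]
        changed <- TRUE
        cur <- rss0_fun(included)
      } else break
    }
    if (!changed) break
  }
  fit_ols(X[, included, drop = FALSE], y, method = "STEPWISE_MLR")
}
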