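#' Leverage (hat) values
#'
#' Computes `h_q = x_q' (X'X)^-1 x_q` for query compounds against a
#' calibration design, with all row vectors intercept-augmented. For
#' query rows that are training rows this is the hat-matrix diagonal;
#' calibration leverages lie in (0, 1] and sum to `k + 1`.
#'
#' @param X_train calibration descriptor matrix (full column rank after
#'   adding the intercept).
#' @param X_query descriptors of the compounds to assess; defaults to the
#'   training rows themselves.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverages <- function(X_train, X_query = X_train) {
  Xt <- cbind(1, as.matrix(X_train))
  Xq <- cbind(1, as.matrix(X_query))
  if (ncol(Xq) != ncol(Xt)) stop("query columns must match training columns")
  if (qr(Xt)$rank < ncol(Xt)) {
    stop("rank-deficient calibration design for leverage computation")
  }
  xtx_inv <- solve(crossprod(Xt))
  unname(rowSums((Xq %*% xtx_inv) * Xq))
}

#' Warning leverage threshold
#'
#' The customary applicability-domain cutoff `h* = 3 (k + 1) / n`, where
#' `k` is the number of model descriptors and `n` the number of
#' compounds. A compound with leverage above `h*` is a structural
#' extrapolation. For the published six-descriptor models over the
#' 50-compound series, `h* = 3 * 7 / 50 = 0.42`.
#'
#' @param k number of model descriptors (>= 0).
#' @param n number of compounds (> 0).
#' @return `3 * (k + 1) / n`.
#' @export
warning_leverage <- function(k, n) {
  if (k < 0 || n <= 0) stop("need k >= 0 and n > 0")
  3 * (k + 1) / n
}

#' Williams-plot table (applicability domain assessment)
#'
#' Tabulates, for calibration and (optionally) validation compounds, the
#' leverage against the calibration design restricted to the model's
#' descriptors, the standardized residual, and the resulting outlier
#' flags: `response_outlier` when |standardized residual| exceeds
#' `residual_limit` (default 2.5 SD for MLR-type models, 3.0 for PLS/
#' GA-PLS), `structural_outlier` when leverage exceeds the warning
#' leverage [warning_leverage()].
#'
#' The residual scale is, by default, the population standard deviation
#' (divisor n) of the calibration residuals; `residual_scale =
#' "unbiased"` uses `sqrt(RSS / (n - k - 1))` instead. The `n` in the
#' warning leverage is by default the total number of tabulated
#' compounds (`h_star_n = "all"`, matching the published 0.42 for
#' 6 descriptors and 50 compounds); `"calibration"` uses the calibration
#' count.
#'
#' @param model fitted `qsar_model`.
#' @param X_cal,y_cal calibration descriptors and activities (the data
#'   the model was fit on).
#' @param X_val,y_val optional validation set.
#' @param residual_limit response-outlier cutoff in SD units; default
#'   2.5, or 3.0 when `model$method == "PLS"`.
#' @param h_star_n `"all"` (default) or `"calibration"`.
#' @param residual_scale `"population"` (default) or `"unbiased"`.
#' @return Object of class `qsar_domain`: a data frame with columns
#'   `compound_id`, `role`, `leverage`, `std_residual`,
#'   `response_outlier`, `structural_outlier`, and attributes `h_star`,
#'   `residual_limit`, `residual_sd`.
#' @export
williams_table <- function(model, X_cal, y_cal, X_val = NULL, y_val = NULL,
                           residual_limit = NULL,
                           h_star_n = c("all", "calibration"),
                           residual_scale = c("population", "unbiased")) {
  h_star_n <- match.arg(h_star_n)
  residual_scale <- match.arg(residual_scale)
  if (is.null(residual_limit)) {
    residual_limit <- if (identical(model$method, "PLS")) 3.0 else 2.5
  }
  desc <- names(coef(model))
  if (length(desc) == 0) stop("model has no descriptors")
  Xc <- as.matrix(X_cal)[, desc, drop = FALSE]
  y_cal <- as.numeric(y_cal)
  n_cal <- nrow(Xc)
  k <- length(desc)
  res_cal <- y_cal - predict(model, Xc)
  s <- switch(residual_scale,
    population = sqrt(sum((res_cal - mean(res_cal))^2) / n_cal),
    unbiased = sqrt(sum(res_cal^2) / max(n_cal - k - 1, 1))
  )
  if (s < 1e-12) {
    if (max(abs(res_cal)) < 1e-10) {
      std_cal <- rep(0, n_cal)
      s <- 0
    } else {
      stop("zero residual variance with non-zero residuals")
    }
  } else {
    std_cal <- res_cal / s
  }
  h_cal <- leverages(Xc)
  ids_cal <- rownames(Xc)
  if (is.null(ids_cal)) ids_cal <- paste0("cal", seq_len(n_cal))
  out <- data.frame(compound_id = ids_cal, role = "calibration",
                    leverage = h_cal, std_residual = std_cal,
                    stringsAsFactors = FALSE)
  n_val <- 0L
  if (!is.null(X_val)) {
    Xv <- as.matrix(X_val)[, desc, drop = FALSE]
    n_val <- nrow(Xv)
    res_val <- as.numeric(y_val) - predict(model, Xv)
    std_val <- if (s > 0) res_val / s else
      ifelse(abs(res_val) < 1e-10, 0, Inf)
    ids_val <- rownames(Xv)
    if (is.null(ids_val)) ids_val <- paste0("val", seq_len(n_val))
    out <- rbind(out, data.frame(compound_id = ids_val, role = "validation",
                                 leverage = leverages(Xc, Xv),
                                 std_residual = std_val,
                                 stringsAsFactors = FALSE))
  }
  n_for_hstar <- if (h_star_n == "all") n_cal + n_val else n_cal
  h_star <- warning_leverage(k, n_for_hstar)
  out$response_outlier <- abs(out$std_residual) > residual_limit
  out$structural_outlier <- out$leverage > h_star
  rownames(out) <- NULL
  structure(out, h_star = h_star, residual_limit = residual_limit,
            residual_sd = s, class = c("qsar_domain", "data.frame"))
}

#' Williams plot
#'
#' Standardized residuals against leverage, with the warning-leverage and
#' residual-limit boundaries; calibration compounds as filled circles,
#' validation compounds as open triangles.
#'
#' @param x a `qsar_domain` from [williams_table()].
#' @param ... passed to [plot()].
#' @export
plot.qsar_domain <- function(x, ...) {
  h_star <- attr(x, "h_star")
  lim <- attr(x, "residual_limit")
  cal <- x$role == "calibration"
  plot(x$leverage, x$std_residual,
       pch = ifelse(cal, 19, 2),
       xlab = "leverage (h)", ylab = "standardized residual",
       xlim = c(0, max(c(x$leverage, h_star)) * 1.1),
       ylim = range(c(x$std_residual, lim + 0.5, -lim - 0.5)), ...)
  abline(v = h_star, lty = 2)
  abline(h = c(-lim, lim), lty = 3)
  legend("topright", legend = c("calibration", "validation"),
         pch = c(19, 2), bty = "n")
  invisible(x)
}

#' @export
print.qsar_domain <- function(x, ...) {
  cat(sprintf("applicability domain: h* = %.3f, residual limit = %.1f SD\n",
              attr(x, "h_star"), attr(x, "residual_limit")))
  cat(sprintf("  %d response outlier(s), %d structural outlier(s) of %d compounds\n",
              sum(x$response_outlier), sum(x$structural_outlier), nrow(x)))
  NextMethod()
}
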