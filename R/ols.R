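#' Ordinary least squares fit
#'
#' Fits `y = b0 + X b` by QR least squares on raw (unscaled) descriptors,
#' the regression engine underlying [stepwise_mlr()] and all
#' cross-validation refits. Reports the calibration statistics used
#' throughout: `r2_c = 1 - RSS/TSS` and the standard error of regression
#' `se = sqrt(RSS / (n - k - 1))` with `k` descriptors.
#'
#' @param X numeric matrix of descriptors (may have zero columns for an
#'   intercept-only model); column names are used as coefficient names.
#' @param y numeric activity vector.
#' @param method label stored on the model (default `"OLS"`).
#' @return A `qsar_model`: list with `intercept`, named `coefficients`,
#'   `n_train`, `r2_c`, `se`, `method`, `fitted`, `residuals`.
#' @examples
#' x <- cbind(a = 0:3)
#' fit_ols(x, 2 * (0:3) + 1)   # intercept 1, slope 2, r2_c = 1
#' @export
fit_ols <- function(X, y, method = "OLS") {
  X <- as_descriptor_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n <= k + 1) stop("need n > k + 1 observations for OLS")
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero-variance activity vector")
  Xa <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) {
    dep <- colnames(Xa)[qx$pivot[(qx$rank + 1):ncol(Xa)]]
    stop("rank-deficient design: column(s) ", paste(dep, collapse = ", "),
         " linearly dependent on the others")
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(Xa %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  new_qsar_model(
    intercept = unname(beta[1]),
    coefficients = if (k > 0) stats::setNames(beta[-1], colnames(X)) else
      stats::setNames(numeric(0), character(0)),
    n_train = n,
    r2_c = 1 - rss / tss,
    se = sqrt(rss / (n - k - 1)),
    method = method,
    fitted = fitted,
    residuals = res
  )
}

new_qsar_model <- function(intercept, coefficients, n_train, r2_c, se,
                           method, fitted, residuals, n_components = NULL) {
  structure(list(intercept = intercept, coefficients = coefficients,
                 n_train = n_train, r2_c = r2_c, se = se, method = method,
                 n_components = n_components, fitted = fitted,
                 residuals = residuals),
            class = "qsar_model")
}

# Coerce descriptor input (matrix / data.frame / qsar_dataset X) to a
# named numeric matrix; synthesizes names for anonymous columns.
as_descriptor_matrix <- function(X) {
  if (inherits(X, "qsar_dataset")) X <- X$X
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("D", seq_len(ncol(X)))
  }
  X
}

#' Predict activities from a fitted QSAR model
#'
#' @param object a `qsar_model` from [fit_ols()], [stepwise_mlr()] or
#'   [fit_pls()].
#' @param newdata matrix or data frame containing every descriptor column
#'   named in `coef(object)`; extra columns are ignored.
#' @param ... unused.
#' @return Numeric vector of predicted pIC50, in training units.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  nd <- if (inherits(newdata, "qsar_dataset")) newdata$X else newdata
  nd <- as.matrix(nd)
  need <- names(object$coefficients)
  missing <- setdiff(need, colnames(nd))
  if (length(missing)) {
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  }
  if (length(need) == 0) {
    return(rep(object$intercept, nrow(nd)))
  }
  drop(object$intercept + nd[, need, drop = FALSE] %*% object$coefficients)
}

#' @export
coef.qsar_model <- function(object, ...) object$coefficients

#' @export
residuals.qsar_model <- function(object, ...) object$residuals

#' @export
fitted.qsar_model <- function(object, ...) object$fitted

#' @export
print.qsar_model <- function(x, digits = 3, ...) {
  cat(sprintf("%s model (N = %d%s)\n", x$method, x$n_train,
              if (!is.null(x$n_components))
                sprintf(", %d latent components", x$n_components) else ""))
  terms <- c(sprintf("%.*f", digits, x$intercept),
             if (length(x$coefficients))
               sprintf("%+.*f %s", digits, x$coefficients,
                       names(x$coefficients)))
  cat("  pIC50 =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  R2c = %.*f, S.E. = %.*f\n", digits, x$r2_c, digits, x$se))
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  structure(list(model = object), class = "summary.qsar_model")
}

#' @export
print.summary.qsar_model <- function(x, ...) {
  print(x$model)
  m <- x$model
  if (length(m$coefficients)) {
    cat("coefficients:\n")
    print(data.frame(descriptor = names(m$coefficients),
                     coefficient = round(unname(m$coefficients), 3),
                     row.names = NULL))
  }
  invisible(x)
}
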