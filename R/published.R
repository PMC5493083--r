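.published_equations <- list(
  mlr = list(
    name = "MLR_GENERAL",
    intercept = 16.977,
    coefficients = c(`X5A` = -176.806, `HATS4u` = -4.366, `Mor26p` = -1.951,
                     `TIE` = 0.001, `dipole z` = 0.227, `Mor26e` = 0.863),
    reported = list(n = 41, r2_c = 0.771, se = 0.267, q2_loo = 0.637,
                    q2_loo_text = 0.710, rmse_cv = 0.297)
  ),
  gapls = list(
    name = "GAPLS",
    intercept = 9.018,
    coefficients = c(`X5A` = -114.521, `GATS4e` = -1.406, `E3u` = -1.586,
                     `MATS7e` = -2.615, `G1u` = 38.705, `RDF075m` = 0.048),
    reported = list(n = 41, r2_c = 0.755, se = 0.249, q2_loo = 0.653,
                    q2_l3o = 0.834, rmse_cv = 0.266)
  )
)

#' Published reference equations
#'
#' The two published six-descriptor prediction equations for the Hsp90
#' inhibitory pIC50 of 3,4-isoxazolediamides, as fixed, citable
#' predictors:
#'
#' * `MLR_GENERAL` (general stepwise-MLR model):
#'   `pIC50 = 16.977 - 176.806 X5A - 4.366 HATS4u - 1.951 Mor26p
#'   + 0.001 TIE + 0.227 dipole z + 0.863 Mor26e`
#'   (N = 41, R2c = 0.771, S.E. = 0.267, Q2LOO = 0.637, RMS_CV = 0.297;
#'   an accompanying narrative quotes Q2LOO = 0.710 for the same model —
#'   both values are carried in `reported`).
#' * `GAPLS`:
#'   `pIC50 = 9.018 - 114.521 X5A - 1.406 GATS4e - 1.586 E3u
#'   - 2.615 MATS7e + 38.705 G1u + 0.048 RDF075m`
#'   (N = 41, R2c = 0.755, S.E. = 0.249, Q2LOO = 0.653, Q2LTO = 0.834,
#'   RMS_CV = 0.266).
#'
#' The TIE coefficient is printed as 0.001 (+-0.00) and is stored exactly
#' as 0.001; predictions involving large TIE values inherit that
#' truncation.
#'
#' @return Named list of two `published_equation` objects, each with
#'   `name`, `intercept`, `coefficients`, `reported`.
#' @seealso [predict_published()]
#' @export
published_models <- function() {
  lapply(.published_equations, function(e) structure(e, class = "published_equation"))
}

#' @export
print.published_equation <- function(x, ...) {
  cat(sprintf("%s: pIC50 = %.3f %s\n", x$name, x$intercept,
              paste(sprintf("%+.3f %s", x$coefficients, names(x$coefficients)),
                    collapse = " ")))
  cat(sprintf("  reported: N = %d, R2c = %.3f, S.E. = %.3f\n",
              x$reported$n, x$reported$r2_c, x$reported$se))
  invisible(x)
}

# Whitespace/case/punctuation-insensitive descriptor name key, so
# "dipole z", "dipole.z" and "dipole_z" all resolve.
normalize_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Predict pIC50 from a published equation
#'
#' Evaluates one of the two reference equations ([published_models()]) on
#' supplied descriptor values: `intercept + sum(coefficient * value)`.
#' Descriptor names are matched whitespace/case-insensitively. No
#' applicability-domain check is performed; pair with [williams_table()]
#' for that.
#'
#' @param equation `"mlr"` (alias `"MLR_GENERAL"`) or `"gapls"`
#'   (alias `"GAPLS"`).
#' @param newdata named numeric vector, or a matrix/data frame with named
#'   columns, holding every descriptor the equation needs.
#' @return Predicted pIC50 (one value per row of `newdata`).
#' @examples
#' predict_published("mlr", c(X5A = 0, HATS4u = 0, Mor26p = 0, TIE = 0,
#'                            `dipole z` = 0, Mor26e = 0))   # 16.977
#' @export
predict_published <- function(equation, newdata) {
  key <- switch(normalize_name(equation),
                mlr = , mlrgeneral = "mlr",
                gapls = "gapls",
                stop("unknown equation \"", equation,
                     "\" (use \"mlr\" or \"gapls\")"))
  eq <- .published_equations[[key]]
  if (is.null(dim(newdata))) {
    newdata <- matrix(as.numeric(newdata), nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  nd <- as.matrix(newdata)
  hit <- match(normalize_name(names(eq$coefficients)),
               normalize_name(colnames(nd)))
  if (anyNA(hit)) {
    stop("missing required descriptor(s): ",
         paste(names(eq$coefficients)[is.na(hit)], collapse = ", "))
  }
  vals <- nd[, hit, drop = FALSE]
  if (!all(is.finite(vals))) stop("descriptor values must be finite")
  drop(eq$intercept + vals %*% eq$coefficients)
}
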