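#' Combined data-splitting feature selection (CDFS)
#'
#' Runs the full model-building workflow: (optional) preprocessing
#' ([drop_invariant()] then [prune_collinear()]), `n_repeats` repeated
#' calibration/validation splits ([make_splits()]), a descriptor selector
#' on each calibration set ([stepwise_mlr()] or [ga_pls()]) with per-split
#' validation (R2c, S.E., R2p, Q2LOO, RMSE_CV), election of the best
#' split model (highest Q2LOO, ties by R2c), pooling of all selected
#' descriptors, a refit of the selector restricted to the pooled
#' descriptors on one designated split's calibration set (the "general
#' model"), and full validation of that general model: leave-one-out Q2,
#' external R2p, Y-randomization and the leverage applicability domain.
#' Everything is reproducible from the master `seed`.
#'
#' @param dataset a [qsar_dataset()].
#' @param n_validation validation compounds per split (default 9, i.e. a
#'   41-compound calibration set for the 50-compound series).
#' @param n_repeats number of splits (default 5).
#' @param selector `"stepwise"` (default) or `"gapls"`.
#' @param seed master integer seed.
#' @param preprocess run [drop_invariant()] + [prune_collinear()] first
#'   (default `TRUE`).
#' @param dominant_fraction,variance_floor,collinearity_threshold
#'   preprocessing parameters.
#' @param p_enter,p_remove,max_terms stepwise parameters.
#' @param ga named list of [ga_pls()] arguments overriding its defaults
#'   (used when `selector = "gapls"`).
#' @param y_randomization_iters permutations for the Y-randomization test
#'   (default 10).
#' @param general_split index of the split whose calibration set the
#'   general model is refit on (default 1), or `"all"` to refit on every
#'   compound (deviates from the published N = 41 convention).
#' @param stratified passed to [make_splits()].
#' @return Object of class `cdfs_fit`: `preprocess` (reports),
#'   `splits`, `split_table` (per-split statistics data frame),
#'   `split_models`, `best_split`, `pooled_descriptors`, `general_model`,
#'   `validation` (list: `q2`, `rmse_cv`, `r2_p`, `q2_ext`, `n_cal`,
#'   `n_val`), `y_randomization`, `domain`, `manifest`.
#' @export
run_cdfs <- function(dataset, n_validation = 9, n_repeats = 5,
                     selector = c("stepwise", "gapls"), seed = 1,
                     preprocess = TRUE, dominant_fraction = 0.95,
                     variance_floor = 1e-8, collinearity_threshold = 0.9,
                     p_enter = 0.05, p_remove = 0.10, max_terms = 7,
                     ga = list(), y_randomization_iters = 10,
                     general_split = 1, stratified = FALSE) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  selector <- match.arg(selector)
  pre_reports <- list()
  if (preprocess) {
    step1 <- drop_invariant(dataset, dominant_fraction, variance_floor)
    step2 <- prune_collinear(step1$dataset, collinearity_threshold)
    pre_reports <- list(invariant = step1$report, collinear = step2$report)
    dataset <- step2$dataset
  }
  splits <- make_splits(dataset, n_validation, n_repeats, seed,
                        stratified = stratified)

  fit_selector <- function(X, y, stage_seed, pool = NULL) {
    if (!is.null(pool)) X <- X[, pool, drop = FALSE]
    if (selector == "stepwise") {
      stepwise_mlr(X, y, p_enter = p_enter, p_remove = p_remove,
                   max_terms = max_terms)
    } else {
      args <- utils::modifyList(list(X = X, y = y, seed = stage_seed), ga)
      do.call(ga_pls, args)$model
    }
  }
  refitter <- function(model) {
    if (identical(model$method, "PLS")) {
      nc <- model$n_components
      function(X, y) fit_pls(X, y, n_components = min(nc, qr(scale(X))$rank))
    } else {
      function(X, y) fit_ols(X, y)
    }
  }
  validate_model <- function(model, Xcal, ycal, Xval, yval, stage) {
    sel <- names(coef(model))
    if (length(sel) == 0) {
      return(list(q2 = NA_real_, rmse_cv = NA_real_, r2_p = NA_real_,
                  q2_ext = NA_real_))
    }
    rf <- refitter(model)
    cv <- tryCatch(q2_cv(rf, Xcal[, sel, drop = FALSE], ycal, leave_out = 1),
                   error = function(e) stop(stage, ": ", conditionMessage(e)))
    pr <- if (!is.null(Xval)) {
      r2_prediction(model, Xval, yval, y_cal_mean = mean(ycal))
    } else list(r2_p = NA_real_, q2_ext = NA_real_)
    list(q2 = cv$q2, rmse_cv = cv$rmse_cv, r2_p = pr$r2_p,
         q2_ext = pr$q2_ext)
  }

  split_models <- vector("list", n_repeats)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- splits[[r]]
    cal <- match(sp$calibration_ids, dataset$compound_ids)
    val <- match(sp$validation_ids, dataset$compound_ids)
    Xcal <- dataset$X[cal, , drop = FALSE]; ycal <- dataset$activities[cal]
    Xval <- dataset$X[val, , drop = FALSE]; yval <- dataset$activities[val]
    model <- tryCatch(
      fit_selector(Xcal, ycal, substream_seed(seed, 100 + r)),
      error = function(e) stop("split ", r, ", selection stage: ",
                               conditionMessage(e)))
    v <- validate_model(model, Xcal, ycal, Xval, yval,
                        paste0("split ", r, ", validation stage"))
    split_models[[r]] <- model
    rows[[r]] <- data.frame(
      split = r, n_descriptors = length(coef(model)),
      descriptors = paste(names(coef(model)), collapse = ", "),
      r2_c = model$r2_c, se = model$se, r2_p = v$r2_p, q2 = v$q2,
      rmse_cv = v$rmse_cv, stringsAsFactors = FALSE)
  }
  split_table <- do.call(rbind, rows)
  usable <- which(split_table$n_descriptors > 0 & is.finite(split_table$q2))
  if (length(usable) == 0) stop("no split produced a non-empty model")
  # election: maximize Q2(LOO), break ties by R2c
  best_split <- usable[order(-split_table$q2[usable],
                             -split_table$r2_c[usable])][1]
  pooled <- unique(unlist(lapply(split_models, function(m) names(coef(m)))))

  if (identical(general_split, "all")) {
    Xg <- dataset$X; yg <- dataset$activities
    Xgv <- NULL; ygv <- NULL
  } else {
    sp <- splits[[general_split]]
    cal <- match(sp$calibration_ids, dataset$compound_ids)
    val <- match(sp$validation_ids, dataset$compound_ids)
    Xg <- dataset$X[cal, , drop = FALSE]; yg <- dataset$activities[cal]
    Xgv <- dataset$X[val, , drop = FALSE]; ygv <- dataset$activities[val]
  }
  general_model <- tryCatch(
    fit_selector(Xg, yg, substream_seed(seed, 999), pool = pooled),
    error = function(e) stop("general-model stage: ", conditionMessage(e)))
  if (length(coef(general_model)) == 0) {
    stop("general-model stage: stepwise selected no descriptors")
  }
  gv <- validate_model(general_model, Xg, yg, Xgv, ygv, "general-model validation")
  sel <- names(coef(general_model))
  yr <- y_randomization(refitter(general_model),
                        Xg[, sel, drop = FALSE], yg,
                        n_iter = y_randomization_iters,
                        seed = substream_seed(seed, 2024))
  domain <- williams_table(general_model, Xg, yg, Xgv, ygv)
  manifest <- list(
    package = "isoqsar", version = as.character(utils::packageVersion("isoqsar")),
    seed = seed, n_validation = n_validation, n_repeats = n_repeats,
    selector = selector, preprocess = preprocess,
    dominant_fraction = dominant_fraction, variance_floor = variance_floor,
    collinearity_threshold = collinearity_threshold,
    p_enter = p_enter, p_remove = p_remove, max_terms = max_terms,
    ga = ga, y_randomization_iters = y_randomization_iters,
    general_split = general_split, stratified = stratified,
    n_compounds = length(dataset$compound_ids),
    n_descriptors_used = ncol(dataset$X)
  )
  structure(list(
    preprocess = pre_reports, splits = splits, split_table = split_table,
    split_models = split_models, best_split = best_split,
    pooled_descriptors = pooled, general_model = general_model,
    validation = c(gv, list(n_cal = nrow(Xg),
                            n_val = if (is.null(Xgv)) 0L else nrow(Xgv))),
    y_randomization = yr, domain = domain, manifest = manifest
  ), class = "cdfs_fit")
}

#' @export
print.cdfs_fit <- function(x, digits = 3, ...) {
  cat(sprintf("CDFS fit: %d splits, selector %s, seed %d\n",
              nrow(x$split_table), x$manifest$selector, x$manifest$seed))
  cat(sprintf("  pooled descriptors: %d; best split: %d\n",
              length(x$pooled_descriptors), x$best_split))
  cat(sprintf("general model (N = %d):\n", x$validation$n_cal))
  print(x$general_model, digits = digits)
  v <- x$validation
  cat(sprintf("  Q2(LOO) = %.*f, RMSE_CV = %.*f%s\n",
              digits, v$q2, digits, v$rmse_cv,
              if (is.finite(v$r2_p))
                sprintf(", R2p = %.*f", digits, v$r2_p) else ""))
  invisible(x)
}

#' @export
summary.cdfs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cdfs_fit")
}

#' @export
print.summary.cdfs_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nper-split models:\n")
  tab <- fit$split_table
  tab[c("r2_c", "se", "r2_p", "q2", "rmse_cv")] <-
    round(tab[c("r2_c", "se", "r2_p", "q2", "rmse_cv")], 3)
  print(tab, row.names = FALSE)
  cat("\n")
  print(fit$y_randomization)
  cat(sprintf("applicability domain: h* = %.3f; %d response / %d structural outlier(s)\n",
              attr(fit$domain, "h_star"), sum(fit$domain$response_outlier),
              sum(fit$domain$structural_outlier)))
  invisible(x)
}
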