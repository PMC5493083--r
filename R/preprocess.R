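#' Remove constant and near-constant descriptors
#'
#' Drops every descriptor column whose most frequent value (values
#' compared after rounding to 6 significant figures) occupies more than
#' `dominant_fraction` of the compounds, or whose variance is below
#' `variance_floor`. This is the first reduction step applied to a raw
#' descriptor matrix before any model building.
#'
#' @param dataset a [qsar_dataset()].
#' @param dominant_fraction drop a column when the share of its modal
#'   value exceeds this fraction (default 0.95).
#' @param variance_floor drop a column when its variance is below this
#'   (default 1e-8).
#' @return A list with `dataset` (reduced [qsar_dataset()]) and `report`,
#'   a `preprocess_report` with elements `dropped_constant`,
#'   `dropped_collinear` (empty here) and `n_remaining`.
#' @seealso [prune_collinear()]
#' @export
drop_invariant <- function(dataset, dominant_fraction = 0.95,
                           variance_floor = 1e-8) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (dominant_fraction <= 0 || dominant_fraction > 1) {
    stop("dominant_fraction must be in (0, 1]")
  }
  if (variance_floor < 0) stop("variance_floor must be >= 0")
  X <- dataset$X
  n <- nrow(X)
  drop <- vapply(seq_len(ncol(X)), function(j) {
    v <- signif(X[, j], 6)
    max(tabulate(match(v, unique(v)))) > dominant_fraction * n ||
      var(X[, j]) < variance_floor
  }, logical(1))
  if (all(drop)) stop("all descriptors are constant or near-constant")
  report <- new_preprocess_report(
    dropped_constant = dataset$descriptor_names[drop],
    dropped_collinear = empty_collinear_report(),
    n_remaining = sum(!drop)
  )
  list(dataset = subset_dataset(dataset, cols = !drop), report = report)
}

#' Prune collinear descriptor pairs
#'
#' Greedy collinearity filter: while any descriptor pair has absolute
#' Pearson correlation above `threshold`, the pair with the largest |r|
#' is taken (ties broken by column order) and the member with the smaller
#' absolute correlation with the activity is dropped (ties: the later
#' column is dropped). The surviving matrix has maximum pairwise |r| at
#' or below `threshold`, and within any block of mutually collinear
#' descriptors the member most correlated with the activity is the one
#' kept.
#'
#' @param dataset a [qsar_dataset()]; constant columns should be removed
#'   first ([drop_invariant()]).
#' @param threshold drop pairs with |r| above this (default 0.9).
#' @param activities activity vector used for the keep decision; defaults
#'   to `dataset$activities`.
#' @return A list with `dataset` and `report` as in [drop_invariant()];
#'   `report$dropped_collinear` is a data frame with columns `kept`,
#'   `dropped`, `r` (the |r| of the decisive pair).
#' @export
prune_collinear <- function(dataset, threshold = 0.9,
                            activities = dataset$activities) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  X <- dataset$X
  p <- ncol(X)
  if (p < 2) {
    return(list(dataset = dataset,
                report = new_preprocess_report(character(0),
                                               empty_collinear_report(), p)))
  }
  C <- abs(suppressWarnings(cor(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  ay <- abs(as.vector(suppressWarnings(cor(X, activities))))
  ay[!is.finite(ay)] <- 0
  alive <- rep(TRUE, p)
  kept <- character(0); dropped <- character(0); rval <- numeric(0)
  repeat {
    m <- max(C)
    if (m <= threshold) break
    # first pair (column-major order) attaining the maximum
    hit <- which(C == m)[1]
    i <- (hit - 1L) %% p + 1L
    j <- (hit - 1L) %/% p + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    loser <- if (ay[i] < ay[j]) i else if (ay[j] < ay[i]) j else j
    winner <- if (loser == i) j else i
    kept <- c(kept, dataset$descriptor_names[winner])
    dropped <- c(dropped, dataset$descriptor_names[loser])
    rval <- c(rval, m)
    alive[loser] <- FALSE
    C[loser, ] <- 0
    C[, loser] <- 0
  }
  report <- new_preprocess_report(
    dropped_constant = character(0),
    dropped_collinear = data.frame(kept = kept, dropped = dropped, r = rval,
                                   stringsAsFactors = FALSE),
    n_remaining = sum(alive)
  )
  list(dataset = subset_dataset(dataset, cols = alive), report = report)
}

empty_collinear_report <- function() {
  data.frame(kept = character(0), dropped = character(0), r = numeric(0),
             stringsAsFactors = FALSE)
}

new_preprocess_report <- function(dropped_constant, dropped_collinear,
                                  n_remaining) {
  structure(list(dropped_constant = dropped_constant,
                 dropped_collinear = dropped_collinear,
                 n_remaining = n_remaining),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess report:\n")
  cat(sprintf("  constant/near-constant dropped: %d\n",
              length(x$dropped_constant)))
  cat(sprintf("  collinear dropped:              %d\n",
              nrow(x$dropped_collinear)))
  cat(sprintf("  descriptors remaining:          %d\n", x$n_remaining))
  invisible(x)
}
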