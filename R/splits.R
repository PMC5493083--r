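#' Repeated calibration/validation splits
#'
#' Draws `n_repeats` independent calibration/validation partitions of the
#' compounds, the resampling backbone of combined data-splitting feature
#' selection (CDFS). Each repeat reserves `n_validation` compounds for
#' validation, without replacement; the default 9-of-50 mirrors the
#' published design (a 41-compound calibration set).
#'
#' Repeat `r` is seeded from a substream derived from `(seed, r)`, so
#' increasing `n_repeats` never changes earlier splits.
#'
#' @param dataset a [qsar_dataset()].
#' @param n_validation number of validation compounds per repeat
#'   (default 9).
#' @param n_repeats number of repeats (default 5).
#' @param seed master integer seed.
#' @param stratified if `TRUE`, compounds are ranked by activity, binned
#'   into `n_validation` contiguous rank bins, and one compound is drawn
#'   per bin, so the validation set spans the activity range.
#' @return A list of `n_repeats` `split_assignment` objects, each with
#'   `repeat_index`, `calibration_ids`, `validation_ids`, `seed`.
#' @export
make_splits <- function(dataset, n_validation = 9, n_repeats = 5, seed = 1,
                        stratified = FALSE) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  n <- length(dataset$compound_ids)
  if (n_validation <= 0 || n_validation >= n) {
    stop("n_validation must be strictly between 0 and the number of compounds")
  }
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  ids <- dataset$compound_ids
  lapply(seq_len(n_repeats), function(r) {
    sub <- substream_seed(seed, r)
    val_idx <- with_seed(sub, {
      if (stratified) {
        ord <- order(dataset$activities, ids)  # id tie-break: deterministic
        bins <- split(ord, cut(seq_len(n), n_validation, labels = FALSE))
        vapply(bins, function(b) b[sample.int(length(b), 1L)], integer(1))
      } else {
        sample.int(n, n_validation)
      }
    })
    val_idx <- sort(val_idx)
    structure(list(repeat_index = r,
                   calibration_ids = ids[-val_idx],
                   validation_ids = ids[val_idx],
                   seed = sub),
              class = "split_assignment")
  })
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split %d: %d calibration / %d validation compounds\n",
              x$repeat_index, length(x$calibration_ids),
              length(x$validation_ids)))
  invisible(x)
}
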