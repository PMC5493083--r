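#' Construct a QSAR dataset
#'
#' A `qsar_dataset` couples a dense numeric compounds-by-descriptors
#' matrix with one activity value (pIC50) per compound. Compound IDs are
#' opaque strings (alphanumeric labels such as `"75a"` are fine) and must
#' be unique; descriptor names must be unique; no entry may be missing or
#' non-finite.
#'
#' @param x numeric matrix (or data frame of numeric columns), rows =
#'   compounds, columns = descriptors.
#' @param activities numeric vector of activities (pIC50), one per row of
#'   `x`.
#' @param compound_ids character vector of unique compound labels;
#'   defaults to `rownames(x)`.
#' @param descriptor_names character vector of unique descriptor names;
#'   defaults to `colnames(x)`.
#' @return An object of class `qsar_dataset`: a list with elements
#'   `X` (named numeric matrix), `activities`, `compound_ids`,
#'   `descriptor_names`.
#' @seealso [read_descriptor_table()], [generate_qsar_data()]
#' @export
qsar_dataset <- function(x, activities, compound_ids = rownames(x),
                         descriptor_names = colnames(x)) {
  X <- as.matrix(x)
  if (!is.numeric(X)) {
    stop("descriptor matrix must be numeric")
  }
  if (is.null(compound_ids)) {
    compound_ids <- as.character(seq_len(nrow(X)))
  }
  compound_ids <- as.character(compound_ids)
  if (is.null(descriptor_names)) {
    descriptor_names <- paste0("D", seq_len(ncol(X)))
  }
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(X)) {
    stop("length(compound_ids) must equal nrow(x)")
  }
  if (length(descriptor_names) != ncol(X)) {
    stop("length(descriptor_names) must equal ncol(x)")
  }
  if (anyDuplicated(compound_ids)) {
    stop("duplicate compound ID: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  }
  if (anyDuplicated(descriptor_names)) {
    stop("duplicate descriptor name: ",
         paste(unique(descriptor_names[duplicated(descriptor_names)]),
               collapse = ", "))
  }
  if (any(compound_ids == "")) stop("compound IDs must be non-empty")
  activities <- as.numeric(activities)
  if (length(activities) != nrow(X)) {
    stop("length(activities) must equal nrow(x)")
  }
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite descriptor value at compound \"%s\", descriptor \"%s\"",
                 compound_ids[bad[1]], descriptor_names[bad[2]]))
  }
  if (!all(is.finite(activities))) {
    stop("non-finite activity for compound \"",
         compound_ids[which(!is.finite(activities))[1]], "\"")
  }
  dimnames(X) <- list(compound_ids, descriptor_names)
  structure(
    list(X = X, activities = activities, compound_ids = compound_ids,
         descriptor_names = descriptor_names),
    class = "qsar_dataset"
  )
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("qsar_dataset: %d compounds x %d descriptors\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("activity (pIC50): range %.3f .. %.3f, mean %.3f\n",
              min(x$activities), max(x$activities), mean(x$activities)))
  invisible(x)
}

#' @export
dim.qsar_dataset <- function(x) dim(x$X)

# Subset a dataset by compound rows and/or descriptor columns
# (indices, logicals or names). Internal helper used throughout.
subset_dataset <- function(dataset, rows = NULL, cols = NULL) {
  X <- dataset$X
  y <- dataset$activities
  if (!is.null(rows)) {
    X <- X[rows, , drop = FALSE]
    y <- y[if (is.character(rows)) match(rows, dataset$compound_ids) else rows]
  }
  if (!is.null(cols)) X <- X[, cols, drop = FALSE]
  qsar_dataset(X, y)
}

#' Read a descriptor table from CSV/TSV
#'
#' Reads a delimited text table whose first (or named) column holds
#' compound IDs, one column holds the activity, and all remaining columns
#' are numeric molecular descriptors. The delimiter is sniffed from the
#' header line (comma vs tab).
#'
#' @param path path to a CSV or TSV file with a header row.
#' @param activity_column name of the activity column (default
#'   `"pIC50"`).
#' @param id_column name of the compound-ID column; default: the first
#'   column.
#' @return A [qsar_dataset()] preserving the file's row and column order.
#' @details Missing or non-numeric cells raise an error naming the
#'   offending compound and descriptor; duplicated compound IDs raise an
#'   error.
#' @export
read_descriptor_table <- function(path, activity_column = "pIC50",
                                  id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "\"",
                   strip.white = TRUE, comment.char = "")
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!id_column %in% names(df)) {
    stop("ID column \"", id_column, "\" not found")
  }
  if (!activity_column %in% names(df)) {
    stop("activity column \"", activity_column, "\" not found")
  }
  ids <- df[[id_column]]
  if (anyDuplicated(ids)) {
    stop("duplicate compound ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc_names <- setdiff(names(df), c(id_column, activity_column))
  if (length(desc_names) == 0) stop("no descriptor columns found")
  parse_num <- function(v, colname) {
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out))
    if (length(bad)) {
      stop(sprintf("missing or non-numeric value at compound \"%s\", column \"%s\"",
                   ids[bad[1]], colname))
    }
    out
  }
  X <- vapply(desc_names, function(nm) parse_num(df[[nm]], nm),
              numeric(nrow(df)))
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, desc_names))
  y <- parse_num(df[[activity_column]], activity_column)
  qsar_dataset(X, y, compound_ids = ids, descriptor_names = desc_names)
}

#' Write a QSAR dataset to CSV
#'
#' Inverse of [read_descriptor_table()]: writes `compound_id`, the
#' activity column, then all descriptors. Values are written at full
#' precision (17 significant digits) so a write/read round-trip is exact.
#'
#' @param dataset a [qsar_dataset()].
#' @param path output file path.
#' @param activity_column column name for the activity (default
#'   `"pIC50"`).
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(dataset, path, activity_column = "pIC50") {
  stopifnot(inherits(dataset, "qsar_dataset"))
  df <- data.frame(compound_id = dataset$compound_ids,
                   activity = format(dataset$activities, digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2] <- activity_column
  for (j in seq_along(dataset$descriptor_names)) {
    df[[dataset$descriptor_names[j]]] <- format(dataset$X[, j], digits = 17)
  }
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
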