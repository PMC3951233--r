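# Reading descriptor / pharmacokinetic tables and min-max normalization.

#' Read a compound-by-descriptor table from CSV
#'
#' Reads a comma-separated table whose first column holds compound
#' identifiers and whose header row names the molecular descriptors.
#' All remaining cells must be numeric or one of the designated missing
#' tokens.  Row and column order are preserved exactly.
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @param missing_tokens Character vector of cell values treated as
#'   missing.  Defaults to `"NA"` and the empty string.
#' @return An object of class `qspkr_raw`: a list with `compound_ids`,
#'   `column_names` and a numeric `values` matrix (compounds x columns,
#'   `NA` where a missing token was found).
#' @seealso [minmax_normalize()], [handle_missing()]
#' @export
read_descriptor_table <- function(path, missing_tokens = c("NA", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("table must have an id column plus at least one value column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate compound id(s): ", paste(dup, collapse = ", "))
  }
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols)) {
    stop("duplicate column name(s): ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(df), length(cols),
                 dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- df[[j + 1L]]
    miss <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cell[i], ids[i], cols[j]))
    }
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  new_qspkr_raw(ids, cols, vals)
}

#' Read a pharmacokinetic parameter table from CSV
#'
#' Expects columns: compound id, parameter value, and optionally a unit
#' string (e.g. `"mL/min/kg"` for clearance).  Exactly one
#' pharmacokinetic parameter per file.
#'
#' @inheritParams read_descriptor_table
#' @return A one-column `qspkr_raw` object; the unit (if present) is
#'   stored in the `"unit"` attribute.
#' @export
read_pk_table <- function(path, missing_tokens = c("NA", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL, fileEncoding = "UTF-8")
  if (!ncol(df) %in% c(2L, 3L))
    stop("PK table must have columns: compound id, value[, unit]")
  unit <- if (ncol(df) == 3L) {
    u <- unique(df[[3L]])
    if (length(u) > 1L) stop("PK table mixes units: ", paste(u, collapse = ", "))
    u
  } else NA_character_
  tmp <- df[, 1:2]
  raw <- read_raw_from_df(tmp, missing_tokens)
  attr(raw, "unit") <- unit
  raw
}

# shared constructor/validation used by read_pk_table
read_raw_from_df <- function(df, missing_tokens) {
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(df)[-1L]
  cell <- df[[2L]]
  miss <- cell %in% missing_tokens
  num <- suppressWarnings(as.numeric(cell))
  bad <- !miss & is.na(num)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cell[i], ids[i], cols[1L]))
  }
  num[miss] <- NA_real_
  vals <- matrix(num, ncol = 1L, dimnames = list(ids, cols))
  new_qspkr_raw(ids, cols, vals)
}

#' Construct a raw table object
#'
#' Low-level constructor for in-memory data; validates uniqueness of
#' compound ids and column names.
#'
#' @param compound_ids Character vector of unique compound identifiers.
#' @param column_names Character vector of unique column names.
#' @param values Numeric matrix, `length(compound_ids)` rows by
#'   `length(column_names)` columns, in original units.
#' @return A `qspkr_raw` object.
#' @export
new_qspkr_raw <- function(compound_ids, column_names, values) {
  compound_ids <- as.character(compound_ids)
  column_names <- as.character(column_names)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) == length(compound_ids),
            ncol(values) == length(column_names))
  if (anyDuplicated(compound_ids)) stop("compound ids must be unique")
  if (anyDuplicated(column_names)) stop("column names must be unique")
  dimnames(values) <- list(compound_ids, column_names)
  structure(list(compound_ids = compound_ids,
                 column_names = column_names,
                 values = values),
            class = "qspkr_raw")
}

#' @export
print.qspkr_raw <- function(x, ...) {
  cat(sprintf("<qspkr_raw> %d compounds x %d columns, %d missing cells\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Resolve missing values before normalization
#'
#' Missing cells are never handled silently: this explicit step either
#' drops every descriptor column containing a missing value (default)
#' or replaces missing cells by the column mean.  The action taken is
#' reported via `message()`.
#'
#' @param raw A `qspkr_raw` object.
#' @param policy `"drop_columns"` (default) or `"impute_mean"`.
#' @return A `qspkr_raw` object with no missing values.
#' @export
handle_missing <- function(raw, policy = c("drop_columns", "impute_mean")) {
  policy <- match.arg(policy)
  stopifnot(inherits(raw, "qspkr_raw"))
  nas <- colSums(is.na(raw$values))
  if (all(nas == 0L)) return(raw)
  if (policy == "drop_columns") {
    keep <- nas == 0L
    message(sprintf("dropping %d column(s) with missing values: %s",
                    sum(!keep), paste(raw$column_names[!keep], collapse = ", ")))
    new_qspkr_raw(raw$compound_ids, raw$column_names[keep],
                  raw$values[, keep, drop = FALSE])
  } else {
    vals <- raw$values
    for (j in which(nas > 0L)) {
      m <- mean(vals[, j], na.rm = TRUE)
      vals[is.na(vals[, j]), j] <- m
    }
    message(sprintf("mean-imputed %d missing cell(s) in %d column(s)",
                    sum(nas), sum(nas > 0L)))
    new_qspkr_raw(raw$compound_ids, raw$column_names, vals)
  }
}

#' Min-max normalize descriptors and pharmacokinetic values to [0, 1]
#'
#' Each column `y` is mapped to `(y - min) / (max - min)` using the
#' observed extremes, so every non-constant column attains both 0 and 1.
#' Constant columns (no pairwise information) are mapped to 0 and
#' flagged; flagged descriptors are excluded from genetic-algorithm
#' selection by default.  The observed minima and maxima are retained so
#' predictions can be mapped back to original units and so NRMSE can be
#' computed.
#'
#' By default the extremes are taken over the full dataset, mirroring
#' normalization of the complete compound set before any train/test
#' split; pass training-row indices in `scope_rows` to normalize on a
#' training fold only (avoids information leakage into the test fold).
#'
#' @param raw A `qspkr_raw` descriptor table with no missing values
#'   (see [handle_missing()]).
#' @param pk A one-column `qspkr_raw` table of pharmacokinetic values
#'   with identical compound ids in identical order.
#' @param scope_rows Optional integer vector of row indices over which
#'   column minima/maxima are computed (default: all rows).
#' @return An object of class `qspkr_dataset` with elements
#'   `compound_ids`, `descriptor_names`, `X` (normalized descriptor
#'   matrix), `dp` (normalized PK vector), `scale_x` and `scale_pk`
#'   (data frames of observed min/max per column), `constant` (logical
#'   flags for constant descriptor columns), `pk_name`, `pk_unit`.
#' @export
minmax_normalize <- function(raw, pk, scope_rows = NULL) {
  stopifnot(inherits(raw, "qspkr_raw"), inherits(pk, "qspkr_raw"))
  if (!identical(raw$compound_ids, pk$compound_ids))
    stop("descriptor and PK tables must share identical compound ids in identical order")
  if (ncol(pk$values) != 1L) stop("PK table must have exactly one value column")
  if (anyNA(raw$values) || anyNA(pk$values))
    stop("missing values present; resolve them with handle_missing() first")
  rows <- if (is.null(scope_rows)) seq_len(nrow(raw$values)) else as.integer(scope_rows)
  stopifnot(all(rows >= 1L), all(rows <= nrow(raw$values)))

  norm_col <- function(y, lo, hi) {
    if (hi > lo) (y - lo) / (hi - lo) else rep(0, length(y))
  }
  lo_x <- apply(raw$values[rows, , drop = FALSE], 2L, min)
  hi_x <- apply(raw$values[rows, , drop = FALSE], 2L, max)
  X <- raw$values
  for (j in seq_len(ncol(X))) X[, j] <- norm_col(raw$values[, j], lo_x[j], hi_x[j])
  constant <- hi_x <= lo_x

  lo_p <- min(pk$values[rows, 1L]); hi_p <- max(pk$values[rows, 1L])
  if (hi_p <= lo_p) stop("PK column is constant; cannot normalize")
  dp <- norm_col(pk$values[, 1L], lo_p, hi_p)

  structure(list(
    compound_ids = raw$compound_ids,
    descriptor_names = raw$column_names,
    X = X,
    dp = as.numeric(dp),
    scale_x = data.frame(column = raw$column_names, min = unname(lo_x),
                         max = unname(hi_x), stringsAsFactors = FALSE),
    scale_pk = data.frame(column = pk$column_names, min = lo_p, max = hi_p,
                          stringsAsFactors = FALSE),
    constant = unname(constant),
    pk_name = pk$column_names[1L],
    pk_unit = attr(pk, "unit") %||% NA_character_
  ), class = "qspkr_dataset")
}

#' @export
print.qspkr_dataset <- function(x, ...) {
  cat(sprintf("<qspkr_dataset> %d compounds x %d descriptors (%d constant)\n",
              nrow(x$X), ncol(x$X), sum(x$constant)))
  cat(sprintf("  PK parameter: %s [%s], observed range %g..%g\n",
              x$pk_name, x$pk_unit, x$scale_pk$min, x$scale_pk$max))
  invisible(x)
}

#' Map normalized values back to the original measurement scale
#'
#' Inverse of min-max normalization: `v * (max - min) + min`.  Used to
#' report predictions and RMSE in the parameter's original units.
#'
#' @param values Numeric vector of normalized values.
#' @param scale Either a numeric vector `c(min, max)` or a one-row data
#'   frame with `min` and `max` columns (as stored in a
#'   `qspkr_dataset`).
#' @return Numeric vector on the original scale.
#' @export
denormalize <- function(values, scale) {
  s <- scale_bounds(scale)
  if (s[2L] <= s[1L]) stop("constant scale: cannot denormalize")
  values * (s[2L] - s[1L]) + s[1L]
}

scale_bounds <- function(scale) {
  if (is.data.frame(scale)) {
    stopifnot(nrow(scale) == 1L, all(c("min", "max") %in% names(scale)))
    c(scale$min, scale$max)
  } else {
    stopifnot(is.numeric(scale), length(scale) == 2L)
    as.numeric(scale)
  }
}

#' Write a raw table back to CSV
#'
#' Writes the same dialect [read_descriptor_table()] reads, so synthetic
#' fixtures round-trip losslessly through the file system.
#'
#' @param raw A `qspkr_raw` object.
#' @param path Output CSV path.
#' @param id_name Header used for the identifier column.
#' @param unit Optional unit string appended as a third column (PK
#'   tables only).
#' @return `path`, invisibly.
#' @export
write_qspkr_csv <- function(raw, path, id_name = "compound", unit = NULL) {
  stopifnot(inherits(raw, "qspkr_raw"))
  # %.17g guarantees a lossless double -> text -> double round trip
  chr <- matrix(sprintf("%.17g", raw$values), nrow = nrow(raw$values))
  chr[is.na(raw$values)] <- "NA"
  df <- data.frame(raw$compound_ids, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, raw$column_names)
  if (!is.null(unit)) df$unit <- unit
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
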