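#' Construct a feature table
#'
#' A feature table is the package's container for a rectangular numeric
#' biomarker table: one row per subject, one named column per variable, plus a
#' group label (`"normal"` for the healthy reference group, `"abnormal"` for
#' the disease group, `"unknown"` otherwise). Missing measurements are encoded
#' as `NA` and must be removed (see [drop_incomplete_rows()]) before any model
#' fitting.
#'
#' @param values numeric matrix or data frame, subjects in rows, variables in
#'   columns. Column names are required, unique and non-empty.
#' @param group group label for every subject in the table.
#' @param subject_ids optional character vector of row identifiers.
#' @return An object of class `"feature_table"`: a list with elements
#'   `values` (numeric matrix with column names), `group` and `subject_ids`.
#' @examples
#' ft <- feature_table(cbind(A = c(1, 2, 3), B = c(4, 5, 6)), group = "normal")
#' dim(ft)
#' @export
feature_table <- function(values, group = c("unknown", "normal", "abnormal"),
                          subject_ids = NULL) {
  group <- match.arg(group)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("'values' must be a matrix or data frame")
  storage.mode(values) <- "double"
  vn <- colnames(values)
  if (is.null(vn) || any(!nzchar(vn))) {
    stop("all variables must have non-empty names")
  }
  if (anyDuplicated(vn)) {
    stop("duplicate variable names: ",
         paste(unique(vn[duplicated(vn)]), collapse = ", "))
  }
  if (!is.null(subject_ids) && length(subject_ids) != nrow(values)) {
    stop("'subject_ids' must have one entry per row")
  }
  structure(list(values = values, group = group,
                 subject_ids = subject_ids),
            class = "feature_table")
}

#' Coerce to a feature table
#'
#' @param x a `feature_table`, matrix or data frame.
#' @param group group label used when `x` is not already a feature table.
#' @return A `feature_table`.
#' @export
as_feature_table <- function(x, group = "unknown") {
  if (inherits(x, "feature_table")) return(x)
  feature_table(x, group = group)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Variable names of a feature table
#' @param x a `feature_table`.
#' @return Character vector of variable names, in column order.
#' @export
variables <- function(x) colnames(as_feature_table(x)$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d variables (group: %s)\n",
              nrow(x$values), ncol(x$values), x$group))
  cat("Variables:", paste(colnames(x$values), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("Missing cells:", nmiss, "\n")
  invisible(x)
}

# row / column subsetting that preserves the class and metadata
ft_rows <- function(ft, idx) {
  feature_table(ft$values[idx, , drop = FALSE], group = ft$group,
                subject_ids = ft$subject_ids[idx])
}

ft_vars <- function(ft, vars) {
  missing <- setdiff(vars, colnames(ft$values))
  if (length(missing) > 0) {
    stop("variables not present in table: ", paste(missing, collapse = ", "))
  }
  feature_table(ft$values[, vars, drop = FALSE], group = ft$group,
                subject_ids = ft$subject_ids)
}

#' Read a feature table from a delimited text file
#'
#' Reads a CSV or TSV file with a header row of variable names and one subject
#' per row. The delimiter is auto-detected from the header line (tab if
#' present, comma otherwise) unless given. Any cell that does not parse as a
#' decimal-point number (including empty cells) becomes `NA`; values are never
#' silently coerced to zero, so incomplete subjects stay detectable.
#'
#' @param path path to the file.
#' @param group group label to attach.
#' @param sep field delimiter; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, group = c("unknown", "normal", "abnormal"),
                               sep = NULL) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("format error: empty file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  split_row <- function(l) strsplit(l, sep, fixed = TRUE)[[1]]
  header <- trimws(split_row(lines[[1]]))
  if (anyDuplicated(header)) {
    stop("format error: duplicate header names: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  body <- lines[-1]
  if (length(body) == 0) stop("format error: no data rows in ", path)
  cells <- lapply(body, function(l) {
    # strsplit drops a trailing empty field; pad to keep ragged-row detection honest
    n_sep <- lengths(regmatches(l, gregexpr(sep, l, fixed = TRUE)))
    out <- trimws(split_row(l))
    length(out) <- n_sep + 1L
    out
  })
  widths <- lengths(cells)
  bad <- which(widths != length(header))
  if (length(bad) > 0) {
    stop(sprintf("format error: row %d has %d fields, expected %d",
                 bad[[1]], widths[[bad[[1]]]], length(header)))
  }
  m <- do.call(rbind, cells)
  vals <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  colnames(vals) <- header
  feature_table(vals, group = group)
}

#' Write a feature table to a delimited text file
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_feature_table(write_feature_table(x))` round-trips at full double
#' precision. Missing cells are written as empty fields.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param sep field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, sep = ",") {
  ft <- as_feature_table(ft)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  rows <- apply(ft$values, 1L, function(r) paste(fmt(r), collapse = sep))
  out <- c(paste(colnames(ft$values), collapse = sep), rows)
  ok <- try(writeLines(out, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(path)
}
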