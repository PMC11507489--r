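#' Tabular categorical dataset
#'
#' The container every learning function in edgecred consumes: an ordered set
#' of named categorical variables with observations stored as 1-based category
#' indices. Categories are always the lexicographically sorted distinct values
#' of a column, so encoding is deterministic across platforms.
#'
#' @param codes integer matrix, one row per observation, one column per
#'   variable; entry `codes[i, j]` is the 1-based index into
#'   `categories[[j]]`.
#' @param variables character vector of unique, non-empty variable names.
#' @param categories named list (one element per variable) of character
#'   vectors giving the ordered category labels.
#' @return An object of class `tab_data` with fields `variables`,
#'   `categories`, `codes` and `n_rows`.
#' @examples
#' d <- as_tab_data(data.frame(a = c("x", "y", "x"), b = c("u", "u", "v")))
#' d$categories
#' @export
tab_data <- function(codes, variables, categories) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (length(variables) == 0L) stop("dataset must have at least one variable")
  if (anyDuplicated(variables) || any(!nzchar(variables)))
    stop("variable names must be unique and non-empty")
  if (ncol(codes) != length(variables))
    stop("codes must have one column per variable")
  if (!identical(names(categories), as.character(variables)))
    names(categories) <- variables
  for (j in seq_along(variables)) {
    nc <- length(categories[[j]])
    if (nc < 1L) stop("variable '", variables[j], "' has no categories")
    cj <- codes[, j]
    if (anyNA(cj)) stop("missing value in variable '", variables[j], "'")
    if (nrow(codes) > 0L && (min(cj) < 1L || max(cj) > nc))
      stop("category index out of range for variable '", variables[j], "'")
  }
  colnames(codes) <- variables
  structure(
    list(variables = as.character(variables), categories = categories,
         codes = codes, n_rows = nrow(codes)),
    class = "tab_data"
  )
}

#' Coerce a data frame to a categorical dataset
#'
#' All columns are treated as categorical; values are converted to character
#' and categories are the sorted distinct values per column. Continuous data
#' must be discretized before entering the pipeline.
#'
#' @param df a data.frame with at least one row and column, no missing values.
#' @return a [tab_data] object.
#' @export
as_tab_data <- function(df) {
  if (inherits(df, "tab_data")) return(df)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (ncol(df) == 0L) stop("dataset must have at least one variable")
  vars <- colnames(df)
  cats <- vector("list", length(vars))
  codes <- matrix(0L, nrow(df), ncol(df))
  for (j in seq_along(vars)) {
    v <- as.character(df[[j]])
    if (anyNA(v) || any(!nzchar(trimws(v))))
      stop("missing value in column '", vars[j], "'")
    cats[[j]] <- sort(unique(v))
    codes[, j] <- match(v, cats[[j]])
  }
  names(cats) <- vars
  tab_data(codes, vars, cats)
}

#' @export
print.tab_data <- function(x, ...) {
  cat("Categorical dataset:", x$n_rows, "rows,",
      length(x$variables), "variables\n")
  for (v in x$variables) {
    cat("  ", v, ": {", paste(x$categories[[v]], collapse = ", "), "}\n",
        sep = "")
  }
  invisible(x)
}

#' Decode a dataset back to a character data frame
#'
#' @param x a [tab_data] object.
#' @param ... unused.
#' @return data.frame of category labels, rows in stored order.
#' @export
as.data.frame.tab_data <- function(x, ...) {
  out <- as.data.frame(
    lapply(seq_along(x$variables),
           function(j) x$categories[[j]][x$codes[, j]]),
    stringsAsFactors = FALSE, optional = TRUE
  )
  if (x$n_rows == 0L) out <- as.data.frame(matrix(character(0), 0,
                                                  length(x$variables)))
  colnames(out) <- x$variables
  out
}

#' Row subset of a dataset
#'
#' @param x a [tab_data] object.
#' @param i integer row indices (with-replacement indexing allowed).
#' @return a [tab_data] with the selected rows, categories unchanged.
#' @export
tab_rows <- function(x, i) {
  tab_data(x$codes[i, , drop = FALSE], x$variables, x$categories)
}

#' Read a categorical dataset from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8) where every column is categorical. Category
#' sets are inferred as the sorted distinct values per column; row order is
#' preserved. Missing or blank cells are an error: the downstream statistics
#' assume complete i.i.d. samples and silent imputation would distort them.
#'
#' @param path file path.
#' @param header logical; does the first row carry variable names
#'   (default `TRUE`)? With `header = FALSE` columns are named `V1`, `V2`, ...
#' @return a [tab_data] object.
#' @export
read_categorical_csv <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  df <- utils::read.csv(path, header = header, colClasses = "character",
                        check.names = FALSE, na.strings = character(0),
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  as_tab_data(df)
}

#' Write a categorical dataset to CSV
#'
#' Inverse of [read_categorical_csv()]: `read_categorical_csv(write...)`
#' reproduces the dataset exactly (category order is fixed by sorting).
#'
#' @param x a [tab_data] object.
#' @param path output file path.
#' @export
write_categorical_csv <- function(x, path) {
  x <- as_tab_data(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
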