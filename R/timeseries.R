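#' Multivariate time-series container
#'
#' Constructs the basic data object of the package: a \eqn{T \times n} matrix
#' of observations, one row per time step and one column per system variable,
#' together with an ordered vector of time labels. Every downstream stage
#' (size-of-state estimation, binning, the sliding-window Fisher information
#' index) operates on this container.
#'
#' Time labels must be strictly increasing. The method itself only uses the
#' sequential order of the rows, so irregular calendar gaps are accepted, but
#' a warning is issued because a window of \code{w} rows then no longer spans
#' a constant calendar interval.
#'
#' @param values numeric matrix (or object coercible to one) with \code{T}
#'   rows and \code{n >= 1} columns; all entries must be finite.
#' @param time_labels numeric vector of length \code{T}, strictly increasing
#'   (e.g. years). Defaults to \code{1:T}.
#' @param variable_names optional character vector of length \code{n};
#'   defaults to the column names of \code{values} or \code{V1..Vn}.
#' @return An object of class \code{fi_timeseries}: a list with elements
#'   \code{time} (numeric vector) and \code{values} (named numeric matrix).
#' @examples
#' ts <- fi_timeseries(cbind(a = rnorm(10), b = rnorm(10)), 2001:2010)
#' ts
#' @seealso [read_timeseries_table()], [fi_index()]
#' @export
fi_timeseries <- function(values, time_labels = NULL, variable_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  storage.mode(values) <- "double"
  T_ <- nrow(values)
  n <- ncol(values)
  if (T_ < 1L || n < 1L)
    stop("'values' must have at least one row and one column", call. = FALSE)
  if (is.null(time_labels)) time_labels <- seq_len(T_)
  time_labels <- as.numeric(time_labels)
  if (length(time_labels) != T_)
    stop("length of 'time_labels' (", length(time_labels),
         ") does not match number of rows (", T_, ")", call. = FALSE)
  if (anyNA(time_labels))
    stop("time labels contain missing values (row ",
         which(is.na(time_labels))[1L], ")", call. = FALSE)
  d <- diff(time_labels)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("time labels must be strictly increasing; violation at row ", bad,
         " (label ", time_labels[bad], ")", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row ", bad[1L], ", column ", bad[2L],
         call. = FALSE)
  }
  if (!is.null(variable_names)) {
    if (length(variable_names) != n)
      stop("length of 'variable_names' does not match number of columns",
           call. = FALSE)
    colnames(values) <- variable_names
  } else if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(n))
  }
  if (T_ > 2L && length(unique(d)) > 1L)
    warning("time labels are irregularly spaced; the analysis uses row order ",
            "only, so windows cover a varying calendar span", call. = FALSE)
  structure(list(time = time_labels, values = values),
            class = "fi_timeseries")
}

#' @export
print.fi_timeseries <- function(x, ...) {
  cat("Multivariate time series: ", nrow(x$values), " time steps x ",
      ncol(x$values), " variables\n", sep = "")
  cat("  time labels: ", format(x$time[1L]), " ... ",
      format(x$time[length(x$time)]), "\n", sep = "")
  cat("  variables:   ", paste(colnames(x$values), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.fi_timeseries <- function(x) dim(x$values)

#' @export
as.data.frame.fi_timeseries <- function(x, ...) {
  data.frame(time = x$time, x$values, check.names = FALSE)
}

#' Read a multivariate time series from a delimited table
#'
#' Reads a header-bearing CSV with one row per time step, one designated time
#' column and any number of numeric variable columns, and returns the
#' validated [fi_timeseries()] container. Column order of the variables is
#' preserved.
#'
#' @param path path to a comma-delimited file with a header row.
#' @param time_column name of the time column; defaults to the first column.
#' @param sep field separator, comma by default.
#' @return An \code{fi_timeseries} object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = 1:3, a = c(1, 2, 3), b = c(0, 0, 1)), f,
#'           row.names = FALSE)
#' read_timeseries_table(f)
#' @export
read_timeseries_table <- function(path, time_column = NULL, sep = ",") {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = character())
  if (ncol(df) < 2L)
    stop("table must contain a time column and at least one variable",
         call. = FALSE)
  if (is.null(time_column)) time_column <- names(df)[1L]
  if (!time_column %in% names(df))
    stop("time column '", time_column, "' not found in ", path, call. = FALSE)
  tl <- suppressWarnings(as.numeric(df[[time_column]]))
  if (anyNA(tl))
    stop("unparseable time label at data row ", which(is.na(tl))[1L],
         " of ", path, call. = FALSE)
  if (anyDuplicated(tl))
    stop("duplicate time label ", tl[anyDuplicated(tl)], " at data row ",
         anyDuplicated(tl), " of ", path, call. = FALSE)
  vars <- setdiff(names(df), time_column)
  vals <- matrix(NA_real_, nrow(df), length(vars),
                 dimnames = list(NULL, vars))
  for (j in seq_along(vars)) {
    raw <- trimws(df[[vars[j]]])
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | raw == "")
    if (length(bad))
      stop("non-numeric or empty cell at data row ", bad[1L], ", column '",
           vars[j], "' of ", path, call. = FALSE)
    vals[, j] <- v
  }
  fi_timeseries(vals, tl)
}

#' Write a multivariate time series to a delimited table
#'
#' Inverse of [read_timeseries_table()]: writes a CSV with the time column
#' first. Values are written with 15 significant digits so a read-back
#' reproduces them to full double precision for all practical purposes.
#'
#' @param ts an \code{fi_timeseries} object.
#' @param path output file path.
#' @param time_column header name for the time column.
#' @return Invisibly, \code{path}.
#' @export
write_timeseries_table <- function(ts, path, time_column = "time") {
  stopifnot(inherits(ts, "fi_timeseries"))
  chr <- matrix(vapply(ts$values, format, character(1L), digits = 15,
                       trim = TRUE, scientific = FALSE),
                nrow = nrow(ts$values))
  df <- data.frame(format(ts$time, digits = 15, trim = TRUE, scientific = FALSE),
                   chr, check.names = FALSE)
  names(df) <- c(time_column, colnames(ts$values))
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write to ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}
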