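#' Read a GISTEMP-style monthly temperature-anomaly table
#'
#' Parses tables in the layout used by the NASA GISS surface-temperature
#' analysis (GISTEMP): one row per year, a \code{Year} column followed by
#' twelve monthly columns \code{Jan} through \code{Dec}, anomalies expressed
#' in hundredths of a degree Celsius relative to a fixed base period, and
#' missing values marked by runs of asterisks (e.g. \code{***}). Both
#' comma-separated and whitespace-separated layouts are accepted, repeated
#' header lines (GISTEMP re-prints its header every few decades) are skipped,
#' and any annual-summary columns after December (J-D, D-N, seasonal means)
#' are ignored.
#'
#' Each month becomes one system variable, so a complete year contributes one
#' 12-dimensional observation. Years with any missing month are excluded from
#' the result and reported via \code{message()}; the binning criterion needs
#' a value for every variable at every retained time step, and the method
#' defines no imputation.
#'
#' Anomalies are kept in their printed 0.01 degC units; published
#' size-of-state vectors for this data (e.g. 35.96 ... 40.81) are on that
#' scale.
#'
#' @param path path to the anomaly table.
#' @return An [fi_timeseries()] with years as time labels and variables
#'   \code{Jan} ... \code{Dec}. The excluded years (if any) are attached as
#'   attribute \code{"excluded_years"}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Year,Jan,Feb,Mar,Apr,May,Jun,Jul,Aug,Sep,Oct,Nov,Dec",
#'              "2000,23,55,55,51,37,40,37,41,39,40,29,29",
#'              "2001,41,41,56,51,55,51,59,58,53,49,67,54"), f)
#' read_gistemp_monthly(f)
#' @export
read_gistemp_monthly <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  split_fields <- function(l) {
    if (grepl(",", l, fixed = TRUE)) strsplit(l, ",", fixed = TRUE)[[1L]]
    else strsplit(trimws(l), "[[:space:]]+")[[1L]]
  }
  header_at <- which(vapply(lines, function(l) {
    f <- trimws(split_fields(l))
    length(f) >= 13L && tolower(f[1L]) == "year" &&
      all(tolower(months) %in% tolower(f))
  }, logical(1L)))
  if (!length(header_at))
    stop("malformed header: no line with a Year column followed by the ",
         "twelve month columns Jan...Dec found in ", path, call. = FALSE)
  header <- trimws(split_fields(lines[header_at[1L]]))
  month_cols <- match(tolower(months), tolower(header))
  year_col <- match("year", tolower(header))

  data_lines <- lines[-header_at]
  years <- numeric(0)
  rows <- list()
  excluded <- numeric(0)
  for (l in data_lines) {
    f <- trimws(split_fields(l))
    yr <- suppressWarnings(as.numeric(f[year_col]))
    if (is.na(yr)) next                      # stray footer / comment line
    if (length(f) < max(month_cols)) {
      excluded <- c(excluded, yr)
      next
    }
    raw <- f[month_cols]
    raw[grepl("^\\*+$", raw)] <- NA_character_
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v)) {
      excluded <- c(excluded, yr)
    } else {
      years <- c(years, yr)
      rows[[length(rows) + 1L]] <- v
    }
  }
  if (!length(rows))
    stop("no complete year rows (all twelve months present) in ", path,
         call. = FALSE)
  if (length(excluded))
    message("read_gistemp_monthly: excluded ", length(excluded),
            " year(s) with missing months: ",
            paste(sort(excluded), collapse = ", "))
  ord <- order(years)
  ts <- fi_timeseries(do.call(rbind, rows)[ord, , drop = FALSE],
                      years[ord], months)
  attr(ts, "excluded_years") <- sort(excluded)
  ts
}
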