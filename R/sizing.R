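#' Size of state: per-variable bin widths
#'
#' The size of state is the vector of per-variable measurement uncertainties
#' \eqn{\Delta y_i} that defines the hyper-rectangular bin used to decide
#' when two observations are indistinguishable: two points fall in the same
#' state when \eqn{|y_i(t_j) - y_i(t_k)| \le \Delta y_i} for (enough of) the
#' variables. `size_of_state()` wraps an explicitly supplied vector;
#' [estimate_size_of_state()] derives one from a stable reference period.
#'
#' A zero entry is allowed — only exactly equal values of that variable then
#' bin together — but is flagged with a warning since it usually indicates a
#' degenerate (constant) variable.
#'
#' @param deltas numeric vector of non-negative bin widths, one per variable,
#'   in that variable's units.
#' @param variable_names optional names for the entries.
#' @return An object of class \code{fi_sos}: the named delta vector with
#'   attributes \code{mode} (\code{"explicit"} or \code{"estimated"}), and
#'   for estimated vectors \code{k}, \code{coverage} and
#'   \code{stable_period}.
#' @examples
#' size_of_state(c(0.5, 1), c("Y1", "Y2"))
#' @seealso [estimate_size_of_state()], [bin_window()]
#' @export
size_of_state <- function(deltas, variable_names = NULL) {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 1L)
    stop("'deltas' must contain at least one entry", call. = FALSE)
  if (anyNA(deltas) || any(deltas < 0))
    stop("'deltas' must be non-negative and finite", call. = FALSE)
  if (!is.null(variable_names)) names(deltas) <- variable_names
  if (any(deltas == 0))
    warning("size of state is zero for variable(s) ",
            paste(which(deltas == 0), collapse = ", "),
            "; only exactly equal values will share a state", call. = FALSE)
  structure(deltas, class = "fi_sos", mode = "explicit")
}

#' Estimate the size of state from a stable period
#'
#' Applies the Chebyshev-inequality recipe for choosing bin widths when the
#' measurement uncertainty is not reported with the data: over a reference
#' period judged relatively stable by the analyst, compute each variable's
#' standard deviation and set \eqn{\Delta y_i = k \cdot \mathrm{sd}_i}.
#' Chebyshev's inequality guarantees, for any distribution, that at least
#' \eqn{1 - 1/k^2} of observations fall within \eqn{k} standard deviations
#' of the mean; the default \eqn{k = 2} therefore covers at least 75%.
#'
#' The sample standard deviation (denominator \eqn{T - 1}) is used. Choosing
#' the stable period is deliberately left to the analyst.
#'
#' @param ts an [fi_timeseries()].
#' @param stable_period length-2 numeric vector \code{c(start, end)} of time
#'   labels, inclusive; the period must contain at least 2 time steps.
#' @param k positive Chebyshev multiplier; default 2.
#' @return An \code{fi_sos} vector with attributes \code{k},
#'   \code{coverage} (\eqn{1 - 1/k^2}) and \code{stable_period}.
#' @examples
#' ts <- fi_timeseries(cbind(y = c(0.6, 2, 0.3, 3.5, 0.95, 3.1, 2.4, 2.7)))
#' estimate_size_of_state(ts, c(1, 8), k = 2)  # 2 * sample sd = 2.395
#' @export
estimate_size_of_state <- function(ts, stable_period, k = 2) {
  stopifnot(inherits(ts, "fi_timeseries"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a positive number", call. = FALSE)
  if (length(stable_period) != 2L)
    stop("'stable_period' must be c(start, end)", call. = FALSE)
  sel <- ts$time >= stable_period[1L] & ts$time <= stable_period[2L]
  if (!any(sel))
    stop("stable period [", stable_period[1L], ", ", stable_period[2L],
         "] contains no time steps of the series", call. = FALSE)
  if (sum(sel) < 2L)
    stop("stable period must contain at least 2 time steps (found ",
         sum(sel), ")", call. = FALSE)
  sds <- apply(ts$values[sel, , drop = FALSE], 2L, stats::sd)
  deltas <- k * sds
  if (any(deltas == 0))
    warning("size of state is zero for variable(s) ",
            paste(colnames(ts$values)[deltas == 0], collapse = ", "),
            " (constant over the stable period)", call. = FALSE)
  structure(deltas, class = "fi_sos", mode = "estimated", k = k,
            coverage = 1 - 1 / k^2, stable_period = as.numeric(stable_period))
}

#' @export
print.fi_sos <- function(x, ...) {
  cat("Size of state (", attr(x, "mode"), ")\n", sep = "")
  print(unclass(stats::setNames(as.numeric(x), names(x))))
  if (identical(attr(x, "mode"), "estimated"))
    cat(sprintf("k = %g, Chebyshev coverage >= %.4g, stable period [%g, %g]\n",
                attr(x, "k"), attr(x, "coverage"),
                attr(x, "stable_period")[1L], attr(x, "stable_period")[2L]))
  invisible(x)
}

# Coerce a size-of-state argument to a plain numeric vector of width n,
# validating length against the data it is used with.
sos_deltas <- function(deltas, n) {
  d <- as.numeric(deltas)
  if (length(d) != n)
    stop("size of state has length ", length(d),
         " but the data has ", n, " variable(s)", call. = FALSE)
  if (anyNA(d) || any(d < 0))
    stop("size of state must be non-negative and finite", call. = FALSE)
  d
}
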