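#' Sliding-window Fisher information index
#'
#' The package's main computation. A window of \code{width} consecutive time
#' steps slides through the series in increments of \code{increment}; within
#' each window the points are binned into discrete states ([bin_window()]),
#' converted to a probability profile ([state_probabilities()]) and scored
#' with the discrete Fisher information ([fisher_information()]). Each
#' window's value is attributed to its last time step, so only past data
#' enter every reported value; incomplete trailing windows are dropped. For
#' a series of T steps the result has \code{floor((T - width)/increment) + 1}
#' entries.
#'
#' With \code{tl = "strict"} every variable must satisfy its size-of-state
#' criterion for two points to share a state. With \code{tl = "averaged"}
#' the window's index is the mean of the Fisher information over all
#' tightening levels from 100% down to the lowest level at which the window
#' still shows more than one state ([tl_levels()]), a concession to noisy
#' data in which no single level is privileged.
#'
#' Optional block-average smoothing (\code{smooth > 1}) replaces consecutive
#' blocks of values by their mean; see [block_average()].
#'
#' @param ts an [fi_timeseries()].
#' @param deltas size of state: an [size_of_state()] /
#'   [estimate_size_of_state()] object or numeric vector, one entry per
#'   variable.
#' @param width window width in time steps; at least 2, and at least 8 is
#'   recommended for a stable probability estimate.
#' @param increment window increment in time steps; must not exceed
#'   \code{width} (equal is allowed with a warning, but then adjacent
#'   windows share no data).
#' @param tl \code{"strict"} (default) or \code{"averaged"}.
#' @param smooth block size for [block_average()] smoothing; 1 (default)
#'   disables it.
#' @return An object of class \code{fi_series}: a data frame with columns
#'   \code{time} (label of each window's last step), \code{fi},
#'   \code{n_states} (states at the strict level) and \code{tl_mode}, plus
#'   \code{n_levels} (tightening levels averaged) in averaged mode.
#'   Attributes record \code{width}, \code{increment}, \code{deltas} and
#'   \code{smooth}.
#' @examples
#' pts <- rbind(c(0.6, 1.5), c(2, 1.5), c(0.3, 1), c(3.5, 4.8),
#'              c(0.95, 2), c(3.1, 4), c(2.4, 1.8), c(2.7, 2.1))
#' fit <- fi_index(fi_timeseries(pts), c(0.5, 1), width = 8)
#' fit          # one window, FI = 2.1363
#' @seealso [summary.fi_series()], [regime_summary()], [classify_trend()],
#'   [plot.fi_series()]
#' @export
fi_index <- function(ts, deltas, width, increment = 1,
                     tl = c("strict", "averaged"), smooth = 1L) {
  stopifnot(inherits(ts, "fi_timeseries"))
  tl <- match.arg(tl)
  T_ <- nrow(ts$values)
  n <- ncol(ts$values)
  d <- sos_deltas(deltas, n)
  if (!is.numeric(width) || length(width) != 1L || width < 2L ||
      width != round(width))
    stop("'width' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(increment) || length(increment) != 1L || increment < 1L ||
      increment != round(increment))
    stop("'increment' must be an integer >= 1", call. = FALSE)
  if (increment > width)
    stop("window increment (", increment, ") must not exceed window width (",
         width, ")", call. = FALSE)
  if (increment == width)
    warning("increment equals width: adjacent windows share no data",
            call. = FALSE)
  if (width < 8L)
    warning("window width ", width, " is below the recommended minimum of 8",
            call. = FALSE)
  if (T_ < width)
    stop("series has ", T_, " time steps but the window needs at least ",
         width, call. = FALSE)

  starts <- seq.int(1L, T_ - width + 1L, by = increment)
  k <- length(starts)
  fi <- numeric(k)
  n_states <- integer(k)
  n_levels <- integer(k)
  for (j in seq_len(k)) {
    win <- ts$values[starts[j]:(starts[j] + width - 1L), , drop = FALSE]
    strict_part <- bin_window(win, d, tl = 1)
    n_states[j] <- strict_part$m
    if (tl == "strict") {
      fi[j] <- fisher_information(strict_part)
      n_levels[j] <- 1L
    } else {
      levels <- tl_levels(win, d)
      vals <- vapply(levels, function(lev) {
        if (abs(lev - 1) < 1e-12) fisher_information(strict_part)
        else fisher_information(bin_window(win, d, tl = lev))
      }, numeric(1L))
      fi[j] <- mean(vals)
      n_levels[j] <- length(levels)
    }
  }
  out <- data.frame(time = ts$time[starts + width - 1L],
                    fi = fi, n_states = n_states, tl_mode = tl)
  if (tl == "averaged") out$n_levels <- n_levels
  out <- structure(out, class = c("fi_series", "data.frame"),
                   width = width, increment = increment,
                   deltas = d, smooth = 1L)
  if (smooth > 1L) out <- block_average(out, smooth)
  out
}

#' @export
print.fi_series <- function(x, digits = 4, ...) {
  cat("Fisher information series (", nrow(x), " windows, width ",
      attr(x, "width"), ", increment ", attr(x, "increment"),
      ", tightening: ", x$tl_mode[1L],
      if (attr(x, "smooth") > 1L)
        paste0(", block-averaged b = ", attr(x, "smooth")) else "",
      ")\n", sep = "")
  print.data.frame(cbind(x[, "time", drop = FALSE],
                         fi = round(x$fi, digits),
                         x[, setdiff(names(x), c("time", "fi")),
                           drop = FALSE]),
                   row.names = FALSE)
  invisible(x)
}

#' Block-average smoothing of a Fisher information series
#'
#' Replaces each block of \code{b} consecutive index values by their mean;
#' that mean then stands for every entry of the block (time labels are
#' preserved). A trailing partial block is averaged over its own length.
#' Block averaging acts as a high-frequency filter that emphasises trends
#' in dynamic order over window-to-window fluctuation; large blocks blur
#' the timing of changes, so the block should stay small relative to the
#' features of interest.
#'
#' @param series an \code{fi_series}.
#' @param b block size, integer >= 1; \code{b = 1} returns the series
#'   unchanged.
#' @return The smoothed \code{fi_series} (attribute \code{smooth} set to
#'   \code{b}).
#' @export
block_average <- function(series, b) {
  stopifnot(inherits(series, "fi_series"))
  if (!is.numeric(b) || length(b) != 1L || b < 1L || b != round(b))
    stop("'b' must be an integer >= 1", call. = FALSE)
  b <- as.integer(b)
  if (b > 1L) {
    k <- nrow(series)
    block <- (seq_len(k) - 1L) %/% b
    series$fi <- stats::ave(series$fi, block)
  }
  attr(series, "smooth") <- b
  series
}

#' Regime summary: mean and spread of the index over a period
#'
#' Summarises the Fisher information over an inclusive time-label period by
#' its mean and sample standard deviation. When comparing regimes, a stable
#' one shows a relatively high and steady mean index with low standard
#' deviation; a regime with lower mean and larger spread is less stable.
#'
#' @param series an \code{fi_series}.
#' @param period length-2 vector \code{c(start, end)} of time labels,
#'   inclusive; defaults to the whole series.
#' @return An object of class \code{fi_regime}: data frame with columns
#'   \code{start}, \code{end}, \code{n}, \code{mu_fi} and \code{sigma_fi}
#'   (0 when \code{n = 1}).
#' @examples
#' \donttest{
#' ts <- simulate_regimes(list(regime(1, 60, 0, 0.1)), seed = 1)
#' s <- fi_index(ts, 0.5, width = 10)
#' regime_summary(s, c(20, 40))
#' }
#' @export
regime_summary <- function(series, period = NULL) {
  stopifnot(inherits(series, "fi_series"))
  if (is.null(period)) period <- range(series$time)
  if (length(period) != 2L)
    stop("'period' must be c(start, end)", call. = FALSE)
  sel <- series$time >= period[1L] & series$time <= period[2L]
  if (!any(sel))
    stop("no index entries inside period [", period[1L], ", ", period[2L],
         "]", call. = FALSE)
  v <- series$fi[sel]
  structure(data.frame(start = period[1L], end = period[2L],
                       n = length(v), mu_fi = mean(v),
                       sigma_fi = if (length(v) > 1L) stats::sd(v) else 0),
            class = c("fi_regime", "data.frame"))
}

#' @export
print.fi_regime <- function(x, digits = 3, ...) {
  cat("Regime summary\n")
  print.data.frame(cbind(x[, c("start", "end", "n")],
                         mu_fi = round(x$mu_fi, digits),
                         sigma_fi = round(x$sigma_fi, digits)),
                   row.names = FALSE)
  invisible(x)
}

#' @describeIn fi_index Summary method: regime summaries over one or more
#'   periods (default: the whole series).
#' @param object an \code{fi_series}.
#' @param periods list of \code{c(start, end)} label ranges.
#' @param ... unused.
#' @export
summary.fi_series <- function(object, periods = NULL, ...) {
  if (is.null(periods)) periods <- list(range(object$time))
  out <- do.call(rbind, lapply(periods, function(p)
    regime_summary(object, p)))
  class(out) <- c("fi_regime", "data.frame")
  out
}

#' Classify the trend of the Fisher information index
#'
#' Applies the regime-interpretation rules to each entry of the series,
#' using a trailing assessment span: a near-zero least-squares slope of the
#' index over the span marks an orderly, stable regime; a positive slope a
#' system becoming more organised; a negative slope a steady loss of order
#' (an early warning); and a single-step drop larger than
#' \code{drop_threshold} a regime shift (\code{sharp_drop}, which takes
#' precedence over the slope label). Entries with less history than the
#' span are assessed over what is available; the first entry is labelled
#' \code{stable}.
#'
#' The thresholds are heuristics: the interpretation rules are qualitative,
#' and the defaults (slope within ±0.05 index units per step = stable,
#' single-step drop > 2 = shift) are starting points to be tuned per
#' application.
#'
#' @param series an \code{fi_series} with at least 2 entries.
#' @param span trailing window of entries used for the slope; default 8.
#' @param slope_tolerance slope magnitude regarded as flat.
#' @param drop_threshold single-step decrease flagged as a regime shift.
#' @return Character vector, one label per entry:
#'   \code{stable}, \code{increasing}, \code{declining} or
#'   \code{sharp_drop}.
#' @examples
#' \donttest{
#' ts <- simulate_regimes(list(regime(1, 30, 0, 0), regime(31, 60, 10, 0)),
#'                        seed = 1)
#' s <- fi_index(ts, 0.5, width = 10)
#' table(classify_trend(s))
#' }
#' @export
classify_trend <- function(series, span = 8L, slope_tolerance = 0.05,
                           drop_threshold = 2) {
  stopifnot(inherits(series, "fi_series"))
  k <- nrow(series)
  if (k < 2L)
    stop("trend classification needs at least 2 entries", call. = FALSE)
  if (span > k)
    stop("assessment span (", span, ") exceeds series length (", k, ")",
         call. = FALSE)
  fi <- series$fi
  labels <- character(k)
  for (j in seq_len(k)) {
    if (j > 1L && fi[j] - fi[j - 1L] < -drop_threshold) {
      labels[j] <- "sharp_drop"
      next
    }
    i0 <- max(1L, j - span + 1L)
    y <- fi[i0:j]
    if (length(y) < 2L) {
      labels[j] <- "stable"
      next
    }
    x <- seq_along(y)
    slope <- stats::cov(x, y) / stats::var(x)
    labels[j] <- if (abs(slope) <= slope_tolerance) "stable"
                 else if (slope > 0) "increasing" else "declining"
  }
  labels
}

#' Plot a Fisher information series
#'
#' Draws the index against time. High flat stretches are orderly regimes;
#' declines and sharp drops flag destabilisation and regime shifts. The
#' theoretical ceiling of 8 (a single occupied state per window) is drawn
#' as a dashed reference line.
#'
#' @param x an \code{fi_series}.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.fi_series <- function(x, ...) {
  args <- list(x = x$time, y = x$fi, type = "l",
               xlab = "time", ylab = "Fisher information",
               ylim = c(0, 8.2))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(graphics::plot, args)
  graphics::abline(h = 8, lty = 2, col = "grey50")
  invisible(x)
}

#' Write / read a Fisher information series as CSV
#'
#' `write_fi_table()` writes the series with columns \code{time_label},
#' \code{fi}, \code{n_states} and \code{tl_mode}; values carry 15
#' significant digits so `read_fi_table()` recovers them to better than 12
#' significant digits.
#'
#' @param series a non-empty \code{fi_series}.
#' @param path file path.
#' @return `write_fi_table()` invisibly returns \code{path};
#'   `read_fi_table()` returns an \code{fi_series} (window metadata
#'   attributes are not stored in the file and default to \code{NA}).
#' @export
write_fi_table <- function(series, path) {
  stopifnot(inherits(series, "fi_series"))
  if (nrow(series) < 1L)
    stop("cannot write an empty index series", call. = FALSE)
  df <- data.frame(
    time_label = format(series$time, digits = 15, trim = TRUE,
                        scientific = FALSE),
    fi = format(series$fi, digits = 15, trim = TRUE),
    n_states = series$n_states,
    tl_mode = series$tl_mode)
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write to ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_fi_table
#' @export
read_fi_table <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_label", "fi", "n_states", "tl_mode")
  if (!all(need %in% names(df)))
    stop("not an index table (expected columns ",
         paste(need, collapse = ", "), "): ", path, call. = FALSE)
  structure(data.frame(time = as.numeric(df$time_label),
                       fi = as.numeric(df$fi),
                       n_states = as.integer(df$n_states),
                       tl_mode = df$tl_mode),
            class = c("fi_series", "data.frame"),
            width = NA_integer_, increment = NA_integer_,
            deltas = NULL, smooth = 1L)
}
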