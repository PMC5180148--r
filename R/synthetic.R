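#' Specify one regime of a piecewise-stationary test series
#'
#' A regime is a contiguous block of time steps during which each variable
#' fluctuates around a fixed mean with a fixed Gaussian noise scale.
#' Successive regimes passed to [simulate_regimes()] must tile the time
#' axis without gaps or overlaps; a shift in the mean vector between
#' regimes is the regime shift the Fisher information index is meant to
#' detect.
#'
#' @param start,end inclusive time-step range (integers, \code{start <=
#'   end}).
#' @param means numeric vector of per-variable means.
#' @param sds per-variable noise standard deviations (non-negative);
#'   recycled to the length of \code{means}. Zero gives a noiseless regime.
#' @return A \code{fi_regime_spec} list.
#' @export
regime <- function(start, end, means, sds = 0) {
  if (!is.numeric(start) || !is.numeric(end) || start != round(start) ||
      end != round(end) || end < start)
    stop("'start' and 'end' must be integers with start <= end",
         call. = FALSE)
  means <- as.numeric(means)
  sds <- rep_len(as.numeric(sds), length(means))
  if (anyNA(means) || anyNA(sds) || any(sds < 0))
    stop("'means' must be finite and 'sds' non-negative", call. = FALSE)
  structure(list(start = as.integer(start), end = as.integer(end),
                 means = means, sds = sds),
            class = "fi_regime_spec")
}

#' Generate a piecewise-stationary multivariate series
#'
#' Draws each time step of each regime independently as
#' \eqn{y_i(t) \sim N(\mu_i, \sigma_i^2)} with the regime's mean and noise
#' scale for variable i. The generator exists so that every stage of the
#' analysis is testable without external data: regimes whose means differ
#' by much more than the size of state while the noise stays well inside it
#' produce windows with a known number of states and hence a known index.
#'
#' A seed is mandatory; the same seed reproduces the same matrix exactly.
#' The global random-number state is left untouched.
#'
#' @param regimes list of [regime()] specifications, contiguous in time
#'   (\code{start} of each equals \code{end + 1} of the previous) and with
#'   a consistent number of variables.
#' @param seed integer seed.
#' @param variable_names optional variable names.
#' @return An [fi_timeseries()] with time labels running over the regimes'
#'   combined range.
#' @examples
#' ts <- simulate_regimes(list(regime(1, 50, c(0, 0), 0.1),
#'                             regime(51, 100, c(5, 5), 0.1)), seed = 42)
#' ts
#' @export
simulate_regimes <- function(regimes, seed, variable_names = NULL) {
  if (inherits(regimes, "fi_regime_spec")) regimes <- list(regimes)
  if (!length(regimes) || !all(vapply(regimes, inherits, logical(1L),
                                      "fi_regime_spec")))
    stop("'regimes' must be a non-empty list of regime() specifications",
         call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("an integer 'seed' is required", call. = FALSE)
  n <- length(regimes[[1L]]$means)
  for (r in regimes)
    if (length(r$means) != n)
      stop("all regimes must have the same number of variables",
           call. = FALSE)
  starts <- vapply(regimes, `[[`, integer(1L), "start")
  ends <- vapply(regimes, `[[`, integer(1L), "end")
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]; regimes <- regimes[ord]
  if (length(regimes) > 1L &&
      any(starts[-1L] != ends[-length(ends)] + 1L))
    stop("regime ranges must be contiguous and non-overlapping",
         call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))

  rows <- lapply(regimes, function(r) {
    len <- r$end - r$start + 1L
    noise <- matrix(stats::rnorm(len * n), len, n)
    sweep(noise, 2L, r$sds, `*`) +
      matrix(r$means, len, n, byrow = TRUE)
  })
  fi_timeseries(do.call(rbind, rows), starts[1L]:ends[length(ends)],
                variable_names)
}
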