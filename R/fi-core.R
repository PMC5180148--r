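#' State probabilities and amplitudes of a window
#'
#' Converts a state partition into the discrete probability distribution
#' over states, \eqn{p_i = } (points in state i) / (points in window), in
#' discovery order, together with the amplitudes \eqn{q_i = \sqrt{p_i}}.
#' Working with amplitudes rather than raw probabilities is what lets the
#' discrete Fisher information avoid dividing by small probabilities.
#'
#' @param partition an [bin_window()] result.
#' @return An object of class \code{fi_profile}: list with \code{p},
#'   \code{q} (both length m, discovery order), \code{m} and
#'   \code{window_size}.
#' @examples
#' pts <- rbind(c(0.6, 1.5), c(2, 1.5), c(0.3, 1), c(3.5, 4.8),
#'              c(0.95, 2), c(3.1, 4), c(2.4, 1.8), c(2.7, 2.1))
#' state_probabilities(bin_window(pts, c(0.5, 1)))$p
#' # 0.375 0.250 0.250 0.125
#' @export
state_probabilities <- function(partition) {
  stopifnot(inherits(partition, "fi_partition"))
  counts <- tabulate(partition$assignments, nbins = partition$m)
  w <- length(partition$assignments)
  p <- counts / w
  structure(list(p = p, q = sqrt(p), m = partition$m, window_size = w),
            class = "fi_profile")
}

#' @export
print.fi_profile <- function(x, ...) {
  cat("State probability profile: m = ", x$m, " states over ",
      x$window_size, " points\n", sep = "")
  print(round(rbind(p = x$p, q = x$q), 4))
  invisible(x)
}

#' Discrete Fisher information of one window
#'
#' Evaluates the discrete Fisher information
#' \deqn{FI = 4 \sum_i (q_i - q_{i+1})^2}
#' over the state amplitudes \eqn{q_i = \sqrt{p_i}} taken in discovery
#' order, with one zero amplitude prepended and one appended (the initial
#' and final amplitudes are set to zero). The zero boundary makes the index
#' strictly positive; its maximum, 8, is attained exactly when the window
#' occupies a single state (\eqn{4[(0-1)^2 + (1-0)^2]}). A uniform
#' distribution over m states gives exactly 8/m. High, steady values of the
#' index indicate an orderly regime; declines indicate loss of order and a
#' sharp drop signals a regime shift.
#'
#' @param x an \code{fi_profile} from [state_probabilities()], an
#'   \code{fi_partition} from [bin_window()], or a numeric probability
#'   vector (summing to 1) in state order.
#' @return The Fisher information, a number in (0, 8].
#' @examples
#' fisher_information(c(0.375, 0.25, 0.25, 0.125))  # 2.1363 (= 4 x 0.534074)
#' fisher_information(1)                            # 8: single state
#' fisher_information(rep(1 / 8, 8))                # 1: uniform over 8 states
#' @export
fisher_information <- function(x) {
  if (inherits(x, "fi_partition")) x <- state_probabilities(x)
  if (inherits(x, "fi_profile")) {
    q <- x$q
  } else {
    p <- as.numeric(x)
    if (length(p) < 1L || anyNA(p) || any(p < 0))
      stop("'x' must be a valid probability vector, profile or partition",
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-8)
      stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
           call. = FALSE)
    q <- sqrt(p)
  }
  4 * sum(diff(c(0, q, 0))^2)
}
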