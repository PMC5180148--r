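#' Indistinguishability of two system observations
#'
#' Two points of an n-variable system are indistinguishable — they belong to
#' the same state — when \eqn{|c_i - x_i| \le \Delta y_i} holds for at least
#' a fraction \code{tl} of the variables. With the strict tightening level
#' \code{tl = 1} every variable must satisfy its bin width; lower levels
#' admit points for which only a given percentage of variables do, which is
#' useful for noisy high-dimensional data. The comparison is inclusive.
#'
#' @param center,point numeric vectors of equal length n.
#' @param deltas size of state: an [size_of_state()] object or numeric
#'   vector of length n.
#' @param tl tightening level, a fraction in (0, 1]; default 1 (strict).
#' @return \code{TRUE} if the point lies in the center's state.
#' @examples
#' same_state(c(0.6, 1.5), c(0.3, 1.0), c(0.5, 1))         # TRUE
#' same_state(c(2, 1.5), c(2.7, 2.1), c(0.5, 1))           # FALSE
#' same_state(c(2, 1.5), c(2.7, 2.1), c(0.5, 1), tl = 0.5) # TRUE
#' @export
same_state <- function(center, point, deltas, tl = 1) {
  n <- length(center)
  if (length(point) != n)
    stop("'center' and 'point' have different lengths", call. = FALSE)
  d <- sos_deltas(deltas, n)
  if (!is.numeric(tl) || length(tl) != 1L || tl <= 0 || tl > 1)
    stop("'tl' must be a fraction in (0, 1]", call. = FALSE)
  sum(abs(center - point) <= d) >= tl * n - 1e-9
}

#' Greedy hyper-rectangle binning of a time window
#'
#' Partitions the points of one time window into discrete system states. The
#' earliest point not yet assigned founds the next state and becomes its
#' center; every later unassigned point within the center's hyper-rectangle
#' (per [same_state()] at the given tightening level) is captured
#' immediately. Assigned points are never revisited, so membership is
#' first-come: a point stays with the first center that captured it even if
#' a later center's rectangle also covers it. The procedure terminates with
#' every point assigned to exactly one state, states numbered in discovery
#' (time) order.
#'
#' Membership is tested against the founding center only, not pairwise
#' between members, so two members of one state may differ by more than the
#' size of state. The result deliberately depends on time order; that is
#' part of the method's definition, not an artefact.
#'
#' @param points numeric matrix, one row per in-window point (time order),
#'   or an [fi_timeseries()] (all of whose rows form the window).
#' @param deltas size of state (vector or [size_of_state()]).
#' @param tl tightening level in (0, 1]; default 1.
#' @return An object of class \code{fi_partition}: list with
#'   \code{assignments} (state index per point), \code{center_indices}
#'   (founding point of each state), \code{m} (number of states) and
#'   \code{tl}.
#' @examples
#' pts <- rbind(c(0.6, 1.5), c(2, 1.5), c(0.3, 1), c(3.5, 4.8),
#'              c(0.95, 2), c(3.1, 4), c(2.4, 1.8), c(2.7, 2.1))
#' bin_window(pts, c(0.5, 1))  # four states: {1,3,5} {2,7} {4,6} {8}
#' @export
bin_window <- function(points, deltas, tl = 1) {
  if (inherits(points, "fi_timeseries")) points <- points$values
  points <- as.matrix(points)
  w <- nrow(points)
  if (w < 1L)
    stop("window is empty", call. = FALSE)
  n <- ncol(points)
  d <- sos_deltas(deltas, n)
  if (!is.numeric(tl) || length(tl) != 1L || tl <= 0 || tl > 1)
    stop("'tl' must be a fraction in (0, 1]", call. = FALSE)
  need <- tl * n - 1e-9
  assignments <- integer(w)
  centers <- integer(0)
  m <- 0L
  for (i in seq_len(w)) {
    if (assignments[i] != 0L) next
    m <- m + 1L
    centers[m] <- i
    assignments[i] <- m
    if (i < w) {
      free <- which(assignments == 0L)
      free <- free[free > i]
      if (length(free)) {
        dev <- abs(points[free, , drop = FALSE] -
                     matrix(points[i, ], length(free), n, byrow = TRUE))
        hits <- rowSums(dev <= matrix(d, length(free), n, byrow = TRUE))
        assignments[free[hits >= need]] <- m
      }
    }
  }
  structure(list(assignments = assignments, center_indices = centers,
                 m = m, tl = tl),
            class = "fi_partition")
}

#' @export
print.fi_partition <- function(x, ...) {
  cat("State partition: ", length(x$assignments), " points in ", x$m,
      " state(s), tightening level ", format(x$tl), "\n", sep = "")
  for (s in seq_len(x$m))
    cat("  state ", s, " (center point ", x$center_indices[s], "): {",
        paste(which(x$assignments == s), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Tightening levels over which a window's index is averaged
#'
#' With n variables the natural grid of tightening levels is
#' \eqn{n/n, (n-1)/n, \ldots, 1/n}. When no single level is preferred, the
#' index for a window is averaged over all levels from strict (100%) down to
#' the lowest level at which the window still resolves more than one state.
#' This function returns that contiguous prefix of the grid. Lowering the
#' level can only merge states, so the number of states is non-increasing
#' along the grid; if even the strict level yields a single state the
#' result is just \code{1}.
#'
#' @param points window points (matrix or [fi_timeseries()]).
#' @param deltas size of state.
#' @param grid optional descending vector of levels; defaults to multiples
#'   of 1/n.
#' @return Numeric vector of levels, descending, starting at 1.
#' @examples
#' pts <- rbind(c(0.6, 1.5), c(2, 1.5), c(0.3, 1), c(3.5, 4.8),
#'              c(0.95, 2), c(3.1, 4), c(2.4, 1.8), c(2.7, 2.1))
#' tl_levels(pts, c(0.5, 1))  # c(1, 0.5): both levels give m > 1
#' @export
tl_levels <- function(points, deltas, grid = NULL) {
  if (inherits(points, "fi_timeseries")) points <- points$values
  points <- as.matrix(points)
  n <- ncol(points)
  if (is.null(grid)) grid <- seq.int(n, 1L) / n
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  if (abs(grid[1L] - 1) > 1e-9)
    stop("the tightening grid must start at the strict level 1", call. = FALSE)
  keep <- numeric(0)
  for (lev in grid) {
    m <- bin_window(points, deltas, tl = lev)$m
    if (m > 1L) keep <- c(keep, lev) else break
  }
  if (!length(keep)) keep <- 1
  keep
}
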