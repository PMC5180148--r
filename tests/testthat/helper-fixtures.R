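# Shared fixtures, all built in code at test time.

# The 8-point, 2-variable walkthrough window: binning with size of state
# (0.5, 1) at the strict tightening level yields the four states
# {1,3,5} {2,7} {4,6} {8}.
table1_points <- function() {
  rbind(c(0.6, 1.5), c(2.0, 1.5), c(0.3, 1.0), c(3.5, 4.8),
        c(0.95, 2.0), c(3.1, 4.0), c(2.4, 1.8), c(2.7, 2.1))
}

table1_deltas <- function() c(0.5, 1)

write_table1_csv <- function(path = tempfile(fileext = ".csv")) {
  pts <- table1_points()
  utils::write.csv(data.frame(time = 1:8, Y1 = pts[, 1], Y2 = pts[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  path
}

# GISTEMP-style monthly anomaly fixture. 'missing' maps year -> month
# indices replaced by the *** marker.
write_gistemp_fixture <- function(years, values = NULL,
                                  missing = list(),
                                  path = tempfile(fileext = ".csv"),
                                  sep = ",") {
  months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  if (is.null(values))
    values <- matrix(seq_len(12 * length(years)), length(years), 12)
  lines <- paste(c("Year", months), collapse = sep)
  for (i in seq_along(years)) {
    row <- format(values[i, ], trim = TRUE)
    miss <- missing[[as.character(years[i])]]
    if (!is.null(miss)) row[miss] <- "***"
    lines <- c(lines, paste(c(years[i], row), collapse = sep))
  }
  writeLines(lines, path)
  path
}

# Random window of points for property tests.
random_window <- function(w, n, spread = 3) {
  matrix(stats::runif(w * n, 0, spread), w, n)
}
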