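test_that("delimited tables parse into a validated container", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(t = 1:3, a = c(1.5, 2.5, 3.5), b = c(0, 0, 1)),
            f, row.names = FALSE)
  ts <- read_timeseries_table(f)
  expect_s3_class(ts, "fi_timeseries")
  expect_equal(dim(ts), c(3L, 2L))
  expect_equal(ts$time, c(1, 2, 3))
  expect_equal(colnames(ts$values), c("a", "b"))
  expect_equal(ts$values[, "a"], c(1.5, 2.5, 3.5))
})

test_that("write then read reproduces a series exactly", {
  set.seed(11)
  ts <- fi_timeseries(matrix(rnorm(60), 20, 3), 1981:2000,
                      c("x", "y", "z"))
  f <- tempfile(fileext = ".csv")
  write_timeseries_table(ts, f)
  back <- read_timeseries_table(f)
  expect_equal(back$time, ts$time)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  # single-row series round-trips too
  one <- fi_timeseries(matrix(c(1.25, -2.5), 1, 2), 5)
  f2 <- tempfile(fileext = ".csv")
  write_timeseries_table(one, f2)
  expect_equal(read_timeseries_table(f2)$values, one$values)
})

test_that("malformed tables are rejected with located errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("t,a", "1,0.5", "2,", "3,1"), f)
  expect_error(read_timeseries_table(f), "row 2.*column 'a'")
  writeLines(c("t,a", "1,0.5", "3,1", "2,2"), f)
  expect_error(read_timeseries_table(f), "strictly increasing.*row 3")
  writeLines(c("t,a", "1,0.5", "1,1"), f)
  expect_error(read_timeseries_table(f), "[Dd]uplicate")
  writeLines(c("t,a", "1,0.5", "two,1"), f)
  expect_error(read_timeseries_table(f), "time label.*row 2")
  expect_error(read_timeseries_table(tempfile()), "not found")
})

test_that("container invariants are enforced at construction", {
  expect_error(fi_timeseries(matrix(c(1, NA), 2, 1)), "row 2, column 1")
  expect_error(fi_timeseries(matrix(1:4, 2, 2), c(2, 1)),
               "strictly increasing")
  expect_error(fi_timeseries(matrix(1:4, 2, 2), 1:3), "does not match")
  expect_warning(fi_timeseries(matrix(1:4, 4, 1), c(1, 2, 5, 6)),
                 "irregularly spaced")
})

test_that("GISTEMP-style tables become 12-variable yearly series", {
  f <- write_gistemp_fixture(2000:2002)
  ts <- read_gistemp_monthly(f)
  expect_equal(dim(ts), c(3L, 12L))
  expect_equal(ts$time, c(2000, 2001, 2002))
  expect_equal(colnames(ts$values)[c(1, 12)], c("Jan", "Dec"))
  # whitespace-separated layout with annual-summary extras is accepted
  months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  f2 <- tempfile()
  writeLines(c(paste(c("Year", months, "J-D"), collapse = "  "),
               paste(c(1999, 1:12, 99), collapse = "  "),
               paste(c(2000, 13:24, 99), collapse = "  ")), f2)
  ts2 <- read_gistemp_monthly(f2)
  expect_equal(dim(ts2), c(2L, 12L))
  expect_equal(unname(ts2$values[1, ]), as.numeric(1:12))
})

test_that("years with any missing month are excluded and reported", {
  f <- write_gistemp_fixture(2000:2002,
                             missing = list("2001" = 5L))
  expect_message(ts <- read_gistemp_monthly(f), "excluded 1 year.*2001")
  expect_equal(ts$time, c(2000, 2002))
  expect_equal(attr(ts, "excluded_years"), 2001)

  f2 <- write_gistemp_fixture(2000:2001,
                              missing = list("2000" = 1L, "2001" = 2L))
  expect_error(read_gistemp_monthly(f2), "no complete year rows")
  f3 <- tempfile()
  writeLines(c("Year,Jan,Feb", "2000,1,2"), f3)
  expect_error(read_gistemp_monthly(f3), "malformed header")
})

test_that("the GISTEMP reader always yields a valid container", {
  # randomized fixtures with injected missing markers
  set.seed(402)
  for (rep in 1:20) {
    ny <- sample(3:12, 1)
    years <- seq(1950, by = 1, length.out = ny)
    vals <- matrix(round(rnorm(ny * 12, 0, 50)), ny, 12)
    miss <- list()
    for (y in sample(years, sample(0:(ny - 1), 1)))
      miss[[as.character(y)]] <- sample(12, sample(1:3, 1))
    f <- write_gistemp_fixture(years, vals, miss)
    ts <- suppressWarnings(suppressMessages(read_gistemp_monthly(f)))
    expect_equal(ncol(ts$values), 12L)
    expect_true(all(diff(ts$time) > 0))
    expect_true(all(is.finite(ts$values)))
    expect_setequal(c(ts$time, attr(ts, "excluded_years")), years)
  }
})

test_that("index tables round-trip through CSV", {
  ts <- suppressWarnings(
    fi_timeseries(matrix(runif(30), 30, 1), 1:30))
  s <- fi_index(ts, 0.2, width = 8)
  f <- tempfile(fileext = ".csv")
  write_fi_table(s, f)
  back <- read_fi_table(f)
  expect_equal(back$time, s$time)
  expect_equal(back$fi, s$fi, tolerance = 1e-12)
  expect_equal(back$n_states, s$n_states)
  expect_equal(nrow(read.csv(f)), nrow(s))
})

test_that("an empty index series cannot be written", {
  s <- structure(data.frame(time = numeric(0), fi = numeric(0),
                            n_states = integer(0),
                            tl_mode = character(0)),
                 class = c("fi_series", "data.frame"))
  expect_error(write_fi_table(s, tempfile()), "empty")
})
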