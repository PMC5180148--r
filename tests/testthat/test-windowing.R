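test_that("windows slide by the increment and label their last step", {
  set.seed(5)
  ts <- fi_timeseries(matrix(rnorm(136 * 2), 136, 2), 1880:2015)
  s <- fi_index(ts, c(1, 1), width = 40, increment = 1)
  expect_equal(nrow(s), 97L)                       # 136 - 40 + 1
  expect_equal(s$time[1], 1919)
  expect_equal(s$time[97], 2015)
  # entry-count formula over assorted (T, w, h)
  for (rep in 1:25) {
    T_ <- sample(8:60, 1)
    w <- (8:T_)[sample.int(T_ - 7, 1)]
    h <- sample(seq_len(max(1, w - 1)), 1)
    tsr <- fi_timeseries(matrix(rnorm(T_), T_, 1))
    sr <- fi_index(tsr, 1, width = w, increment = h)
    expect_equal(nrow(sr), floor((T_ - w) / h) + 1)
    expect_equal(sr$time, (seq.int(0, by = h,
                                   length.out = nrow(sr)) + w))
  }
})

test_that("edge window specs behave as documented", {
  ts <- fi_timeseries(matrix(rnorm(10), 10, 1))
  one <- fi_index(ts, 1, width = 10)
  expect_equal(nrow(one), 1L)
  expect_equal(one$time, 10)
  expect_error(fi_index(ts, 1, width = 11), "at least 11")
  expect_error(fi_index(ts, 1, width = 8, increment = 9), "must not exceed")
  expect_warning(fi_index(ts, 1, width = 8, increment = 8),
                 "share no data")
  expect_warning(fi_index(ts, 1, width = 4), "recommended minimum")
  expect_error(fi_index(ts, c(1, 2), width = 8), "1 variable")
})

test_that("a single-window run reproduces the worked example end to end", {
  ts <- fi_timeseries(table1_points(), 1:8, c("Y1", "Y2"))
  s <- fi_index(ts, size_of_state(table1_deltas()), width = 8)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_states, 4L)
  expect_equal(s$fi, 2.1362967, tolerance = 1e-7)
  # averaged tightening: mean of FI at levels 1 and 0.5
  sa <- fi_index(ts, table1_deltas(), width = 8, tl = "averaged")
  fi_half <- fisher_information(bin_window(table1_points(),
                                           table1_deltas(), tl = 0.5))
  expect_equal(sa$fi, mean(c(2.1362967, fi_half)), tolerance = 1e-7)
  expect_equal(sa$n_levels, 2L)
})

test_that("a straddling window follows the two-state closed form", {
  # two noiseless regimes far apart: a window with a fraction f of its
  # points in the first regime scores 4[f + (sqrt(f)-sqrt(1-f))^2 + (1-f)]
  ts <- simulate_regimes(list(regime(1, 30, 0, 0), regime(31, 60, 10, 0)),
                         seed = 1)
  w <- 10L
  s <- fi_index(ts, 0.5, width = w)
  for (j in seq_len(nrow(s))) {
    t_end <- s$time[j]
    n_a <- sum(seq.int(t_end - w + 1, t_end) <= 30)
    f <- n_a / w
    expected <- if (f == 0 || f == 1) 8 else
      4 * (f + (sqrt(f) - sqrt(1 - f))^2 + (1 - f))
    expect_equal(s$fi[j], expected, tolerance = 1e-12)
    expect_equal(s$n_states[j], if (f %in% c(0, 1)) 1L else 2L)
  }
})

test_that("block averaging replaces blocks by their mean, partial tail by its own",
{
  base <- structure(
    data.frame(time = 1:5, fi = c(1, 2, 3, 4, 5), n_states = 1L,
               tl_mode = "strict"),
    class = c("fi_series", "data.frame"),
    width = 2L, increment = 1L, smooth = 1L)
  expect_equal(block_average(base, 1)$fi, base$fi)
  expect_equal(block_average(base, 2)$fi, c(1.5, 1.5, 3.5, 3.5, 5))
  b3 <- base; b3$fi <- c(2, 4, 6, 0, 0)
  expect_equal(block_average(b3, 3)$fi[1:3], c(4, 4, 4))
  # mean-preserving per complete block, labels untouched
  sm <- block_average(base, 2)
  expect_equal(sm$time, base$time)
  expect_equal(mean(sm$fi[1:2]), mean(base$fi[1:2]))
  expect_error(block_average(base, 0), "integer")
})

test_that("regime summaries report mean and sample sd over the period", {
  s <- structure(
    data.frame(time = 1:4, fi = c(4, 6, 5, 5), n_states = 2L,
               tl_mode = "strict"),
    class = c("fi_series", "data.frame"),
    width = 2L, increment = 1L, smooth = 1L)
  r <- regime_summary(s, c(1, 2))
  expect_equal(r$mu_fi, 5)
  expect_equal(r$sigma_fi, sqrt(2))
  expect_equal(r$n, 2L)
  const <- s; const$fi <- rep(3, 4)
  expect_equal(regime_summary(const, c(1, 4))$sigma_fi, 0)
  expect_equal(regime_summary(s, c(3, 3))$sigma_fi, 0)   # n = 1
  expect_error(regime_summary(s, c(10, 20)), "no index entries")
  both <- summary(s, periods = list(c(1, 2), c(3, 4)))
  expect_equal(nrow(both), 2L)
  expect_equal(both$mu_fi, c(5, 5))
})

test_that("trend labels follow the interpretation rules", {
  mk <- function(fi) structure(
    data.frame(time = seq_along(fi), fi = fi, n_states = 1L,
               tl_mode = "strict"),
    class = c("fi_series", "data.frame"),
    width = 8L, increment = 1L, smooth = 1L)
  expect_true(all(classify_trend(mk(rep(5, 12))) == "stable"))
  ramp <- mk(seq(8, 2.5, by = -0.5))
  lab <- classify_trend(ramp, span = 6, slope_tolerance = 0.1)
  expect_true(all(lab[-1] == "declining"))
  rise <- mk(seq(2, 7.5, by = 0.5))
  expect_true(all(classify_trend(rise, span = 6,
                                 slope_tolerance = 0.1)[-1] == "increasing"))
  step <- mk(c(rep(6, 6), 2, rep(2, 5)))
  lab2 <- classify_trend(step, span = 4, drop_threshold = 2)
  expect_equal(lab2[7], "sharp_drop")
  expect_error(classify_trend(mk(c(1, 2)), span = 5), "span")
  expect_error(classify_trend(mk(5)[0, ]), "at least 2")
})

test_that("the index series is invariant to shifts and joint rescaling", {
  set.seed(61)
  ts <- simulate_regimes(list(regime(1, 25, c(0, 2), 0.3),
                              regime(26, 50, c(4, -1), 0.3)), seed = 61)
  d <- c(0.6, 0.6)
  ref <- fi_index(ts, d, width = 10)
  for (shift in c(-5, 3.7)) {
    shifted <- fi_timeseries(ts$values + shift, ts$time)
    expect_equal(fi_index(shifted, d, width = 10)$fi, ref$fi)
  }
  for (c_ in c(0.2, 5)) {
    scaled <- fi_timeseries(ts$values * c_, ts$time)
    expect_equal(fi_index(scaled, d * c_, width = 10)$fi, ref$fi)
  }
  # averaged mode inherits both invariances
  ref_a <- fi_index(ts, d, width = 10, tl = "averaged")
  shifted <- fi_timeseries(ts$values + 11, ts$time)
  expect_equal(fi_index(shifted, d, width = 10, tl = "averaged")$fi,
               ref_a$fi)
})

test_that("smoothing through fi_index matches block_average", {
  set.seed(71)
  ts <- fi_timeseries(matrix(rnorm(30), 30, 1))
  plain <- fi_index(ts, 0.5, width = 8)
  sm <- fi_index(ts, 0.5, width = 8, smooth = 3)
  expect_equal(sm$fi, block_average(plain, 3)$fi)
  expect_equal(attr(sm, "smooth"), 3L)
})
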