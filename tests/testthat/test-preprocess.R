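t0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")

series_at <- function(minutes, glucose, id = "s1") {
  cgm_series(id, t0 + minutes * 60, glucose)
}

test_that("short gaps are linearly imputed, long and 15-min gaps are not", {
  ser <- series_at(c(0, 10), c(100, 110))
  grid <- impute_gaps(ser)
  expect_equal(grid$glucose, c(100, 105, 110))
  expect_equal(grid$imputed, c(FALSE, TRUE, FALSE))

  ser20 <- series_at(c(0, 5, 25, 30), c(100, 100, 120, 120))
  grid20 <- impute_gaps(ser20)
  expect_true(all(is.na(grid20$glucose[3:5])))

  # a gap of exactly 15 minutes stays missing (strictly-under rule)
  ser15 <- series_at(c(0, 15), c(100, 130))
  expect_true(all(is.na(impute_gaps(ser15)$glucose[2:3])))
})

test_that("Savitzky-Golay smoothing preserves polynomials and damps spikes", {
  expect_equal(sg_smooth(rep(7, 20)), rep(7, 20), tolerance = 1e-9)
  ramp <- seq(80, 120, length.out = 25)
  expect_equal(sg_smooth(ramp), ramp, tolerance = 1e-9)

  spike <- c(rep(100, 10), 160, rep(100, 10))
  sm <- sg_smooth(spike)
  expect_lt(max(sm) - 100, 60)
  # oracle: direct least-squares cubic fit over the centered 5-point window
  idx <- 9:13
  fit <- lm(y ~ poly(x, 3, raw = TRUE),
            data = data.frame(x = idx, y = spike[idx]))
  expect_equal(sm[11], unname(predict(fit)[3]), tolerance = 1e-8)

  expect_error(sg_smooth(c(1, 2, 3)), "shorter")
  expect_error(sg_smooth(c(1, NA, 3, 4, 5)), "missing")
})

test_that("z-normalization uses sample sd and flags flat windows", {
  w <- glucotyper:::new_window("s1", t0, c(90, 100, 110))
  wz <- znormalize(w)
  expect_equal(wz$norm, c(-1, 0, 1))

  flat <- znormalize(glucotyper:::new_window("s1", t0, rep(100, 30)))
  expect_true(flat$degenerate)
  expect_null(flat$norm)

  set.seed(1)
  for (i in 1:20) {
    wz <- znormalize(glucotyper:::new_window("s1", t0, rnorm(30, 100, 15)))
    expect_equal(mean(wz$norm), 0, tolerance = 1e-9)
    expect_equal(sd(wz$norm), 1, tolerance = 1e-9)
  }
})

test_that("segmentation honors window length, shift, and missingness", {
  cfg40 <- windowing_config(shift_min = 40)
  short <- series_at(seq(0, 115, by = 5), 100 + sin(1:24))
  expect_length(segment_windows(impute_gaps(short), cfg40), 0)

  five_h <- series_at(seq(0, 300, by = 5), 100 + 10 * sin((0:60) / 3))
  wins <- segment_windows(impute_gaps(five_h), cfg40)
  expect_length(wins, 4)
  starts <- vapply(wins, function(w)
    as.numeric(difftime(w$start_time, t0, units = "mins")), numeric(1))
  expect_equal(starts, c(0, 40, 80, 120))
  expect_true(all(vapply(wins, function(w) length(w$raw), integer(1)) == 30))
  expect_false(any(vapply(wins, function(w) anyNA(w$norm), logical(1))))

  # default 75% overlap of 150 min: cumulative starts snap to the 5-min
  # grid with alternating 35/40-min shifts averaging 37.5
  long <- series_at(seq(0, 600, by = 5), 100 + 10 * sin((0:120) / 3))
  wd <- segment_windows(impute_gaps(long), windowing_config())
  sd_starts <- vapply(wd, function(w)
    as.numeric(difftime(w$start_time, t0, units = "mins")), numeric(1))
  expect_equal(sd_starts[1:5], c(0, 40, 75, 110, 150))
  expect_true(all(diff(sd_starts) %in% c(35, 40)))

  # windows overlapping an unfilled gap are dropped
  gappy <- series_at(c(seq(0, 100, 5), seq(125, 300, 5)),
                     100 + 10 * sin(seq_len(57)))
  wg <- segment_windows(impute_gaps(gappy), cfg40)
  sg <- vapply(wg, function(w)
    as.numeric(difftime(w$start_time, t0, units = "mins")), numeric(1))
  expect_false(any(sg <= 120 & sg + 145 >= 105))
})

test_that("count equalization trims every subject to the smallest count", {
  raw <- matrix(rnorm(37 * 30, 100, 12), nrow = 37)
  subj <- rep(c("a", "b", "c"), c(10, 12, 15))
  wins <- make_windows(raw, subject = subj)
  eq <- equalize_counts(wins)
  expect_length(eq, 30)
  expect_equal(as.integer(table(vapply(eq, function(w) w$subject_id,
                                       character(1)))), rep(10L, 3))
  # kept windows are each subject's earliest
  first_b <- which(subj == "b")[1:10]
  kept_b <- vapply(eq, function(w) w$subject_id, character(1)) == "b"
  expect_equal(vapply(eq[kept_b], function(w) w$start_time[[1]], numeric(1)),
               vapply(wins[first_b], function(w) w$start_time[[1]],
                      numeric(1)))

  one <- make_windows(raw[1:5, ], subject = rep("solo", 5))
  expect_length(equalize_counts(one), 5)
})

test_that("cohort preprocessing warns on zero-window subjects", {
  co <- shared_cohort()
  tiny <- co$series[1:2]
  tiny$stub <- cgm_series("stub", t0 + (0:10) * 300, rep(100, 11))
  expect_warning(wins <- preprocess_cohort(tiny), "stub")
  ids <- unique(vapply(wins, function(w) w$subject_id, character(1)))
  expect_false("stub" %in% ids)
  tab <- table(vapply(wins, function(w) w$subject_id, character(1)))
  expect_true(length(unique(tab)) == 1)
})
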