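test_that("descriptive statistics match hand arithmetic and a loop oracle", {
  const <- basic_stats(rep(100, 20))
  expect_equal(const$sd, 0)
  expect_equal(const$distance_traveled, 0)
  expect_equal(const$n_above_140, 0)
  expect_equal(const$cv, 0)

  tri <- basic_stats(c(100, 110, 100))
  expect_equal(tri$max_rate, 2)
  expect_equal(tri$mean_rate, 2)
  expect_equal(tri$distance_traveled, 20)

  set.seed(17)
  x <- round(rnorm(100, 120, 35))
  bs <- basic_stats(x)
  # naive recomputation
  dist_tr <- 0; mx <- 0; cross140 <- 0; cross200 <- 0
  for (i in 2:length(x)) {
    dist_tr <- dist_tr + abs(x[i] - x[i - 1])
    mx <- max(mx, abs(x[i] - x[i - 1]) / 5)
    if (x[i] > 140 && x[i - 1] <= 140) cross140 <- cross140 + 1
    if (x[i] > 200 && x[i - 1] <= 200) cross200 <- cross200 + 1
  }
  expect_equal(bs$distance_traveled, dist_tr)
  expect_equal(bs$max_rate, mx)
  expect_equal(bs$n_above_140, cross140)
  expect_equal(bs$n_above_200, cross200)
  expect_equal(bs$frac_below_80, sum(x < 80) / length(x))
  expect_gte(bs$distance_traveled, abs(x[length(x)] - x[1]))
  expect_true(bs$min <= bs$q25 && bs$q25 <= bs$median &&
                bs$median <= bs$q75 && bs$q75 <= bs$max)
  expect_error(basic_stats(100), "at least 2")
})

test_that("MAGE closed forms: flat traces, square waves, sinusoids", {
  expect_equal(mage(rep(100, 50))$mage, 0)

  sq <- rep(c(80, 160), 12)
  expect_equal(mage(sq)$mage, 80)
  expect_equal(mage(sq)$mage_ascending, 80)
  expect_equal(mage(sq)$mage_descending, 80)

  tt <- seq(0, 10 * 2 * pi, length.out = 1200)
  for (A in c(25, 60)) {
    sine <- 120 + A * sin(tt)
    m <- mage(sine)
    expect_equal(m$mage, 2 * A, tolerance = 0.05)
  }
})

test_that("MAGE ignores sub-threshold ripples and honors invariances", {
  # large slow wave with a small superimposed ripple: only the large
  # excursions qualify (ripple 10 << SD of the compound trace)
  tt <- seq(0, 6 * 2 * pi, length.out = 800)
  x <- 120 + 50 * sin(tt) + 5 * sin(24 * tt)
  m <- mage(x)
  expect_equal(m$mage, 100, tolerance = 0.1 * 100)

  sq <- rep(c(90, 150), 10) + rep(c(0, 1, -1, 2), 5)
  base <- mage(sq)
  shifted <- mage(sq + 37)
  expect_equal(shifted$mage, base$mage, tolerance = 1e-9)
  scaled <- mage(sq * 2.5)
  expect_equal(scaled$mage, 2.5 * base$mage, tolerance = 1e-9)
})

test_that("J index follows its closed form and is monotone in sd", {
  expect_equal(j_index(100, 0), 10)
  expect_equal(j_index(120, 30), 22.5)
  expect_lt(j_index(120, 10), j_index(120, 40))
  expect_error(j_index(-5, 3))
})

test_that("MODD pairs consecutive-day 06:00 anchors", {
  t0 <- as.POSIXct("2023-01-02 06:00:00", tz = "UTC")
  days3 <- cgm_series("s", t0 + c(0, 1, 2) * 86400, c(90, 110, 100))
  expect_equal(modd(days3), 15)

  same <- cgm_series("s", t0 + (0:3) * 86400, rep(105, 4))
  expect_equal(modd(same), 0)

  # a day whose nearest sample misses the +/-15-min anchor window drops
  # the pairs that involve it
  t_offsets <- c(0, 86400 + 3600, 2 * 86400, 3 * 86400)
  miss <- cgm_series("s", t0 + t_offsets, c(90, 200, 100, 130))
  expect_equal(modd(miss), 30)  # only the day3-day4 pair survives

  expect_true(is.na(modd(cgm_series("s", t0, 100))))
})

test_that("variability metrics separate synthetic low from severe windows", {
  cfg <- sim_config(n_subjects = 2, days = 2, regimes = c("low", "severe"),
                    gap_rate = 0, seed = 77)
  lo <- simulate_subject(cfg, "low", seed = 101, subject_id = "lo")
  hi <- simulate_subject(cfg, "severe", seed = 102, subject_id = "hi")
  wl <- segment_windows(impute_gaps(lo), windowing_config())
  wh <- segment_windows(impute_gaps(hi), windowing_config())
  wins <- glucotyper:::new_window_set(
    c(unclass(wl), unclass(wh)), m = 30, interval_min = 5)
  for (i in seq_along(wins)) {
    wins[[i]]$class <- if (i <= length(wl)) "low" else "severe"
  }
  tab <- class_metric_table(wins)
  means <- tab$means
  rownames(means) <- means$class
  for (metric in c("sd", "mage", "distance_traveled", "j_index", "cv",
                   "mean_rate", "iqr")) {
    expect_gt(means["severe", metric], means["low", metric])
  }
  expect_true(all(tab$tests$p_value[tab$tests$metric %in%
                                      c("sd", "mage", "j_index")] < 1e-6))
})

test_that("identical class distributions give null Kruskal-Wallis results", {
  raw <- matrix(rnorm(5 * 30, 100, 12), nrow = 5)
  wins3 <- make_windows(rbind(raw, raw, raw),
                        classes = rep(c("low", "moderate", "severe"),
                                      each = 5))
  tab <- class_metric_table(wins3)
  expect_true(all(tab$tests$p_value > 0.99))
})
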