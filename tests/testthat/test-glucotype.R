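test_that("class fractions sum to one and drive the glucotype", {
  f <- class_fractions(rep("low", 10))
  expect_equal(unname(f), c(1, 0, 0))
  f2 <- class_fractions(rep(c("low", "severe"), each = 119))
  expect_equal(unname(f2), c(0.5, 0, 0.5))
  expect_equal(sum(f2), 1)
  expect_error(class_fractions(character(0)), "no labeled")

  expect_equal(assign_glucotype(c(low = 0.6, moderate = 0.3,
                                  severe = 0.1)), "low")
  # exact tie resolves toward the more severe class
  expect_equal(assign_glucotype(c(low = 0.4, moderate = 0.4,
                                  severe = 0.2)), "moderate")
  expect_equal(assign_glucotype(c(low = 0.5, moderate = 0, severe = 0.5)),
               "severe")
})

test_that("ADA thresholds classify the canonical boundary cases", {
  expect_equal(ada_diagnosis(hba1c = 6.5), "diabetic")
  expect_equal(ada_diagnosis(fbg = 126), "diabetic")
  expect_equal(ada_diagnosis(ogtt_2h = 200), "diabetic")
  expect_equal(ada_diagnosis(hba1c = 5.5, fbg = 100, ogtt_2h = 120),
               "prediabetic")
  expect_equal(ada_diagnosis(hba1c = 5.8), "prediabetic")
  expect_equal(ada_diagnosis(ogtt_2h = 140), "prediabetic")
  expect_equal(ada_diagnosis(hba1c = 5.6, fbg = 99, ogtt_2h = 139),
               "normoglycemic")
  expect_equal(ada_diagnosis(hba1c = 5.7), "normoglycemic")  # strict >5.7
  expect_error(ada_diagnosis(), "missing")

  # monotonicity: raising any measure never lowers the category
  rank <- c(normoglycemic = 1, prediabetic = 2, diabetic = 3)
  set.seed(8)
  for (i in 1:50) {
    h <- runif(1, 4.5, 8); f <- runif(1, 70, 220); o <- runif(1, 80, 260)
    base <- rank[ada_diagnosis(h, f, o)]
    expect_gte(rank[ada_diagnosis(h + 0.5, f, o)], base)
    expect_gte(rank[ada_diagnosis(h, f + 15, o)], base)
    expect_gte(rank[ada_diagnosis(h, f, o + 25)], base)
  }
})

test_that("time in glycemic ranges partitions the readings", {
  expect_equal(unname(time_in_ranges(rep(100, 10))), c(0, 0))
  expect_equal(unname(time_in_ranges(c(rep(150, 5), rep(90, 5)))),
               c(0.5, 0))
  g <- c(120, 140, 141, 200, 201, 250)  # boundary handling: (140,200], >200
  tir <- time_in_ranges(g)
  expect_equal(unname(tir), c(2 / 6, 2 / 6))
})

test_that("meal responses take the most severe overlapping window", {
  t0 <- as.POSIXct("2023-01-02 08:00:00", tz = "UTC")
  labels <- data.frame(
    subject_id = "a",
    start_time = format(t0 + c(-40, -20, 0, 15, 45) * 60,
                        "%Y-%m-%d %H:%M:%S"),
    class = c("severe", "low", "low", "moderate", "severe"),
    stringsAsFactors = FALSE)
  meal <- data.frame(subject_id = "a", meal_type = "cornflakes",
                     time = t0, replicate_index = 1,
                     stringsAsFactors = FALSE)
  # candidates are the windows starting within +/-20 min: low, low, moderate
  resp <- classify_meal_response(labels, meal)
  expect_equal(resp$class, "moderate")

  # order of the label rows must not matter
  resp2 <- classify_meal_response(labels[sample(5), ], meal)
  expect_equal(resp2$class, "moderate")

  meal_na <- transform(meal, time = as.POSIXct(NA))
  expect_true(is.na(classify_meal_response(labels, meal_na)$class))

  far <- transform(meal, time = t0 + 6 * 3600)
  expect_true(is.na(classify_meal_response(labels, far)$class))
})

test_that("meal-severity association matches the chi-squared formula", {
  # toy 3x3 contingency built from explicit responses
  counts <- matrix(c(6, 2, 2, 3, 4, 3, 1, 2, 7), nrow = 3, byrow = TRUE,
                   dimnames = list(c("bread_pb", "protein_bar",
                                     "cornflakes"),
                                   c("low", "moderate", "severe")))
  responses <- do.call(rbind, lapply(rownames(counts), function(mt) {
    do.call(rbind, lapply(colnames(counts), function(cl) {
      if (counts[mt, cl] == 0) return(NULL)
      data.frame(meal_type = mt, class = rep(cl, counts[mt, cl]),
                 stringsAsFactors = FALSE)
    }))
  }))
  res <- meal_severity_association(responses)
  O <- unclass(res$table)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(unname(res$obs_exp_ratio), unname(O / E))

  # uniform responses carry no association signal
  unif <- expand.grid(meal_type = rownames(counts),
                      class = colnames(counts),
                      rep = 1:4, stringsAsFactors = FALSE)
  resu <- meal_severity_association(unif)
  expect_gt(resu$p_value, 0.99)
  expect_equal(resu$statistic, 0, tolerance = 1e-12)
})

test_that("subject summaries combine fractions, glucotype, and ranges", {
  labels <- data.frame(
    subject_id = rep(c("a", "b"), each = 4),
    class = c("low", "low", "moderate", "low",
              "severe", "severe", "moderate", "low"),
    stringsAsFactors = FALSE)
  t0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
  series <- list(a = cgm_series("a", t0 + (0:9) * 300, rep(100, 10)),
                 b = cgm_series("b", t0 + (0:9) * 300,
                                c(rep(150, 5), rep(210, 5))))
  s <- glucotype_summary(labels, series)
  expect_equal(s$glucotype, c("low", "severe"))
  expect_equal(s$frac_low + s$frac_moderate + s$frac_severe, c(1, 1))
  expect_equal(s$frac_prediabetic_range, c(0, 0.5))
  expect_equal(s$frac_diabetic_range, c(0, 0.5))
})
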