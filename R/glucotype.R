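.class_levels <- c("low", "moderate", "severe")

#' Fraction of a subject's windows in each glycemic class
#'
#' @param classes Character vector of window class labels for one subject.
#' @param levels Class levels in ascending severity.
#' @return Named numeric vector of fractions summing to 1.
#' @export
class_fractions <- function(classes, levels = .class_levels) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) stop("no labeled windows", call. = FALSE)
  tab <- table(factor(classes, levels = levels))
  setNames(as.numeric(tab) / length(classes), levels)
}

#' Assign a subject's glucotype from class-time fractions
#'
#' The glucotype is the class with the largest fraction; ties break toward
#' the more severe class.
#'
#' @param fractions Named fractions as from [class_fractions()].
#' @return A class name.
#' @export
assign_glucotype <- function(fractions) {
  lev <- names(fractions)
  best <- which(fractions >= max(fractions) - 1e-12)
  lev[max(best)]  # levels ascend in severity, so max index is most severe
}

#' ADA-threshold diagnosis from clinical measures
#'
#' Diabetes: HbA1c >= 6.5%, fasting glucose >= 126 mg/dL, or 2-h OGTT
#' glucose >= 200 mg/dL. Prediabetes: HbA1c in (5.7, 6.5), fasting glucose
#' 100-125 mg/dL, or 2-h OGTT 140-199 mg/dL. Otherwise normoglycemic.
#' Missing measures are skipped; all three missing is an error.
#'
#' @param hba1c HbA1c in percent, or `NA`.
#' @param fbg Fasting blood glucose in mg/dL, or `NA`.
#' @param ogtt_2h 2-hour OGTT glucose in mg/dL, or `NA`.
#' @return One of `"normoglycemic"`, `"prediabetic"`, `"diabetic"`.
#' @export
ada_diagnosis <- function(hba1c = NA, fbg = NA, ogtt_2h = NA) {
  if (is.na(hba1c) && is.na(fbg) && is.na(ogtt_2h)) {
    stop("all diagnostic measures missing", call. = FALSE)
  }
  dia <- isTRUE(hba1c >= 6.5) || isTRUE(fbg >= 126) || isTRUE(ogtt_2h >= 200)
  if (dia) return("diabetic")
  pre <- isTRUE(hba1c > 5.7 & hba1c < 6.5) ||
    isTRUE(fbg >= 100 & fbg <= 125) ||
    isTRUE(ogtt_2h >= 140 & ogtt_2h <= 199)
  if (pre) return("prediabetic")
  "normoglycemic"
}

#' Fraction of CGM readings in prediabetic and diabetic glycemic ranges
#'
#' Prediabetic range: glucose in (140, 200]; diabetic range: above 200
#' mg/dL. Fractions are over all non-missing readings, so together with
#' the normal-range fraction they sum to 1.
#'
#' @param series A [cgm_series] (or numeric vector of mg/dL readings).
#' @return Named vector `frac_prediabetic`, `frac_diabetic`.
#' @export
time_in_ranges <- function(series) {
  g <- if (inherits(series, "cgm_series")) series$glucose else series
  g <- g[!is.na(g)]
  if (!length(g)) stop("no readings", call. = FALSE)
  c(frac_prediabetic = mean(g > 140 & g <= 200),
    frac_diabetic = mean(g > 200))
}

#' Subject-level glucotype summary
#'
#' @param labels Data frame as returned by [classify_windows()] (or with
#'   columns `subject_id`, `class`).
#' @param series_list Optional named list of [cgm_series] to add
#'   time-in-range fractions.
#' @return Data frame with one row per subject: class fractions,
#'   glucotype, and (when series are given) range fractions.
#' @export
glucotype_summary <- function(labels, series_list = NULL) {
  out <- do.call(rbind, lapply(split(labels, labels$subject_id), function(d) {
    f <- class_fractions(d$class)
    data.frame(subject_id = d$subject_id[1],
               frac_low = f["low"], frac_moderate = f["moderate"],
               frac_severe = f["severe"],
               glucotype = assign_glucotype(f),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(series_list)) {
    tir <- t(vapply(out$subject_id, function(id) {
      if (is.null(series_list[[id]])) c(NA_real_, NA_real_)
      else time_in_ranges(series_list[[id]])
    }, numeric(2)))
    out$frac_prediabetic_range <- tir[, 1]
    out$frac_diabetic_range <- tir[, 2]
  }
  out
}

#' Classify a standardized-meal response
#'
#' Candidate windows are those starting within 20 minutes of the annotated
#' meal time (inclusive on both sides); the response class is the most
#' severe class among them. Meals with no candidate window (or no
#' timestamp) are unclassifiable.
#'
#' @param labels Window labels for the subject's entire profile (data
#'   frame with `subject_id`, `start_time`, `class`).
#' @param meal One row of a meal table (`subject_id`, `meal_type`, `time`,
#'   `replicate_index`).
#' @param margin_min Half-width (minutes) of the candidate interval.
#' @return Data frame row with `subject_id`, `meal_type`,
#'   `replicate_index`, `class` (`NA` if unclassifiable).
#' @export
classify_meal_response <- function(labels, meal, margin_min = 20) {
  cls <- NA_character_
  if (!is.na(meal$time)) {
    sub <- labels[labels$subject_id == meal$subject_id, , drop = FALSE]
    if (nrow(sub)) {
      st <- .parse_time(sub$start_time)
      off <- abs(as.numeric(difftime(st, meal$time, units = "mins")))
      cand <- sub$class[off <= margin_min & !is.na(sub$class)]
      if (length(cand)) {
        rank <- match(cand, .class_levels)
        cls <- .class_levels[max(rank)]
      }
    }
  }
  data.frame(subject_id = meal$subject_id, meal_type = meal$meal_type,
             replicate_index = meal$replicate_index, class = cls,
             stringsAsFactors = FALSE)
}

#' Meal-type by response-severity association
#'
#' Contingency table of response classes per meal type with a chi-squared
#' test and observed/expected ratios.
#'
#' @param responses Data frame with `meal_type` and `class` (NA rows
#'   dropped).
#' @return List with `table`, `statistic`, `p_value`, `obs_exp_ratio`.
#' @export
meal_severity_association <- function(responses) {
  resp <- responses[!is.na(responses$class), , drop = FALSE]
  if (length(unique(resp$meal_type)) < 2 || length(unique(resp$class)) < 2) {
    stop("need at least 2 meal types and 2 classes", call. = FALSE)
  }
  tab <- table(meal = resp$meal_type,
               class = factor(resp$class, levels = .class_levels))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab))
  list(table = tab, statistic = unname(ct$statistic),
       p_value = ct$p.value, obs_exp_ratio = unclass(tab) / expected)
}
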