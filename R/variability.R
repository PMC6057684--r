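#' Descriptive glycemic statistics for a uniform-grid trace
#'
#' Rates are first differences divided by the sampling interval; the mean
#' rate uses absolute differences. Distance traveled is the total absolute
#' glucose change. Threshold counts are upward crossings (entries into the
#' range above 140 and above 200 mg/dL), not sample counts.
#'
#' @param values Glucose values in mg/dL, no missing entries.
#' @param interval_min Sampling interval in minutes.
#' @return Named list: `mean`, `min`, `max`, `sd`, `iqr`, `median`, `q25`,
#'   `q75` (mg/dL); `mean_rate`, `max_rate` (mg/dL per minute);
#'   `distance_traveled` (mg/dL); `cv`; `n_above_140`, `n_above_200`
#'   (upward crossings); `frac_below_80`, `frac_above_130`.
#' @export
basic_stats <- function(values, interval_min = 5) {
  if (length(values) < 2) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(values)) stop("missing values in input", call. = FALSE)
  dg <- diff(values)
  qs <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  crossings <- function(th) sum(values[-1] > th & values[-length(values)] <= th)
  list(mean = mean(values), min = min(values), max = max(values),
       sd = sd(values), iqr = qs[3] - qs[1], median = qs[2],
       q25 = qs[1], q75 = qs[3],
       mean_rate = mean(abs(dg)) / interval_min,
       max_rate = max(abs(dg)) / interval_min,
       distance_traveled = sum(abs(dg)),
       cv = sd(values) / mean(values),
       n_above_140 = crossings(140), n_above_200 = crossings(200),
       frac_below_80 = mean(values < 80),
       frac_above_130 = mean(values > 130))
}

# turning points of a vector: indices where the first difference changes
# sign, with flat runs collapsed to their midpoint; endpoints included
.turning_points <- function(x) {
  n <- length(x)
  if (n < 3) return(c(1L, n))
  d <- diff(x)
  s <- sign(d)
  # carry the last nonzero slope through flat runs
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  tp <- which(diff(s) != 0) + 1L
  unique(c(1L, tp, n))
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Turning-point elimination: the trace is smoothed to locate candidate
#' peaks and nadirs, then turning points whose excursions on both sides
#' fall below one standard deviation of the whole trace are iteratively
#' deleted (smallest first, re-merging same-direction extrema) until all
#' retained excursions reach 1 SD. Amplitudes are taken from the original
#' values at the retained turning points. MAGE is the mean amplitude over
#' all qualifying excursions; ascending-only and descending-only means are
#' reported alongside.
#'
#' @param values Glucose values in mg/dL, no missing entries.
#' @param smooth Smooth before locating turning points?
#' @param smooth_window,smooth_order Savitzky-Golay parameters.
#' @param sd_threshold Multiple of the trace SD an excursion must reach.
#' @return List `mage` (mean of all qualifying excursions),
#'   `mage_ascending`, `mage_descending`, `n_excursions`, `sd_used`;
#'   `mage = 0` when no excursion qualifies.
#' @export
mage <- function(values, smooth = TRUE, smooth_window = 5, smooth_order = 3,
                 sd_threshold = 1) {
  if (anyNA(values)) stop("missing values in input", call. = FALSE)
  zero <- list(mage = 0, mage_ascending = NA_real_,
               mage_descending = NA_real_, n_excursions = 0L,
               sd_used = sd(values))
  if (length(values) < 3) return(zero)
  thr <- sd_threshold * sd(values)
  if (!is.finite(thr) || thr == 0) return(zero)
  ref <- if (smooth && length(values) >= smooth_window) {
    sg_smooth(values, smooth_window, smooth_order)
  } else values
  tp <- .turning_points(ref)
  # iterative elimination on the original values at the candidate points
  repeat {
    if (length(tp) < 2) break
    v <- values[tp]
    # merge consecutive same-direction segments (keep the more extreme end)
    if (length(tp) > 2) {
      d <- diff(v)
      same <- which(d[-1] * d[-length(d)] > 0)
      if (length(same)) {
        tp <- tp[-(same[1] + 1L)]
        next
      }
    }
    v <- values[tp]
    amp <- abs(diff(v))
    if (!length(amp)) break
    # interior points must clear the threshold on both sides; endpoints on
    # their single side
    side_ok <- c(amp[1] >= thr,
                 if (length(amp) > 1)
                   pmin(amp[-length(amp)], amp[-1]) >= thr else NULL,
                 amp[length(amp)] >= thr)
    if (all(side_ok)) break
    # delete the turning point with the weakest maximal excursion
    weak <- which(!side_ok)
    score <- vapply(weak, function(i) {
      sides <- c(if (i > 1) amp[i - 1], if (i <= length(amp)) amp[i])
      max(sides)
    }, numeric(1))
    tp <- tp[-weak[which.min(score)]]
  }
  if (length(tp) < 2) return(zero)
  v <- values[tp]
  exc <- diff(v)
  qual <- abs(exc) >= thr
  if (!any(qual)) return(zero)
  asc <- exc[qual & exc > 0]; desc <- exc[qual & exc < 0]
  list(mage = mean(abs(exc[qual])),
       mage_ascending = if (length(asc)) mean(asc) else NA_real_,
       mage_descending = if (length(desc)) mean(abs(desc)) else NA_real_,
       n_excursions = sum(qual), sd_used = sd(values))
}

#' J index
#'
#' Composite glycemia score `0.001 * (mean + sd)^2` with mean and SD in
#' mg/dL.
#'
#' @param mean Mean glucose (mg/dL), positive.
#' @param sd Standard deviation (mg/dL).
#' @return Unitless scalar.
#' @export
j_index <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  0.001 * (mean + sd)^2
}

#' Mean of daily differences (MODD) anchored at 06:00
#'
#' Mean absolute difference between the glucose values nearest 06:00
#' (within `tolerance_min`) on consecutive calendar days. Days without a
#' usable 06:00 sample are skipped; fewer than two usable anchors yields
#' `NA`.
#'
#' @param series A [cgm_series].
#' @param anchor_hour Hour of day of the anchor (default 6).
#' @param tolerance_min Maximal distance (minutes) from the anchor.
#' @return mg/dL scalar, or `NA_real_` when undefined.
#' @export
modd <- function(series, anchor_hour = 6, tolerance_min = 15) {
  stopifnot(inherits(series, "cgm_series"))
  ok <- !is.na(series$glucose)
  t <- series$time[ok]; g <- series$glucose[ok]
  if (!length(t)) return(NA_real_)
  days <- sort(unique(as.Date(t, tz = "UTC")))
  anchors <- vapply(days, function(d) {
    target <- as.POSIXct(paste(d, sprintf("%02d:00:00", anchor_hour)),
                         tz = "UTC")
    off <- abs(as.numeric(difftime(t, target, units = "mins")))
    i <- which.min(off)
    if (off[i] <= tolerance_min) g[i] else NA_real_
  }, numeric(1))
  pairs <- cbind(anchors[-length(anchors)], anchors[-1])
  usable <- complete.cases(pairs) &
    diff(as.numeric(days)) == 1  # consecutive calendar days only
  if (!any(usable)) return(NA_real_)
  mean(abs(pairs[usable, 2] - pairs[usable, 1]))
}

#' Variability report for a window or trace
#'
#' Bundles [basic_stats()], [mage()], [j_index()] and the coefficient of
#' variation into one named list.
#'
#' @param values Glucose values in mg/dL.
#' @param interval_min Sampling interval in minutes.
#' @param ... Passed to [mage()].
#' @return Named list of metrics.
#' @export
variability_report <- function(values, interval_min = 5, ...) {
  bs <- basic_stats(values, interval_min)
  mg <- mage(values, ...)
  c(bs, list(mage = mg$mage, j_index = j_index(bs$mean, bs$sd)))
}

#' Per-class means of the variability metrics, with rank tests
#'
#' Computes every variability metric per labeled window, averages within
#' class, and tests each metric across classes with the Kruskal-Wallis
#' rank-sum test. Classes with fewer than 2 windows are excluded from the
#' test and flagged.
#'
#' @param windows A labeled `glucose_windows` set (windows carry `$class`).
#' @param interval_min Sampling interval in minutes.
#' @return List with `means` (class x metric data frame), `tests` (metric,
#'   statistic, p_value), and `excluded_classes`.
#' @export
class_metric_table <- function(windows, interval_min = 5) {
  cls <- vapply(windows, function(w)
    if (is.null(w$class)) NA_character_ else w$class, character(1))
  stopifnot(!anyNA(cls))
  per <- lapply(windows, function(w)
    unlist(variability_report(w$raw, interval_min)))
  M <- do.call(rbind, per)
  sizes <- table(cls)
  if (length(sizes) < 2) stop("need at least 2 populated classes",
                              call. = FALSE)
  excluded <- names(sizes)[sizes < 2]
  keep <- !(cls %in% excluded)
  means <- aggregate(M, by = list(class = cls), FUN = mean)
  tests <- do.call(rbind, lapply(colnames(M), function(metric) {
    vals <- M[keep, metric]
    if (length(unique(vals)) < 2) {
      # a metric constant across all windows carries no class signal
      return(data.frame(metric = metric, statistic = 0, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    kt <- kruskal.test(vals, factor(cls[keep]))
    data.frame(metric = metric, statistic = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  }))
  list(means = means, tests = tests, excluded_classes = excluded)
}
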