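#' Simulation configuration for synthetic CGM cohorts
#'
#' The generator is phenomenological: glucose is a baseline plus a
#' circadian sinusoid, a train of log-normal-shaped glycemic excursions,
#' and AR(1) noise, clipped to the device reporting range of 40-400 mg/dL,
#' sampled every 5 minutes, with sensor dropouts inserted as gaps.
#'
#' The three variability regimes are graded along the axes that
#' distinguish glycemic signatures after per-window z-normalization:
#' excursion amplitude, excursion frequency and sharpness, short-term
#' fluctuation level, and baseline glucose. `low` subjects show gentle,
#' slow, smooth excursions around a low baseline; `severe` subjects show
#' tall, sharp, frequent spikes with rough short-term dynamics around a
#' high baseline; `moderate` sits between. Every 2.5-hour window of a
#' trace therefore carries its subject's regime texture, which is what
#' makes the regimes recoverable at the window level.
#'
#' @param n_subjects Number of subjects.
#' @param days Recording days per subject.
#' @param baseline Regime-named baseline glucose (mg/dL).
#' @param circadian_amp Circadian sinusoid amplitude (mg/dL).
#' @param pulse_amp Regime-named mean excursion amplitude (mg/dL).
#' @param pulse_period_min Regime-named mean spacing between excursion
#'   onsets (minutes; onsets are jittered by +/-20% of the spacing).
#' @param pulse_peak_min Regime-named time-to-peak of an excursion
#'   (minutes; smaller = sharper rise).
#' @param pulse_width Regime-named log-sd of the log-normal excursion
#'   shape (larger = slower decay).
#' @param noise_sd Regime-named marginal SD of the AR(1) short-term
#'   fluctuation (mg/dL).
#' @param noise_rho Lag-1 autocorrelation of the fluctuation process.
#' @param gap_rate Expected sensor gaps per day.
#' @param gap_mean_min Mean gap length (minutes, geometric on the grid).
#' @param interval_min Sampling interval (minutes).
#' @param regimes Regime per subject (recycled); `NULL` cycles
#'   low/moderate/severe.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12, days = 7,
                       baseline = c(low = 80, moderate = 95, severe = 115),
                       circadian_amp = 5,
                       pulse_amp = c(low = 20, moderate = 50, severe = 110),
                       pulse_period_min = c(low = 180, moderate = 80,
                                            severe = 42),
                       pulse_peak_min = c(low = 60, moderate = 25,
                                          severe = 11),
                       pulse_width = c(low = 0.60, moderate = 0.50,
                                       severe = 0.45),
                       noise_sd = c(low = 1, moderate = 5, severe = 7),
                       noise_rho = 0.7,
                       gap_rate = 0.5, gap_mean_min = 20,
                       interval_min = 5, regimes = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(pulse_amp >= 0), all(baseline > 0), all(noise_sd >= 0),
            noise_rho >= 0, noise_rho < 1, days > 0)
  if (is.null(regimes)) {
    regimes <- rep(c("low", "moderate", "severe"), length.out = n_subjects)
  }
  stopifnot(all(regimes %in% c("low", "moderate", "severe")))
  cfg <- list(n_subjects = n_subjects, days = days, baseline = baseline,
              circadian_amp = circadian_amp, pulse_amp = pulse_amp,
              pulse_period_min = pulse_period_min,
              pulse_peak_min = pulse_peak_min, pulse_width = pulse_width,
              noise_sd = noise_sd, noise_rho = noise_rho,
              gap_rate = gap_rate, gap_mean_min = gap_mean_min,
              interval_min = interval_min,
              regimes = rep(regimes, length.out = n_subjects),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# log-normal-shaped excursion: unit peak at t = peak_min after onset
.pulse_shape <- function(dt_min, peak_min, width) {
  out <- numeric(length(dt_min))
  pos <- dt_min > 0
  out[pos] <- exp(-(log(dt_min[pos] / peak_min))^2 / (2 * width^2))
  out
}

.regime_par <- function(x, regime) {
  if (length(x) == 1 && is.null(names(x))) x else x[[regime]]
}

#' Simulate one subject's CGM trace
#'
#' @param cfg A [sim_config()].
#' @param regime `"low"`, `"moderate"`, or `"severe"`.
#' @param seed Integer seed for this subject.
#' @param subject_id Subject identifier.
#' @param start Start timestamp.
#' @return A [cgm_series] with attribute `regime`.
#' @export
simulate_subject <- function(cfg, regime, seed,
                             subject_id = "sim01",
                             start = as.POSIXct("2023-01-02 00:00:00",
                                                tz = "UTC")) {
  stopifnot(inherits(cfg, "sim_config"),
            regime %in% c("low", "moderate", "severe"))
  set.seed(seed)
  step <- cfg$interval_min
  n <- as.integer(cfg$days * 24 * 60 / step)
  t_min <- (seq_len(n) - 1) * step
  g <- rep(.regime_par(cfg$baseline, regime), n) +
    cfg$circadian_amp * sin(2 * pi * (t_min / 60 - 8) / 24)
  per <- .regime_par(cfg$pulse_period_min, regime)
  peak <- .regime_par(cfg$pulse_peak_min, regime)
  width <- .regime_par(cfg$pulse_width, regime)
  amp <- .regime_par(cfg$pulse_amp, regime)
  onsets <- seq(-per, cfg$days * 24 * 60 + per, by = per)
  onsets <- onsets + runif(length(onsets), -0.2 * per, 0.2 * per)
  amps <- amp * exp(rnorm(length(onsets), 0, 0.15))
  for (j in seq_along(onsets)) {
    g <- g + amps[j] * .pulse_shape(t_min - onsets[j], peak, width)
  }
  nsd <- .regime_par(cfg$noise_sd, regime)
  if (nsd > 0) {
    e <- numeric(n)
    innov_sd <- nsd * sqrt(1 - cfg$noise_rho^2)
    e[1] <- rnorm(1, 0, nsd)
    for (i in 2:n) e[i] <- cfg$noise_rho * e[i - 1] + rnorm(1, 0, innov_sd)
    g <- g + e
  }
  g <- pmin(pmax(g, 40), 400)
  # sensor gaps: Poisson count per recording, geometric lengths
  keep <- rep(TRUE, n)
  n_gaps <- stats::rpois(1, cfg$gap_rate * cfg$days)
  if (n_gaps > 0) {
    for (gi in seq_len(n_gaps)) {
      len <- 1 + stats::rgeom(1, min(1, step / cfg$gap_mean_min))
      at <- sample.int(max(1, n - len), 1)
      keep[at:min(n, at + len - 1)] <- FALSE
    }
    keep[1] <- TRUE  # keep the series anchor
  }
  ser <- cgm_series(subject_id, start + t_min[keep] * 60, g[keep],
                    nominal_interval_min = step)
  attr(ser, "regime") <- regime
  ser
}

#' Simulate a full cohort with clinical records and meal events
#'
#' Subjects cycle through the configured regimes; clinical measures are
#' drawn so that fasting glucose, HbA1c and 2-h OGTT increase with regime
#' severity (exercising diagnosis-by-glucotype cross-tabulations), and
#' each subject logs each standardized meal twice on separate days.
#'
#' @param cfg A [sim_config()].
#' @return List with `series` (named list of [cgm_series]), `regimes`
#'   (named character), `clinical` (data frame), `meals` (data frame).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  ids <- sprintf("sim%02d", seq_len(cfg$n_subjects))
  regimes <- setNames(cfg$regimes, ids)
  series <- list()
  for (i in seq_len(cfg$n_subjects)) {
    series[[ids[i]]] <- simulate_subject(
      cfg, regimes[[i]], seed = cfg$seed + 1000L * i, subject_id = ids[i])
  }
  set.seed(cfg$seed + 7L)
  shift <- c(low = 0, moderate = 12, severe = 30)[regimes]
  clinical <- data.frame(
    subject_id = ids,
    age = round(runif(cfg$n_subjects, 30, 70)),
    bmi = round(rnorm(cfg$n_subjects, 27, 3), 1),
    hba1c = round(5.2 + shift / 60 + rnorm(cfg$n_subjects, 0, 0.15), 2),
    fbg = round(88 + shift + rnorm(cfg$n_subjects, 0, 5), 1),
    ogtt_2h = round(110 + 2.2 * shift + rnorm(cfg$n_subjects, 0, 12), 1),
    sspg = round(ifelse(runif(cfg$n_subjects) < 0.2, NA,
                        100 + 2 * shift + rnorm(cfg$n_subjects, 0, 20)), 1),
    stringsAsFactors = FALSE)
  meal_types <- c("bread_pb", "protein_bar", "cornflakes")
  n_days <- max(floor(cfg$days), 1)
  meals <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(i) {
    days <- (sample.int(max(n_days, 6), 6, replace = n_days < 6) - 1) %%
      n_days
    data.frame(subject_id = ids[i],
               meal_type = rep(meal_types, each = 2),
               time = series[[ids[i]]]$time[1] +
                 days * 24 * 3600 + 8 * 3600 +
                 round(runif(6, -20, 20)) * 60,
               replicate_index = rep(1:2, 3),
               stringsAsFactors = FALSE)
  }))
  list(series = series, regimes = regimes, clinical = clinical,
       meals = meals)
}

#' Write a simulated cohort in the study's TSV schemas
#'
#' Emits `cgm.tsv` (DisplayTime / GlucoseValue / subjectId / InternalTime),
#' `clinical.tsv`, and `meals.tsv` (Meal / userID / time / GlucoseValue)
#' under `dir`, readable by [read_cgm()], [read_clinical()] and
#' [read_meals()].
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cgm <- do.call(rbind, lapply(cohort$series, function(s) {
    data.frame(DisplayTime = .format_time(s$time),
               GlucoseValue = s$glucose,
               subjectId = attr(s, "subject_id"),
               InternalTime = .format_time(s$time),
               stringsAsFactors = FALSE)
  }))
  write.table(cgm, file.path(dir, "cgm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cl <- cohort$clinical
  names(cl)[names(cl) == "subject_id"] <- "subjectId"
  write.table(cl, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  meals <- data.frame(Meal = cohort$meals$meal_type,
                      userID = cohort$meals$subject_id,
                      time = .format_time(cohort$meals$time),
                      GlucoseValue = NA, stringsAsFactors = FALSE)
  write.table(meals, file.path(dir, "meals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}
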