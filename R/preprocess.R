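#' Windowing configuration
#'
#' Parameters controlling how a CGM trace is cut into fixed-duration
#' windows. The defaults are the operating point of the glycemic-signature
#' pipeline: 2.5-hour windows with 75% overlap on a 5-minute grid, linear
#' imputation of gaps strictly shorter than 15 minutes, and Savitzky-Golay
#' smoothing of order 3 over 5 samples (25 minutes).
#'
#' The 75% overlap of a 150-minute window implies a 37.5-minute shift,
#' which is off the 5-minute sampling grid. By default cumulative window
#' starts are snapped to the grid (`round(i * 37.5 / 5) * 5`, i.e.
#' alternating 40/35-minute shifts), preserving the stated overlap on
#' average. Set `shift_min` to force a fixed on-grid shift instead.
#'
#' @param window_hours Window duration in hours.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @param interval_min Sampling interval in minutes.
#' @param max_gap_min Gaps strictly shorter than this (minutes) are linearly
#'   imputed; longer gaps exclude the windows covering them.
#' @param smooth_window Savitzky-Golay filter length in samples (odd).
#' @param smooth_order Savitzky-Golay polynomial order.
#' @param shift_min Optional fixed shift in minutes overriding the
#'   overlap-derived shift.
#' @return A list of class `windowing_config`.
#' @export
windowing_config <- function(window_hours = 2.5, overlap_fraction = 0.75,
                             interval_min = 5, max_gap_min = 15,
                             smooth_window = 5, smooth_order = 3,
                             shift_min = NULL) {
  stopifnot(window_hours > 0, overlap_fraction >= 0, overlap_fraction < 1,
            interval_min > 0, smooth_window %% 2 == 1,
            smooth_order < smooth_window)
  cfg <- list(window_hours = window_hours,
              overlap_fraction = overlap_fraction,
              interval_min = interval_min,
              max_gap_min = max_gap_min,
              smooth_window = smooth_window,
              smooth_order = smooth_order,
              shift_min = shift_min)
  class(cfg) <- "windowing_config"
  cfg
}

.window_m <- function(cfg) as.integer(round(cfg$window_hours * 60 / cfg$interval_min))

.window_starts_min <- function(cfg, total_min, m) {
  span <- (m - 1L) * cfg$interval_min  # first-to-last sample span
  if (!is.null(cfg$shift_min)) {
    starts <- seq(0, total_min, by = cfg$shift_min)
  } else {
    shift <- cfg$window_hours * 60 * (1 - cfg$overlap_fraction)
    i <- 0:ceiling(total_min / max(shift, cfg$interval_min))
    starts <- round(i * shift / cfg$interval_min) * cfg$interval_min
  }
  unique(starts[starts + span <= total_min])
}

new_window <- function(subject_id, start_time, raw, interval_min = 5,
                       cfg = NULL) {
  w <- list(subject_id = as.character(subject_id), start_time = start_time,
            raw = as.numeric(raw), norm = NULL, degenerate = FALSE,
            interval_min = interval_min,
            window_hours = if (is.null(cfg)) length(raw) * interval_min / 60
                           else cfg$window_hours,
            shift_min = if (is.null(cfg) || is.null(cfg$shift_min))
                          NA_real_ else cfg$shift_min,
            class = NULL)
  class(w) <- "glucose_window"
  w
}

new_window_set <- function(windows, m, interval_min = 5) {
  structure(windows, m = m, interval_min = interval_min,
            class = "glucose_windows")
}

#' @export
print.glucose_windows <- function(x, ...) {
  cat(sprintf("<glucose_windows> %d windows of %d samples from %d subject(s)\n",
              length(x), attr(x, "m"),
              length(unique(vapply(x, function(w) w$subject_id, character(1))))))
  invisible(x)
}

#' @export
`[.glucose_windows` <- function(x, i) {
  new_window_set(unclass(x)[i], m = attr(x, "m"),
                 interval_min = attr(x, "interval_min"))
}

#' Window identifier
#'
#' Built as subject id, window size in hours, shift in minutes, and window
#' start time, separated by underscores.
#'
#' @param w A `glucose_window`.
#' @return Character scalar.
#' @export
window_id <- function(w) {
  shift <- if (is.na(w$shift_min)) "na" else format(w$shift_min)
  paste(w$subject_id, format(w$window_hours), shift,
        .format_time(w$start_time), sep = "_")
}

#' Resample a CGM series to a uniform grid and impute short gaps
#'
#' Snaps samples to the nominal grid anchored at the first sample, fills
#' interior gaps strictly shorter than `max_gap_min` by linear
#' interpolation (marking filled samples as imputed), and leaves longer
#' gaps missing so downstream windowing can exclude them.
#'
#' @param series A [cgm_series].
#' @param max_gap_min Strict upper bound (minutes) on imputable gap length.
#' @param interval_min Grid interval in minutes.
#' @return A `cgm_series` on the uniform grid; `glucose` is `NA` inside
#'   unfilled gaps and `imputed` flags interpolated samples.
#' @export
impute_gaps <- function(series, max_gap_min = 15, interval_min = 5) {
  stopifnot(inherits(series, "cgm_series"))
  if (nrow(series) < 2) stop("series has fewer than 2 samples", call. = FALSE)
  if (max_gap_min < interval_min) stop("max_gap_min below sampling interval",
                                       call. = FALSE)
  t0 <- series$time[1]
  rel <- as.numeric(difftime(series$time, t0, units = "mins"))
  slot <- round(rel / interval_min)
  keep <- !duplicated(slot)
  slot <- slot[keep]; g <- series$glucose[keep]
  grid <- 0:slot[length(slot)]
  glucose <- rep(NA_real_, length(grid))
  glucose[slot + 1] <- g
  imputed <- rep(FALSE, length(grid))
  # fill runs of NA whose enclosing observed-to-observed gap is < max_gap_min
  obs <- which(!is.na(glucose))
  if (length(obs) > 1) {
    for (i in seq_len(length(obs) - 1)) {
      a <- obs[i]; b <- obs[i + 1]
      gap_min <- (grid[b] - grid[a]) * interval_min
      if (b - a > 1 && gap_min < max_gap_min) {
        idx <- (a + 1):(b - 1)
        glucose[idx] <- glucose[a] +
          (glucose[b] - glucose[a]) * (idx - a) / (b - a)
        imputed[idx] <- TRUE
      }
    }
  }
  out <- data.frame(time = t0 + grid * interval_min * 60,
                    glucose = glucose, imputed = imputed)
  attr(out, "subject_id") <- attr(series, "subject_id")
  attr(out, "interval_min") <- interval_min
  class(out) <- c("cgm_series", "data.frame")
  out
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial smoothing of a complete glucose vector. Constant and
#' linear signals pass through unchanged; isolated spikes are attenuated.
#'
#' @param values Numeric vector without missing values.
#' @param window Filter length in samples (odd).
#' @param order Polynomial order (`< window`).
#' @return Smoothed vector of the same length.
#' @export
sg_smooth <- function(values, window = 5, order = 3) {
  if (anyNA(values)) stop("missing values in input", call. = FALSE)
  if (length(values) < window) {
    stop("vector shorter than smoothing window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(values, p = order, n = window))
}

#' Z-score normalize a window
#'
#' Centers and scales `raw` by its own mean and sample (n-1) standard
#' deviation. A zero-variance window is flagged degenerate (its `norm`
#' stays `NULL`) rather than erroring; degenerate windows are excluded from
#' distance computation upstream.
#'
#' @param w A `glucose_window`.
#' @return The window with `norm` filled in (or `degenerate = TRUE`).
#' @export
znormalize <- function(w) {
  s <- sd(w$raw)
  if (!is.finite(s) || s == 0) {
    w$degenerate <- TRUE
  } else {
    w$norm <- (w$raw - mean(w$raw)) / s
  }
  w
}

#' Segment a gridded CGM series into sliding windows
#'
#' Cuts a uniform-grid series (see [impute_gaps()]) into fixed-duration
#' windows advancing by the overlap-derived shift. Windows containing any
#' missing sample are dropped; each retained window is smoothed and
#' z-normalized, and degenerate (flat) windows are discarded.
#'
#' @param series A gridded `cgm_series`.
#' @param cfg A [windowing_config()].
#' @return A `glucose_windows` set (possibly empty).
#' @export
segment_windows <- function(series, cfg = windowing_config()) {
  stopifnot(inherits(series, "cgm_series"), inherits(cfg, "windowing_config"))
  m <- .window_m(cfg)
  n <- nrow(series)
  total_min <- (n - 1L) * cfg$interval_min
  if (n < m) return(new_window_set(list(), m = m,
                                   interval_min = cfg$interval_min))
  starts <- .window_starts_min(cfg, total_min, m)
  wins <- list()
  for (s in starts) {
    i0 <- as.integer(s / cfg$interval_min) + 1L
    raw <- series$glucose[i0:(i0 + m - 1L)]
    if (anyNA(raw)) next
    w <- new_window(attr(series, "subject_id"), series$time[i0], raw,
                    interval_min = cfg$interval_min, cfg = cfg)
    w$raw_smooth <- sg_smooth(raw, cfg$smooth_window, cfg$smooth_order)
    wsm <- w; wsm$raw <- w$raw_smooth
    wsm <- znormalize(wsm)
    w$norm <- wsm$norm
    w$degenerate <- wsm$degenerate
    if (!w$degenerate) wins[[length(wins) + 1L]] <- w
  }
  new_window_set(wins, m = m, interval_min = cfg$interval_min)
}

#' Equalize window counts across subjects
#'
#' Trims every subject to the first `N` windows in temporal order, where
#' `N` is the smallest per-subject window count, so each participant
#' contributes equal recording duration to the clustering.
#'
#' @param windows A `glucose_windows` set covering one or more subjects.
#' @return A trimmed `glucose_windows` set; subjects with zero windows are
#'   dropped with a warning before computing `N`.
#' @export
equalize_counts <- function(windows) {
  stopifnot(inherits(windows, "glucose_windows"))
  if (length(windows) == 0) stop("no windows to equalize", call. = FALSE)
  ids <- vapply(windows, function(w) w$subject_id, character(1))
  counts <- table(ids)
  n_min <- min(counts)
  keep <- unlist(lapply(split(seq_along(ids), ids), function(idx) {
    idx[order(vapply(unclass(windows)[idx],
                     function(w) as.numeric(w$start_time), numeric(1)))][seq_len(n_min)]
  }), use.names = FALSE)
  out <- windows[sort(keep)]
  attr(out, "n_per_subject") <- as.integer(n_min)
  out
}

#' Full preprocessing for a collection of series
#'
#' Imputation, segmentation and (optionally) count equalization for every
#' subject in one call.
#'
#' @param series_list A list of [cgm_series].
#' @param cfg A [windowing_config()].
#' @param equalize Trim all subjects to the minimum window count?
#' @return A `glucose_windows` set.
#' @export
preprocess_cohort <- function(series_list, cfg = windowing_config(),
                              equalize = TRUE) {
  all_wins <- list()
  empty <- character(0)
  for (ser in series_list) {
    grid <- impute_gaps(ser, max_gap_min = cfg$max_gap_min,
                        interval_min = cfg$interval_min)
    ws <- segment_windows(grid, cfg)
    if (length(ws) == 0) {
      empty <- c(empty, attr(ser, "subject_id"))
      next
    }
    all_wins <- c(all_wins, unclass(ws))
  }
  if (length(empty)) {
    warning("subject(s) with zero windows excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- new_window_set(all_wins, m = .window_m(cfg),
                        interval_min = cfg$interval_min)
  if (equalize && length(out)) out <- equalize_counts(out)
  out
}

.norm_matrix <- function(windows) {
  m <- attr(windows, "m")
  if (length(windows) == 0) return(matrix(numeric(0), 0, m))
  bad <- vapply(windows, function(w) w$degenerate || is.null(w$norm),
                logical(1))
  if (any(bad)) {
    stop("degenerate (flat) windows present; exclude them upstream",
         call. = FALSE)
  }
  t(vapply(windows, function(w) w$norm, numeric(m)))
}

.raw_matrix <- function(windows) {
  m <- attr(windows, "m")
  t(vapply(windows, function(w) w$raw, numeric(m)))
}
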