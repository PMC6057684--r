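#' @useDynLib glucotyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd median quantile kmeans kruskal.test chisq.test
#'   aggregate ave rnorm runif rpois rgeom complete.cases setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Timestamps are parsed timezone-naive; a fixed UTC representation keeps
# arithmetic stable regardless of the host locale.
.parse_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%S", "%m/%d/%Y %H:%M"))
  if (anyNA(out) && !all(is.na(x))) {
    stop("unparseable timestamp(s), e.g. '", x[which(is.na(out))[1]], "'",
         call. = FALSE)
  }
  out
}

.format_time <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop("empty file: ", path, call. = FALSE)
  }
  df
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Construct a CGM series
#'
#' A `cgm_series` holds one subject's timestamped interstitial glucose trace
#' in mg/dL, sorted by time with duplicate timestamps removed (first kept).
#'
#' @param subject_id Subject identifier (scalar character).
#' @param time Timestamps (`POSIXct` or parseable character), minute
#'   resolution.
#' @param glucose Glucose concentrations in mg/dL; must be positive and
#'   finite.
#' @param nominal_interval_min Nominal sampling interval in minutes
#'   (default 5).
#' @return An object of class `cgm_series`: a data frame with columns
#'   `time`, `glucose`, `imputed`, plus attributes `subject_id` and
#'   `interval_min`.
#' @export
cgm_series <- function(subject_id, time, glucose, nominal_interval_min = 5) {
  if (!is.numeric(glucose)) stop("glucose must be numeric", call. = FALSE)
  if (inherits(time, "POSIXct")) t <- time else t <- .parse_time(time)
  keep <- is.finite(glucose) & glucose > 0
  t <- t[keep]; glucose <- glucose[keep]
  if (length(t) < 1) stop("series has no valid samples", call. = FALSE)
  ord <- order(t)
  t <- t[ord]; glucose <- glucose[ord]
  dup <- duplicated(t)
  if (any(dup)) {
    t <- t[!dup]; glucose <- glucose[!dup]
  }
  out <- data.frame(time = t, glucose = glucose,
                    imputed = rep(FALSE, length(t)))
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "interval_min") <- nominal_interval_min
  class(out) <- c("cgm_series", "data.frame")
  out
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf("<cgm_series> subject %s: %d samples, %s .. %s\n",
              attr(x, "subject_id"), nrow(x),
              .format_time(x$time[1]), .format_time(x$time[nrow(x)])))
  invisible(x)
}

subject_id <- function(x) attr(x, "subject_id")

#' Read tab-delimited CGM recordings
#'
#' Parses a TSV with columns `DisplayTime`, `GlucoseValue`, `subjectId`
#' (and optionally `InternalTime`). `DisplayTime` is the analysis clock;
#' `InternalTime`, when present, is carried along but unused. Rows with
#' non-numeric or non-positive glucose are dropped with a message; duplicate
#' timestamps within a subject keep the first occurrence.
#'
#' @param path Path to the tab-delimited file.
#' @param interval_min Nominal sampling interval in minutes.
#' @return A named list of [cgm_series], one per distinct `subjectId`.
#' @export
read_cgm <- function(path, interval_min = 5) {
  df <- .read_tsv(path)
  .require_columns(df, c("DisplayTime", "GlucoseValue", "subjectId"), path)
  gl <- suppressWarnings(as.numeric(df$GlucoseValue))
  bad <- !is.finite(gl) | gl <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) with non-numeric or non-positive glucose dropped")
    df <- df[!bad, , drop = FALSE]
    gl <- gl[!bad]
  }
  if (nrow(df) == 0) stop("no valid CGM rows in ", path, call. = FALSE)
  ids <- as.character(df$subjectId)
  out <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    cgm_series(ids[idx[1]], df$DisplayTime[idx], gl[idx],
               nominal_interval_min = interval_min)
  })
  out[order(names(out))]
}

#' Read a clinical table
#'
#' One row per subject, keyed on a subject-id column. Recognized clinical
#' columns are coerced to numeric; empty cells become `NA` (explicitly
#' missing, never zero-filled). Unknown columns are preserved untouched.
#'
#' @param path Path to the tab-delimited clinical table.
#' @param id_col Name of the subject-id column (default `subjectId`).
#' @return A data frame of class `clinical_table`, one row per subject.
#' @export
read_clinical <- function(path, id_col = "subjectId") {
  df <- .read_tsv(path)
  .require_columns(df, id_col, path)
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate subject id(s) in clinical table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c("age", "bmi", "hba1c", "fbg", "ogtt_2h", "sspg", "fasting_insulin",
      "triglycerides", "hdl", "ldl"),
    names(df))
  for (cc in numeric_cols) {
    raw <- df[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    malformed <- which(!is.na(raw) & trimws(as.character(raw)) != "" &
                         is.na(val))
    if (length(malformed)) {
      stop("malformed numeric in column '", cc, "' at row ", malformed[1],
           call. = FALSE)
    }
    val[is.finite(val) & val <= 0] <- NA
    df[[cc]] <- val
  }
  names(df)[names(df) == id_col] <- "subject_id"
  df$subject_id <- ids
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read meal-event annotations
#'
#' Expects columns `Meal`, `userID`, `time`. Meal types must come from the
#' closed standardized-meal set.
#'
#' @param path Path to the tab-delimited meal file.
#' @param meal_types Allowed meal types.
#' @return Data frame with columns `subject_id`, `meal_type`, `time`,
#'   `replicate_index`.
#' @export
read_meals <- function(path,
                       meal_types = c("bread_pb", "protein_bar", "cornflakes")) {
  df <- .read_tsv(path)
  .require_columns(df, c("Meal", "userID", "time"), path)
  meal <- as.character(df$Meal)
  unknown <- setdiff(unique(meal), meal_types)
  if (length(unknown)) {
    stop("unknown meal type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(subject_id = as.character(df$userID),
                    meal_type = meal,
                    time = .parse_time(df$time),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$meal_type, out$time), , drop = FALSE]
  out$replicate_index <- stats::ave(seq_len(nrow(out)),
                                    out$subject_id, out$meal_type,
                                    FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Write and read labeled glucose windows
#'
#' Serializes a window set to a wide TSV: one row per window with subject id,
#' start time, optional class label, and the raw mg/dL values. The window id
#' encodes subject, window size in hours, shift in minutes, and start time.
#' `read_windows(write_windows(x))` reconstructs `x`.
#'
#' @param windows A `glucose_windows` object (see [segment_windows()]).
#' @param path Output path.
#' @return `write_windows` returns `path` invisibly; `read_windows` returns
#'   a `glucose_windows` object.
#' @export
write_windows <- function(windows, path) {
  stopifnot(inherits(windows, "glucose_windows"))
  m <- attr(windows, "m")
  n <- length(windows)
  mat <- if (n) t(vapply(windows, function(w) w$raw, numeric(m))) else
    matrix(numeric(0), 0, m)
  df <- data.frame(
    window_id = vapply(windows, window_id, character(1)),
    subject_id = vapply(windows, function(w) w$subject_id, character(1)),
    start_time = vapply(windows, function(w) .format_time(w$start_time),
                        character(1)),
    class = vapply(windows, function(w)
      if (is.null(w$class)) NA_character_ else w$class, character(1)),
    stringsAsFactors = FALSE)
  colnames(mat) <- paste0("g", seq_len(m))
  df <- cbind(df, as.data.frame(mat))
  ok <- tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write windows to '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_windows
#' @param interval_min Sampling interval in minutes of the stored windows.
#' @export
read_windows <- function(path, interval_min = 5) {
  df <- .read_tsv(path)
  .require_columns(df, c("window_id", "subject_id", "start_time"), path)
  gcols <- grep("^g[0-9]+$", names(df), value = TRUE)
  gcols <- gcols[order(as.integer(sub("^g", "", gcols)))]
  m <- length(gcols)
  wins <- lapply(seq_len(nrow(df)), function(i) {
    raw <- as.numeric(df[i, gcols])
    w <- new_window(df$subject_id[i], .parse_time(df$start_time[i]), raw,
                    interval_min = interval_min)
    cl <- df$class[i]
    if (!is.null(cl) && !is.na(cl) && nzchar(cl)) w$class <- cl
    w
  })
  new_window_set(wins, m = m, interval_min = interval_min)
}
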