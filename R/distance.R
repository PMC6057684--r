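.metric_code <- function(metric) {
  match(match.arg(metric, c("euclidean", "dtw", "cid", "cid_dtw")),
        c("euclidean", "dtw", "cid", "cid_dtw")) - 1L
}

.band_width <- function(m, band_fraction) {
  stopifnot(band_fraction > 0, band_fraction <= 1)
  as.integer(ceiling(band_fraction * m))
}

#' Dynamic time warping distance with a Sakoe-Chiba band
#'
#' Minimal cumulative cost over monotone warping paths between two
#' equal-length vectors, with local cost `|a_i - b_j|` and the classical
#' symmetric step pattern (diagonal steps weighted 2 by default). Paths are
#' restricted to a diagonal band of half-width `ceiling(band_fraction * m)`
#' samples.
#'
#' @param a,b Complete numeric vectors.
#' @param band_fraction Band half-width as a fraction of the series length,
#'   in `(0, 1]`; 1 disables the constraint for equal lengths.
#' @param symmetric2 Weight diagonal steps by 2 (classical symmetric
#'   pattern)? `FALSE` gives unit-weight symmetric stepping.
#' @return Nonnegative cumulative warping cost.
#' @export
dtw_distance <- function(a, b, band_fraction = 0.1, symmetric2 = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b), !anyNA(a), !anyNA(b))
  band <- .band_width(max(length(a), length(b)), band_fraction)
  .dtw_cpp(as.numeric(a), as.numeric(b), band, symmetric2)
}

#' Complexity estimate of a series
#'
#' Square root of the first-difference energy,
#' `CE(x) = sqrt(sum((x_i - x_{i+1})^2))`. Flat series score 0.
#'
#' @param x Complete numeric vector of length at least 2.
#' @return Nonnegative scalar.
#' @export
complexity_estimate <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(x)) stop("missing values in input", call. = FALSE)
  .ce_cpp(as.numeric(x))
}

#' Complexity-invariant DTW distance
#'
#' The banded DTW distance multiplied by the complexity correction factor
#' `CF = max(CE(a), CE(b)) / max(min(CE(a), CE(b)), eps)`, which penalizes
#' pairing series of unequal waveform complexity. `CF = 1` when both
#' complexities are below `eps`.
#'
#' @inheritParams dtw_distance
#' @param eps Guard against division by zero for flat series.
#' @return Nonnegative scalar, always `>= dtw_distance(a, b)`.
#' @export
cid_dtw <- function(a, b, band_fraction = 0.1, symmetric2 = TRUE,
                    eps = 1e-12) {
  d <- dtw_distance(a, b, band_fraction, symmetric2)
  ca <- complexity_estimate(a); cb <- complexity_estimate(b)
  hi <- max(ca, cb); lo <- min(ca, cb)
  cf <- if (hi <= eps) 1 else hi / max(lo, eps)
  d * cf
}

#' Pairwise dissimilarity matrix between normalized windows
#'
#' Computes the full symmetric matrix of pairwise distances between the
#' z-normalized values of a window set, once per unordered pair. Distances
#' are always taken on `norm` values, never raw mg/dL.
#'
#' @param windows A `glucose_windows` set with no degenerate windows.
#' @param metric One of `"cid_dtw"` (default), `"dtw"`, `"cid"`,
#'   `"euclidean"`.
#' @param band_fraction Sakoe-Chiba band fraction for the DTW metrics.
#' @param symmetric2 Diagonal step weight 2?
#' @return A `dissimilarity_matrix`: a symmetric numeric matrix with zero
#'   diagonal and window ids as dimnames.
#' @export
pairwise_dissimilarity <- function(windows, metric = "cid_dtw",
                                   band_fraction = 0.1, symmetric2 = TRUE) {
  code <- .metric_code(metric)
  X <- .norm_matrix(windows)
  band <- .band_width(ncol(X), band_fraction)
  D <- .pairwise_cpp(X, code, band, symmetric2, 1e-12)
  ids <- vapply(windows, window_id, character(1))
  dimnames(D) <- list(ids, ids)
  structure(D, metric = metric, class = c("dissimilarity_matrix", "matrix"))
}

#' Cross-dissimilarities between two sets of scaled vectors
#'
#' Distances between the rows of `X` (e.g. new windows) and the rows of
#' `Y` (e.g. reference windows), used by the out-of-sample classifier.
#'
#' @param X,Y Numeric matrices with equal row length.
#' @inheritParams pairwise_dissimilarity
#' @return `nrow(X) x nrow(Y)` nonnegative matrix.
#' @export
cross_dissimilarity <- function(X, Y, metric = "cid_dtw",
                                band_fraction = 0.1, symmetric2 = TRUE) {
  code <- .metric_code(metric)
  band <- .band_width(ncol(X), band_fraction)
  .cross_cpp(X, Y, code, band, symmetric2, 1e-12)
}

#' Write/read a dissimilarity matrix as TSV
#'
#' @param D A `dissimilarity_matrix`.
#' @param path File path.
#' @return `read_dissimilarity` returns the matrix with ids restored.
#' @export
write_dissimilarity <- function(D, path) {
  df <- data.frame(id = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- .read_tsv(path)
  ids <- df$id
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  storage.mode(M) <- "double"
  structure(M, class = c("dissimilarity_matrix", "matrix"))
}
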