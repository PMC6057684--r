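.dist_ss <- function(D, idx) {
  # pairwise-squared-distance form of a sum of squares:
  # sum_{i<j} d_ij^2 / n  (reproduces the Euclidean decomposition exactly)
  n <- length(idx)
  if (n < 2) return(0)
  sub <- D[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)]^2) / n
}

#' Cluster-quality metrics on a dissimilarity matrix
#'
#' Distance-based decomposition of the total sum of squares into
#' between- and within-cluster parts, plus average silhouette width,
#' Calinski-Harabasz index, assignment entropy (natural log), and the Dunn
#' index. Singleton clusters get silhouette 0; with a single cluster the
#' pairwise indices are reported `NA` and variance explained is 0.
#'
#' @param D A `dissimilarity_matrix`.
#' @param labels Cluster assignment per window (any atomic type).
#' @return List of class `quality_report`: `k`, `variance_explained`,
#'   `silhouette_mean`, `ch_index`, `entropy`, `dunn`, `tot_ss`,
#'   `tot_wss`, `tot_bss`.
#' @export
cluster_quality <- function(D, labels) {
  D <- unclass(D)
  W <- nrow(D)
  stopifnot(length(labels) == W)
  labels <- as.character(labels)
  groups <- split(seq_len(W), labels)
  k <- length(groups)
  tot_ss <- .dist_ss(D, seq_len(W))
  tot_wss <- sum(vapply(groups, function(idx) .dist_ss(D, idx), numeric(1)))
  tot_bss <- tot_ss - tot_wss
  p <- vapply(groups, length, integer(1)) / W
  entropy <- -sum(p * log(p))
  if (k < 2) {
    return(structure(list(k = k, variance_explained = 0,
                          silhouette_mean = NA_real_, ch_index = NA_real_,
                          entropy = entropy, dunn = NA_real_,
                          tot_ss = tot_ss, tot_wss = tot_wss,
                          tot_bss = tot_bss),
                     class = "quality_report"))
  }
  # silhouette: a(w) mean distance within own cluster, b(w) lowest mean
  # distance to another cluster; singletons score 0
  sil <- vapply(seq_len(W), function(i) {
    own <- groups[[labels[i]]]
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(groups[names(groups) != labels[i]],
                    function(idx) mean(D[i, idx]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  ch <- (tot_bss / (k - 1)) / (tot_wss / (W - k))
  inter_min <- Inf; intra_max <- 0
  for (gi in seq_len(k)) {
    idx_i <- groups[[gi]]
    if (length(idx_i) > 1) {
      intra_max <- max(intra_max,
                       max(D[idx_i, idx_i][upper.tri(D[idx_i, idx_i])]))
    }
    for (gj in seq_len(k)) {
      if (gj <= gi) next
      inter_min <- min(inter_min, min(D[idx_i, groups[[gj]]]))
    }
  }
  dunn <- if (intra_max > 0) inter_min / intra_max else Inf
  structure(list(k = k,
                 variance_explained = if (tot_ss > 0) tot_bss / tot_ss else 0,
                 silhouette_mean = mean(sil), ch_index = ch,
                 entropy = entropy, dunn = dunn,
                 tot_ss = tot_ss, tot_wss = tot_wss, tot_bss = tot_bss),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("<quality_report> k = %d | variance explained %.3f | ",
                     "silhouette %.3f | CH %.1f | entropy %.3f | Dunn %.3f\n"),
              x$k, x$variance_explained, x$silhouette_mean, x$ch_index,
              x$entropy, x$dunn))
  invisible(x)
}

#' Parameter-optimization grid over windowing and distance choices
#'
#' For every combination of window size, overlap, and distance metric:
#' preprocess the cohort, compute the dissimilarity matrix, build the
#' smallest connected kNN graph, pick `k` by the eigengap, partition, and
#' report the cluster-quality metrics. Output is a long table with columns
#' `distance`, `shift`, `window_size_hrs`, `clust_metric`, `value`,
#' `window_overlap_perc`.
#'
#' @param series_list List of [cgm_series].
#' @param window_hours Window sizes (hours) to try.
#' @param overlaps Overlap fractions to try.
#' @param metrics Distance metrics to try.
#' @param band_fraction Sakoe-Chiba band fraction for the DTW metrics.
#' @param seed Seed for the partition step.
#' @return Data frame in long format; infeasible combinations (fewer than
#'   two windows for some subject) are flagged with `NA` values.
#' @export
optimize_parameters <- function(series_list, window_hours = c(2, 2.5, 3),
                                overlaps = c(0.5, 0.75),
                                metrics = c("euclidean", "dtw", "cid",
                                            "cid_dtw"),
                                band_fraction = 0.1, seed = 1) {
  grid <- expand.grid(window_hours = window_hours, overlap = overlaps,
                      metric = metrics, stringsAsFactors = FALSE)
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    wh <- grid$window_hours[r]; ov <- grid$overlap[r]
    met <- grid$metric[r]
    shift <- wh * 60 * (1 - ov)
    cfg <- windowing_config(window_hours = wh, overlap_fraction = ov)
    wins <- tryCatch(
      suppressWarnings(preprocess_cohort(series_list, cfg)),
      error = function(e) NULL)
    vals <- rep(NA_real_, 7)
    names(vals) <- c("n_clusters", "variance", "silhouette", "CH_index",
                     "entropy", "dunn", "n_windows")
    if (!is.null(wins) && length(wins) >= 8) {
      D <- pairwise_dissimilarity(wins, metric = met,
                                  band_fraction = band_fraction)
      n <- min_connected_neighbors(D)
      graph <- knn_affinity(D, n)
      eg <- eigengap_k(graph)
      k <- max(2, min(eg$k, floor(length(wins) / 2) - 1))
      part <- spectral_partition(graph, k, seed = seed)
      q <- cluster_quality(D, part$labels)
      vals[] <- c(k, q$variance_explained, q$silhouette_mean, q$ch_index,
                  q$entropy, q$dunn, length(wins))
    }
    rows[[r]] <- data.frame(distance = met, shift = shift,
                            window_size_hrs = wh,
                            clust_metric = names(vals), value = unname(vals),
                            window_overlap_perc = 100 * ov,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
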