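.knn_adjacency <- function(D, n) {
  W <- nrow(D)
  A <- matrix(0, W, W)
  for (i in seq_len(W)) {
    # ties at the n-th neighbor broken by index (window id) order
    ord <- order(D[i, -i], seq_len(W - 1))
    nb <- seq_len(W)[-i][ord[seq_len(n)]]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))  # symmetrized kNN: edge if either direction is kNN
  diag(A) <- 0
  A
}

.laplacian <- function(W, normalized = FALSE) {
  d <- rowSums(W)
  L <- diag(d) - W
  if (normalized) {
    inv <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(inv) %*% L %*% diag(inv)
  }
  L
}

.n_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  igraph::components(g)$no
}

.n_zero_eigenvalues <- function(A, tol = 1e-8) {
  ev <- eigen(.laplacian(A), symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev) < tol * max(1, max(abs(ev))))
}

#' Smallest neighbor count yielding a connected kNN graph
#'
#' Scans `n = 1, 2, ...` and returns the smallest `n` for which the
#' symmetrized n-nearest-neighbor graph of `D` is connected, i.e. the
#' unnormalized graph Laplacian has exactly one zero eigenvalue. The
#' multiplicity of the zero eigenvalue equals the number of connected
#' components, so for large graphs the count can equivalently (and much
#' faster) be taken from a graph traversal; `method = "auto"` uses the
#' eigenvalue check up to 400 windows and traversal beyond.
#'
#' @param D A `dissimilarity_matrix`.
#' @param method `"auto"`, `"eigen"`, or `"components"`.
#' @return Integer `n <= nrow(D) - 1`.
#' @export
min_connected_neighbors <- function(D, method = c("auto", "eigen",
                                                  "components")) {
  method <- match.arg(method)
  W <- nrow(D)
  stopifnot(W >= 2)
  use_eigen <- switch(method, eigen = TRUE, components = FALSE,
                      auto = W <= 400)
  for (n in seq_len(W - 1)) {
    A <- .knn_adjacency(unclass(D), n)
    ncomp <- if (use_eigen) .n_zero_eigenvalues(A) else .n_components(A)
    if (ncomp == 1) return(n)
  }
  W - 1L
}

#' k-nearest-neighbor affinity graph
#'
#' Binary symmetric adjacency: an edge joins `i` and `j` iff `j` is among
#' the `n` nearest neighbors of `i` or vice versa. Diagonal is zero.
#'
#' @param D A `dissimilarity_matrix`.
#' @param n Number of neighbors, `1 <= n <= nrow(D) - 1`.
#' @return An `affinity_graph`: 0/1 symmetric matrix with attribute
#'   `n_neighbors`.
#' @export
knn_affinity <- function(D, n) {
  W <- nrow(D)
  stopifnot(n >= 1, n <= W - 1)
  A <- .knn_adjacency(unclass(D), as.integer(n))
  dimnames(A) <- dimnames(D)
  structure(A, n_neighbors = as.integer(n),
            class = c("affinity_graph", "matrix"))
}

#' Eigengap choice of the number of clusters
#'
#' Eigenvalues of the unnormalized Laplacian are sorted ascending and `k`
#' is the index in `[k_min, k_max]` maximizing the gap
#' `lambda[k+1] - lambda[k]`.
#'
#' @param graph An `affinity_graph` (must be connected).
#' @param k_min,k_max Search bounds for `k`.
#' @param normalized Use the symmetric normalized Laplacian instead?
#' @return List with `k` and the ascending eigenvalue `spectrum`.
#' @export
eigengap_k <- function(graph, k_min = 2, k_max = 10, normalized = FALSE) {
  if (.n_components(unclass(graph)) != 1) {
    stop("graph is disconnected; increase n (see min_connected_neighbors)",
         call. = FALSE)
  }
  .eigengap_from_spectrum(
    .laplacian_spectrum(graph, normalized), k_min, k_max)
}

.laplacian_spectrum <- function(graph, normalized = FALSE) {
  ev <- eigen(.laplacian(unclass(graph), normalized), symmetric = TRUE,
              only.values = TRUE)$values
  sort(ev)
}

.eigengap_from_spectrum <- function(lambda, k_min = 2, k_max = 10) {
  k_max <- min(k_max, length(lambda) - 1)
  gaps <- lambda[(k_min + 1):(k_max + 1)] - lambda[k_min:k_max]
  k <- (k_min:k_max)[which.max(gaps)]
  list(k = k, spectrum = lambda)
}

#' Spectral partition of an affinity graph
#'
#' Following the standard spectral clustering recipe: take the
#' eigenvectors of the (unnormalized by default) graph Laplacian belonging
#' to the `k` smallest eigenvalues, and partition their rows with seeded
#' k-means (50 restarts).
#'
#' @param graph A connected `affinity_graph`.
#' @param k Number of clusters, `2 <= k < nrow(graph) / 2`.
#' @param seed Integer seed for the k-means initialization.
#' @param normalized Use the symmetric normalized Laplacian (with row
#'   normalization of the embedding)?
#' @param nstart k-means restarts.
#' @return List with integer `labels`, the `embedding` matrix (W x k), and
#'   k-means `centroids` (k x k).
#' @export
spectral_partition <- function(graph, k, seed = 1, normalized = FALSE,
                               nstart = 50) {
  W <- nrow(graph)
  stopifnot(k >= 2, k < W / 2)
  L <- .laplacian(unclass(graph), normalized)
  es <- eigen(L, symmetric = TRUE)
  U <- es$vectors[, order(es$values)[seq_len(k)], drop = FALSE]
  if (normalized) {
    nr <- sqrt(rowSums(U^2))
    U <- U / ifelse(nr > 0, nr, 1)
  }
  km <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    km <- tryCatch(kmeans(U, centers = k, nstart = nstart, iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " clusters",
                        call. = FALSE)
  list(labels = km$cluster, embedding = U, centroids = km$centers)
}

#' Order clusters by mean raw glucose
#'
#' Ranks clusters by the mean raw (mg/dL) glucose of their member windows;
#' the ascending ranks are named `low`, `moderate`, `severe` when `k = 3`,
#' otherwise generic ordinal names `class1 < class2 < ...`.
#'
#' @param labels Integer cluster labels, one per window.
#' @param windows The corresponding `glucose_windows` (raw values used).
#' @return Named character vector mapping cluster index to class name, with
#'   attribute `mean_glucose` (per class, ascending).
#' @export
order_by_severity <- function(labels, windows) {
  stopifnot(length(labels) == length(windows))
  means <- tapply(
    vapply(windows, function(w) mean(w$raw), numeric(1)), labels, mean)
  k <- length(means)
  nm <- if (k == 3) c("low", "moderate", "severe") else
    paste0("class", seq_len(k))
  ord <- order(means)
  sev <- setNames(nm, names(means)[ord])
  attr(sev, "mean_glucose") <- setNames(as.numeric(means[ord]), nm)
  sev
}

#' Train a glucotype model on a window set
#'
#' End-to-end training: pairwise CID-DTW dissimilarity, smallest-n
#' connected kNN affinity graph, eigengap selection of the number of
#' classes (unless `k` is fixed), spectral partition, severity ordering of
#' the classes by mean glucose, and precomputation of the constants needed
#' to classify new windows (training-pool mean/sd in mg/dL and the
#' affinity kernel scale sigma chosen so that the median training affinity
#' is 0.5).
#'
#' @param windows Preprocessed training `glucose_windows`.
#' @param k Number of classes, or `"auto"` for eigengap selection.
#' @param metric Distance metric (see [pairwise_dissimilarity()]).
#' @param band_fraction Sakoe-Chiba band fraction.
#' @param seed Seed for the k-means step.
#' @param D Optional precomputed `dissimilarity_matrix` (skips the
#'   pairwise computation).
#' @param kernel_knn Neighbor count of the local-scale term of the affinity
#'   kernel used at classification time.
#' @return A `glucotype_model` with the training labels, embedding,
#'   centroids, severity map, eigenvalue spectrum, scaling constants, and
#'   the labeled training pool.
#' @export
glucotype_fit <- function(windows, k = "auto", metric = "cid_dtw",
                          band_fraction = 0.1, seed = 1, D = NULL,
                          kernel_knn = 20) {
  if (is.null(D)) {
    D <- pairwise_dissimilarity(windows, metric = metric,
                                band_fraction = band_fraction)
  }
  n <- min_connected_neighbors(D)
  graph <- knn_affinity(D, n)
  eg <- eigengap_k(graph)
  k_use <- if (identical(k, "auto")) eg$k else as.integer(k)
  part <- spectral_partition(graph, k_use, seed = seed)
  sev <- order_by_severity(part$labels, windows)
  classes <- unname(sev[as.character(part$labels)])
  raw <- .raw_matrix(windows)
  train_mean <- mean(raw); train_sd <- sd(as.numeric(raw))
  # kernel scale: make the median training affinity 0.5 under the
  # locally-scaled Gaussian kernel used for out-of-sample affinities;
  # calibrated on the globally-scaled training pool, the scale on which
  # classification distances are computed
  Sg <- (raw - train_mean) / train_sd
  Dg <- .pairwise_cpp(Sg, .metric_code(metric),
                      .band_width(ncol(Sg), band_fraction), TRUE, 1e-12)
  sigma <- .calibrate_sigma(Dg, kernel_knn)
  model <- list(k = k_use, metric = metric, band_fraction = band_fraction,
                n_neighbors = n, spectrum = eg$spectrum,
                labels = part$labels, classes = classes,
                embedding = part$embedding, centroids = part$centroids,
                severity_order = sev,
                class_mean_glucose = attr(sev, "mean_glucose"),
                train_mean = train_mean, train_sd = train_sd,
                kernel_scale = sigma, kernel_knn = kernel_knn,
                windows = .label_windows(windows, classes),
                seed = seed)
  class(model) <- "glucotype_model"
  model
}

.label_windows <- function(windows, classes) {
  out <- unclass(windows)
  for (i in seq_along(out)) out[[i]]$class <- classes[i]
  new_window_set(out, m = attr(windows, "m"),
                 interval_min = attr(windows, "interval_min"))
}

.calibrate_sigma <- function(D, knn = 20) {
  eps_mat <- .kernel_eps(D, D_self = D, knn = knn)
  ut <- upper.tri(D)
  ratio <- D[ut]^2 / eps_mat[ut]
  q <- median(ratio[is.finite(ratio) & ratio > 0])
  q / log(2)  # exp(-q / sigma) = 0.5 at the median pair
}

# local scale eps_ij = (mean_kNN(d(i,.)) + mean_kNN(d(j,.)) + d_ij) / 3;
# row/col means are each point's mean distance to its knn nearest neighbors
.kernel_eps <- function(D, D_self = NULL, knn = 20, row_means = NULL,
                        col_means = NULL) {
  if (is.null(row_means)) {
    row_means <- .knn_row_means(if (is.null(D_self)) D else D_self, knn)
  }
  if (is.null(col_means)) col_means <- row_means
  outer(row_means, col_means, "+") / 3 + D / 3
}

.knn_row_means <- function(M, knn) {
  apply(M, 1, function(r) {
    r <- sort(r)
    if (r[1] == 0) r <- r[-1]  # self distance
    mean(r[seq_len(min(knn, length(r)))])
  })
}

#' @export
print.glucotype_model <- function(x, ...) {
  cat(sprintf(
    "<glucotype_model> k = %d, %d training windows, metric %s\n",
    x$k, length(x$labels), x$metric))
  cat("class mean glucose (mg/dL):",
      paste(sprintf("%s %.1f", names(x$class_mean_glucose),
                    x$class_mean_glucose), collapse = ", "), "\n")
  invisible(x)
}
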