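#' Select a reference subset of training windows
#'
#' CID-DTW against the full training pool is expensive, so classification
#' uses a reference subset: at least 200 windows, or as many as there are
#' windows to classify if more. Sampling is stratified by class
#' (proportional to class sizes, each class represented) with
#' per-window probability proportional to a Gaussian kernel density of the
#' training points in the spectral embedding, so the subset recapitulates
#' the density around each class centroid. Deterministic given `seed`.
#'
#' @param model A `glucotype_model`.
#' @param n_to_classify Number of windows that will be classified.
#' @param seed Integer seed.
#' @param min_size Minimum reference-set size.
#' @return List with `idx` (training indices), `windows`, `classes`,
#'   `size`, `seed`.
#' @export
select_references <- function(model, n_to_classify, seed = 1,
                              min_size = 200) {
  pool <- length(model$labels)
  size <- max(min_size, n_to_classify)
  if (size >= pool) {
    if (size > pool) warning("training pool smaller than requested ",
                             "reference size; using all ", pool, " windows",
                             call. = FALSE)
    idx <- seq_len(pool)
  } else {
    dens <- .embedding_density(model$embedding)
    cls <- model$classes
    tab <- table(cls)
    # proportional allocation, at least one per class, largest remainders
    alloc <- .proportional_alloc(tab, size)
    set.seed(seed)
    idx <- sort(unlist(lapply(names(alloc), function(cc) {
      cand <- which(cls == cc)
      take <- min(alloc[[cc]], length(cand))
      sample(cand, take, prob = dens[cand])
    }), use.names = FALSE))
  }
  list(idx = idx, windows = model$windows[idx],
       classes = model$classes[idx], size = length(idx), seed = seed)
}

.proportional_alloc <- function(tab, size) {
  p <- as.numeric(tab) / sum(tab)
  base <- pmax(1, floor(p * size))
  rem <- size - sum(base)
  if (rem > 0) {
    frac <- p * size - floor(p * size)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  } else if (rem < 0) {
    cut <- order(base, decreasing = TRUE)[seq_len(-rem)]
    base[cut] <- pmax(1, base[cut] - 1)
  }
  setNames(as.integer(base), names(tab))
}

# Gaussian product-kernel density at each embedding row, Scott bandwidth
.embedding_density <- function(E) {
  n <- nrow(E); p <- ncol(E)
  h <- apply(E, 2, sd) * n^(-1 / (p + 4))
  h[h <= 0 | !is.finite(h)] <- 1e-6
  dens <- numeric(n)
  Z <- sweep(E, 2, h, "/")
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(Z, 2, Z[i, ], "-")^2)
    dens[i] <- mean(exp(-d2 / 2))
  }
  dens / sum(dens)
}

#' Scale a new window with the training constants
#'
#' Mean-centers and scales a raw mg/dL vector with the mean and standard
#' deviation precomputed over the entire training pool (not the window's
#' own moments), so new windows land on the training scale.
#'
#' @param values Raw mg/dL vector of the training window length.
#' @param model A `glucotype_model`.
#' @return Unitless vector.
#' @export
scale_new <- function(values, model) {
  m <- attr(model$windows, "m")
  if (length(values) != m) {
    stop("window has length ", length(values), "; model expects ", m,
         call. = FALSE)
  }
  (values - model$train_mean) / model$train_sd
}

#' Affinity of new windows to the reference set
#'
#' Locally scaled Gaussian kernel on CID-DTW distances:
#' `w_ij = exp(-d_ij^2 / (sigma * eps_ij))` with
#' `eps_ij = (mean_kNN(d(i, .)) + mean_kNN(d(j, .)) + d_ij) / 3` and
#' `sigma` the model's precomputed kernel scale.
#'
#' @param new_scaled Matrix of scaled new windows (rows).
#' @param refs Reference set from [select_references()].
#' @param model A `glucotype_model`.
#' @return `n_new x n_ref` affinity matrix in `(0, 1]`.
#' @export
affinity_to_references <- function(new_scaled, refs, model) {
  if (model$kernel_scale <= 0) stop("model kernel scale must be positive",
                                    call. = FALSE)
  ref_scaled <- .ref_matrix(refs, model)
  Dx <- cross_dissimilarity(new_scaled, ref_scaled, metric = model$metric,
                            band_fraction = model$band_fraction)
  Dr <- .pairwise_cpp(ref_scaled, .metric_code(model$metric),
                      .band_width(ncol(ref_scaled), model$band_fraction),
                      TRUE, 1e-12)
  knn <- model$kernel_knn
  eps <- .kernel_eps(Dx, knn = knn,
                     row_means = .knn_row_means(Dx, knn),
                     col_means = .knn_row_means(Dr, knn))
  exp(-Dx^2 / (model$kernel_scale * eps))
}

.ref_matrix <- function(refs, model) {
  t(vapply(refs$windows, function(w) scale_new(w$raw, model),
           numeric(attr(model$windows, "m"))))
}

#' Project new windows onto the reference eigenspace and assign classes
#'
#' The reference windows' affinity graph (same kernel) provides a spectral
#' embedding; each new window is embedded as the affinity-weighted
#' combination of the reference eigenvectors, row-normalized to unit
#' length, and assigned the class of the nearest reference-class centroid
#' (ties broken toward the more severe class). An all-zero affinity row is
#' unclassifiable and yields `NA`.
#'
#' @param affinities Matrix from [affinity_to_references()].
#' @param refs Reference set from [select_references()].
#' @param model A `glucotype_model`.
#' @return Character vector of class labels (`NA` where unclassifiable).
#' @export
project_and_assign <- function(affinities, refs, model) {
  ref_scaled <- .ref_matrix(refs, model)
  Dr <- .pairwise_cpp(ref_scaled, .metric_code(model$metric),
                      .band_width(ncol(ref_scaled), model$band_fraction),
                      TRUE, 1e-12)
  rm_means <- .knn_row_means(Dr, model$kernel_knn)
  eps_r <- .kernel_eps(Dr, knn = model$kernel_knn,
                       row_means = rm_means, col_means = rm_means)
  Wr <- exp(-Dr^2 / (model$kernel_scale * eps_r))
  diag(Wr) <- 0
  es <- eigen(.laplacian(Wr), symmetric = TRUE)
  U <- es$vectors[, order(es$values)[seq_len(model$k)], drop = FALSE]
  Un <- .row_unit(U)
  sev_rank <- .severity_rank(model)
  cents <- do.call(rbind, lapply(names(sev_rank), function(cc) {
    colMeans(Un[refs$classes == cc, , drop = FALSE])
  }))
  rownames(cents) <- names(sev_rank)
  E <- affinities %*% U
  zero <- rowSums(affinities) == 0
  En <- .row_unit(E)
  d2 <- outer(rowSums(En^2), rowSums(cents^2), "+") - 2 * En %*% t(cents)
  labels <- apply(d2, 1, function(r) {
    best <- which(r <= min(r) + 1e-12)
    cand <- rownames(cents)[best]
    cand[which.max(sev_rank[cand])]  # tie toward the more severe class
  })
  labels[zero] <- NA_character_
  unname(labels)
}

.row_unit <- function(M) {
  nr <- sqrt(rowSums(M^2))
  M / ifelse(nr > 0, nr, 1)
}

.severity_rank <- function(model) {
  nm <- unname(model$severity_order)
  setNames(seq_along(nm), nm)  # ascending severity
}

#' Classify new CGM windows with a trained model
#'
#' Convenience wrapper: scales the raw windows with the training
#' constants, selects references, computes affinities, and assigns classes.
#'
#' @param windows A `glucose_windows` set of raw windows (training length).
#' @param model A `glucotype_model`.
#' @param seed Seed for reference selection.
#' @return Data frame with `window_id`, `subject_id`, `start_time`,
#'   `class`.
#' @export
classify_windows <- function(windows, model, seed = 1) {
  stopifnot(inherits(model, "glucotype_model"))
  refs <- select_references(model, n_to_classify = length(windows),
                            seed = seed)
  new_scaled <- t(vapply(windows, function(w) scale_new(w$raw, model),
                         numeric(attr(model$windows, "m"))))
  A <- affinity_to_references(new_scaled, refs, model)
  cls <- project_and_assign(A, refs, model)
  data.frame(
    window_id = vapply(windows, window_id, character(1)),
    subject_id = vapply(windows, function(w) w$subject_id, character(1)),
    start_time = vapply(windows, function(w) .format_time(w$start_time),
                        character(1)),
    class = cls, stringsAsFactors = FALSE)
}
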