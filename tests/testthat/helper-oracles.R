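# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Exhaustive enumeration of all monotone warping paths on the na x nb grid
# under the symmetric step pattern (diagonal weight 2 when symmetric2).
dtw_enumerate <- function(a, b, band = Inf, symmetric2 = TRUE) {
  na <- length(a); nb <- length(b)
  dw <- if (symmetric2) 2 else 1
  best <- Inf
  recurse <- function(i, j, acc) {
    if (abs(i - j) > band) return()
    if (acc >= best) return()
    if (i == na && j == nb) {
      best <<- min(best, acc)
      return()
    }
    if (i < na && j < nb) {
      recurse(i + 1, j + 1, acc + dw * abs(a[i + 1] - b[j + 1]))
    }
    if (i < na) recurse(i + 1, j, acc + abs(a[i + 1] - b[j]))
    if (j < nb) recurse(i, j + 1, acc + abs(a[i] - b[j + 1]))
  }
  recurse(1, 1, abs(a[1] - b[1]))
  best
}

# naive quality metrics on a distance matrix, written independently
naive_quality <- function(D, labels) {
  labels <- as.character(labels)
  W <- nrow(D)
  cls <- unique(labels)
  k <- length(cls)
  ss <- function(idx) {
    n <- length(idx); if (n < 2) return(0)
    tot <- 0
    for (i in idx) for (j in idx) if (i < j) tot <- tot + D[i, j]^2
    tot / n
  }
  tot_ss <- ss(1:W)
  tot_wss <- sum(sapply(cls, function(cc) ss(which(labels == cc))))
  tot_bss <- tot_ss - tot_wss
  sil <- numeric(W)
  for (i in 1:W) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { sil[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (cc in setdiff(cls, labels[i])) {
      b <- min(b, mean(D[i, labels == cc]))
    }
    sil[i] <- (b - a) / max(a, b)
  }
  p <- as.numeric(table(labels)) / W
  inter <- Inf; intra <- 0
  for (ci in cls) for (cj in cls) {
    ii <- which(labels == ci); jj <- which(labels == cj)
    if (ci == cj) {
      if (length(ii) > 1) {
        intra <- max(intra, max(D[ii, ii]))
      }
    } else inter <- min(inter, min(D[ii, jj]))
  }
  list(variance = tot_bss / tot_ss,
       silhouette = mean(sil),
       ch = (tot_bss / (k - 1)) / (tot_wss / (W - k)),
       entropy = -sum(p * log(p)),
       dunn = inter / intra)
}

# build a glucose_windows set directly from a matrix of raw traces
make_windows <- function(raw, subject = NULL, interval_min = 5,
                         classes = NULL) {
  n <- nrow(raw)
  if (is.null(subject)) subject <- rep("s1", n)
  t0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
  wins <- lapply(seq_len(n), function(i) {
    w <- glucotyper:::new_window(subject[i], t0 + (i - 1) * 9000, raw[i, ],
                                 interval_min = interval_min)
    w <- znormalize(w)
    if (!is.null(classes) && !is.na(classes[i])) w$class <- classes[i]
    w
  })
  glucotyper:::new_window_set(wins, m = ncol(raw),
                              interval_min = interval_min)
}

# shared small synthetic cohort + fitted model, built once per test run
shared_env <- new.env()

shared_cohort <- function() {
  if (is.null(shared_env$cohort)) {
    shared_env$cohort <- simulate_cohort(
      sim_config(n_subjects = 6, days = 3, seed = 2024))
  }
  shared_env$cohort
}

shared_model <- function() {
  if (is.null(shared_env$model)) {
    co <- shared_cohort()
    wins <- suppressWarnings(preprocess_cohort(co$series))
    shared_env$truth <- co$regimes[vapply(wins, function(w) w$subject_id,
                                          character(1))]
    shared_env$model <- glucotype_fit(wins, k = 3, seed = 7)
  }
  shared_env$model
}
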