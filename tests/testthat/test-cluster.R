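as_dmat <- function(M) {
  dimnames(M) <- list(paste0("w", seq_len(nrow(M))),
                      paste0("w", seq_len(nrow(M))))
  structure(M, class = c("dissimilarity_matrix", "matrix"))
}

blob_matrix <- function(centers, per = 3, spread = 0.05, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(centers, function(cc)
    matrix(rnorm(per * 2, cc, spread), ncol = 2)))
  as_dmat(as.matrix(dist(pts)))
}

test_that("a chain of equidistant points is connected at n = 1", {
  D <- as_dmat(as.matrix(dist(matrix(1:6, ncol = 1))))
  expect_equal(min_connected_neighbors(D, method = "eigen"), 1)
})

test_that("eigenvalue and traversal connectivity checks agree", {
  set.seed(4)
  for (i in 1:5) {
    D <- blob_matrix(c(0, 5, 10), per = 4, spread = 0.3, seed = i)
    n_e <- min_connected_neighbors(D, method = "eigen")
    n_c <- min_connected_neighbors(D, method = "components")
    expect_identical(n_e, n_c)
    expect_lte(n_e, nrow(D) - 1)
  }
  # two tight separated blobs need enough neighbors to bridge
  D2 <- blob_matrix(c(0, 100), per = 3, spread = 0.01)
  expect_equal(min_connected_neighbors(D2, method = "eigen"),
               min_connected_neighbors(D2, method = "components"))
  expect_gte(min_connected_neighbors(D2), 3)
})

test_that("kNN affinity is binary, symmetrized, and matches a sort oracle", {
  set.seed(12)
  D <- as_dmat(as.matrix(dist(matrix(rnorm(20), ncol = 2))))
  W <- nrow(D)
  A <- knn_affinity(D, n = W - 1)
  expect_equal(unclass(A), 1 - diag(W), ignore_attr = TRUE)

  for (n in c(2, 4)) {
    A <- knn_affinity(D, n)
    expect_true(all(rowSums(A) >= n))
    expect_identical(unclass(A), t(unclass(A)))
    # oracle: independent neighbor-sort construction
    O <- matrix(0, W, W)
    for (i in seq_len(W)) {
      nb <- setdiff(order(D[i, ]), i)[seq_len(n)]
      O[i, nb] <- 1
    }
    O <- pmax(O, t(O))
    expect_equal(unclass(A), O, ignore_attr = TRUE)
  }
})

test_that("Laplacian zero-eigenvalue count equals connected components", {
  D <- blob_matrix(c(0, 50, 100), per = 4, spread = 0.1)
  A <- glucotyper:::.knn_adjacency(unclass(D), 2)  # disconnected blocks
  n_zero <- glucotyper:::.n_zero_eigenvalues(A)
  n_comp <- glucotyper:::.n_components(A)
  expect_equal(n_zero, 3)
  expect_equal(n_zero, n_comp)
  # PSD: smallest eigenvalue of L is ~0
  ev <- eigen(glucotyper:::.laplacian(A), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("eigengap recovers the block count of weakly bridged blobs", {
  D <- blob_matrix(c(0, 5, 10), per = 10, spread = 0.15, seed = 3)
  n <- min_connected_neighbors(D)
  graph <- knn_affinity(D, n)
  eg <- eigengap_k(graph)
  expect_equal(eg$k, 3)
  # spectrum oracle: dense eigensolver on the same Laplacian
  ev <- sort(eigen(glucotyper:::.laplacian(unclass(graph)),
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(eg$spectrum, ev, tolerance = 1e-9)

  disc <- knn_affinity(D, 2)
  expect_error(eigengap_k(disc), "disconnected")
})

test_that("spectral partition recovers exact components and is deterministic", {
  D <- blob_matrix(c(0, 50, 100), per = 5, spread = 0.1, seed = 8)
  A <- structure(glucotyper:::.knn_adjacency(unclass(D), 2),
                 class = c("affinity_graph", "matrix"))
  part <- spectral_partition(A, 3, seed = 5)
  truth <- rep(1:3, each = 5)
  expect_equal(mclust::adjustedRandIndex(part$labels, truth), 1)
  part2 <- spectral_partition(A, 3, seed = 5)
  expect_identical(part$labels, part2$labels)
  expect_equal(dim(part$embedding), c(15L, 3L))
})

test_that("severity ordering ranks clusters by mean glucose, invariantly", {
  raw <- rbind(matrix(80, 4, 30) + rnorm(120, 0, 3),
               matrix(95, 4, 30) + rnorm(120, 0, 3),
               matrix(120, 4, 30) + rnorm(120, 0, 3))
  wins <- make_windows(raw)
  labels <- rep(c(2L, 3L, 1L), each = 4)  # arbitrary cluster indices
  sev <- order_by_severity(labels, wins)
  expect_equal(unname(sev[c("2", "3", "1")]),
               c("low", "moderate", "severe"))
  # invariance to relabeling of cluster indices
  perm <- c(`1` = 7L, `2` = 5L, `3` = 9L)
  sev2 <- order_by_severity(unname(perm[as.character(labels)]), wins)
  expect_equal(unname(sev2[c("5", "9", "7")]),
               c("low", "moderate", "severe"))
  # non-three-way clusterings get ordinal names
  sev_k2 <- order_by_severity(rep(1:2, 6), wins)
  expect_setequal(unname(sev_k2), c("class1", "class2"))
})

test_that("the fitted model orders severe classes above low in mean glucose", {
  model <- shared_model()
  mg <- model$class_mean_glucose
  expect_true(mg["low"] < mg["moderate"] && mg["moderate"] < mg["severe"])
  expect_equal(sort(unname(model$severity_order)),
               sort(c("low", "moderate", "severe")))
  expect_gt(model$kernel_scale, 0)
  expect_equal(model$k, 3)
})
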