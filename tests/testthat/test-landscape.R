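# Block similarity matrix with distinct between-group levels: groups differ
# in how similar they are to one another (as real structure groups do), so
# their centers stay separated in a rank-2 projection.
block_matrix <- function(sizes, within = 0.9, noise_sd = 0.02, seed = 5) {
  set.seed(seed)
  n <- sum(sizes)
  g <- length(sizes)
  lab <- rep(seq_len(g), sizes)
  between <- matrix(0, g, g)
  between[upper.tri(between)] <- seq(0.05, 0.35,
                                     length.out = g * (g - 1) / 2)
  between <- between + t(between)
  diag(between) <- within
  M <- between[lab, lab] + matrix(rnorm(n * n, 0, noise_sd), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(paste0("c", 1:n), paste0("c", 1:n))
  attr(M, "labels") <- lab
  M
}

test_that("similarity matrices have unit diagonal and expected degenerate rows", {
  P <- matrix(0, 50, 50)
  for (k in 0:3) P[1 + k, 30 - k] <- P[30 - k, 1 + k] <- 0.8
  sim <- build_similarity_matrix(list(a = P, b = P))
  expect_equal(unname(sim), matrix(1, 2, 2))

  empty <- matrix(0, 50, 50)
  sim2 <- build_similarity_matrix(list(a = P, b = empty, c = P))
  expect_equal(diag(sim2), c(a = 1, b = 1, c = 1))
  expect_equal(sim2["a", "b"], 0)
  expect_equal(sim2["a", "c"], 1)

  expect_error(build_similarity_matrix(list(P, P)), "names")
  expect_error(build_similarity_matrix(setNames(list(P, P), c("x", "x"))),
               "names")
})

test_that("PCA projection is deterministic and respects its contracts", {
  M <- block_matrix(c(5, 5))
  M2 <- M
  M2[2, ] <- M2[1, ]
  M2[, 2] <- M2[, 1]
  pc <- pca_project(M2)
  expect_equal(pc$coords[1, ], pc$coords[2, ])

  pc <- pca_project(M, n_components = 3)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-9)

  const <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(flat <- pca_project(const), "variance")
  expect_true(all(flat$coords == 0))
})

test_that("four planted blocks separate in the first two components", {
  M <- block_matrix(c(12, 11, 10, 10), seed = 8)
  lab <- attr(M, "labels")
  pc <- pca_project(M)
  # within-block spread far below between-block distances
  centers <- do.call(rbind, lapply(1:4, function(g)
    colMeans(pc$coords[lab == g, , drop = FALSE])))
  dmin_between <- min(dist(centers))
  dmax_within <- max(vapply(1:4, function(g) {
    x <- pc$coords[lab == g, , drop = FALSE]
    max(dist(rbind(colMeans(x), x))[seq_len(nrow(x))])
  }, 0.0))
  expect_gt(dmin_between, 2 * dmax_within)
})

test_that("inertia-based selection finds the planted number of groups", {
  M <- block_matrix(c(12, 11, 10, 10), seed = 8)
  ck <- choose_k_inertia(M, seed = 2)
  expect_equal(ck$k, 4L)
  expect_true(all(diff(ck$inertia$inertia) <= 1e-8))

  identical_pts <- matrix(0.5, 6, 6, dimnames = list(letters[1:6],
                                                     letters[1:6]))
  expect_warning(ck0 <- choose_k_inertia(identical_pts, seed = 1), "variance")
  expect_equal(ck0$k, 1L)

  tiny <- block_matrix(c(1, 1))
  expect_equal(choose_k_inertia(tiny, seed = 1)$k, 1L)
})

test_that("k-means grouping handles edge cases and recovers planted labels", {
  M <- block_matrix(c(12, 11, 10, 10), seed = 8)
  lab <- attr(M, "labels")

  g1 <- kmeans_groups(M, 1, seed = 1)
  expect_equal(unique(g1$assignments$group), 1L)

  gn <- kmeans_groups(M[1:5, 1:5], 5, seed = 1)
  expect_equal(sort(gn$assignments$group), 1:5)
  expect_equal(sort(gn$centroids), sort(gn$assignments$label))
  expect_error(kmeans_groups(M, 50, seed = 1), "exceeds")

  g4 <- kmeans_groups(M, 4, seed = 2)
  expect_equal(mclust::adjustedRandIndex(g4$assignments$group, lab), 1)
  # centroid constructs are members of their own groups
  for (g in 1:4) {
    members <- g4$assignments$label[g4$assignments$group == g]
    expect_true(g4$centroids[g] %in% members)
  }
})

test_that("group assignments are invariant to construct input order", {
  M <- block_matrix(c(8, 7, 7), seed = 19)
  lab <- attr(M, "labels")
  perm <- sample(nrow(M))
  Mp <- M[perm, perm]
  g <- kmeans_groups(M, 3, seed = 4)
  gp <- kmeans_groups(Mp, 3, seed = 4)
  ref <- g$assignments$group[match(gp$assignments$label, g$assignments$label)]
  expect_equal(mclust::adjustedRandIndex(gp$assignments$group, ref), 1)
})

test_that("archetype panels cluster with high within-group similarity", {
  pan <- simulate_archetype_panel(c(10, 5, 5), n_positions = 200, seed = 6)
  sim <- build_similarity_matrix(pan$pp_list, region = c(1, 200))
  within <- sim[pan$labels == 1, pan$labels == 1]
  between <- sim[pan$labels == 1, pan$labels == 2]
  expect_gt(min(within), max(between))
})
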