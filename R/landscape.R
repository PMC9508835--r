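#' All-pairs structural similarity matrix
#'
#' Builds the square matrix of overall-similarity values over a labeled
#' set of constructs (typically the native transcript plus a mutant
#' panel), from their pairing-probability matrices. The diagonal is
#' forced to 1.
#'
#' @param pp_list Named list of equal-dimension pairing-probability
#'   matrices; names label the constructs.
#' @param region Interval restriction passed to [overall_similarity()]
#'   (e.g. `c(1, 270)`).
#' @param cutoff Probability threshold (default 0.1).
#' @param symmetric Use the symmetrized overall similarity so the matrix
#'   itself is symmetric (default `TRUE` for landscape analysis).
#' @return A square numeric matrix with construct labels as dimnames.
#' @export
build_similarity_matrix <- function(pp_list, region = NULL, cutoff = 0.1,
                                    symmetric = TRUE) {
  if (length(pp_list) < 2L) stop("need at least two constructs")
  labels <- names(pp_list)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
    stop("pp_list must carry unique non-empty names")
  dims <- vapply(pp_list, nrow, 0L)
  if (length(unique(dims)) != 1L)
    stop("pairing-probability matrices have unequal dimensions")
  sets <- lapply(pp_list, function(pp)
    restrict_pairs(probability_pair_set(pp, cutoff), region))
  n <- length(sets)
  sim <- matrix(1, n, n, dimnames = list(labels, labels))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      ab <- sens_ppv(sets[[a]], sets[[b]])$overall
      sim[a, b] <- if (symmetric)
        (ab + sens_ppv(sets[[b]], sets[[a]])$overall) / 2 else ab
    }
  }
  sim
}

#' Project a similarity matrix onto principal components
#'
#' Column-centers the matrix and projects its rows onto the top
#' principal axes. Component signs are fixed by making the
#' largest-magnitude loading of each axis positive, so the projection
#' is deterministic.
#'
#' @param sim Square similarity matrix with labeled rows.
#' @param n_components Number of components to keep (default 2).
#' @return A list with `coords` (constructs x components) and
#'   `explained` (variance fractions, non-increasing).
#' @export
pca_project <- function(sim, n_components = 2L) {
  if (nrow(sim) < n_components) stop("fewer constructs than components")
  vars <- apply(sim, 2, stats::var)
  if (all(vars < 1e-12)) {
    warning("similarity matrix has no variance; coordinates are all zero")
    coords <- matrix(0, nrow(sim), n_components,
                     dimnames = list(rownames(sim),
                                     paste0("PC", seq_len(n_components))))
    return(list(coords = coords, explained = rep(0, n_components)))
  }
  pc <- prcomp(sim, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    big <- which.max(abs(rot[, c]))
    if (rot[big, c] < 0) coords[, c] <- -coords[, c]
  }
  if (k < n_components)
    coords <- cbind(coords, matrix(0, nrow(sim), n_components - k))
  colnames(coords) <- paste0("PC", seq_len(n_components))
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  expl[is.na(expl)] <- 0
  list(coords = coords, explained = expl)
}

landscape_coords <- function(sim, use_projection = TRUE) {
  if (use_projection) pca_project(sim, 2L)$coords else sim
}

#' Choose the number of structure groups by inertia
#'
#' Runs k-means (best of `nstart` restarts) on the 2-D principal
#' component projection for each candidate `k` and selects the elbow of
#' the inertia (total within-group sum of squares) curve: the `k`
#' maximizing the second difference of the log-inertia curve. Working on
#' the log scale locates the point where the *relative* drop in inertia
#' collapses; the raw second difference of a convex decreasing curve
#' peaks at the first drop regardless of cluster structure. Fewer than
#' 3 constructs, or a curve that is flat at zero, yield `k = 1`.
#'
#' @param sim Similarity matrix.
#' @param k_range Candidate values of `k` (default `1:8`).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Restarts per `k` (default 100).
#' @param use_projection Cluster PCA coordinates (default) or raw
#'   similarity rows.
#' @return A list with `k` (chosen), and `inertia` (data frame of the
#'   curve).
#' @export
choose_k_inertia <- function(sim, k_range = 1:8, seed = 1L, nstart = 100L,
                             use_projection = TRUE) {
  n <- nrow(sim)
  if (n < 3L) return(list(k = 1L, inertia = NULL))
  x <- landscape_coords(sim, use_projection)
  n_distinct <- nrow(unique(round(x, 10)))
  if (n_distinct < 2L) return(list(k = 1L, inertia = NULL))
  k_range <- k_range[k_range >= 1L & k_range <= min(n - 1L, n_distinct - 1L)]
  inertia <- vapply(k_range, function(k) {
    set.seed(seed + k)
    kmeans(x, centers = k, nstart = nstart, iter.max = 50L)$tot.withinss
  }, 0.0)
  if (max(inertia) < 1e-12) return(list(
    k = 1L, inertia = data.frame(k = k_range, inertia = inertia)))
  k <- 1L
  if (length(k_range) >= 3L) {
    li <- log(pmax(inertia, 1e-9 * max(inertia)))
    d2 <- li[1:(length(li) - 2)] - 2 * li[2:(length(li) - 1)] +
      li[3:length(li)]
    k <- k_range[which.max(d2) + 1L]
  }
  list(k = as.integer(k), inertia = data.frame(k = k_range, inertia = inertia))
}

#' K-means structure groups and centroid constructs
#'
#' Clusters the constructs into `k` groups by k-means with many restarts
#' and reports, per group, the member list and the centroid construct:
#' the member nearest the group mean in the clustered coordinate space.
#'
#' @param sim Similarity matrix with labeled rows.
#' @param k Number of groups.
#' @param seed Integer seed (k-means restarts are stochastic).
#' @param nstart Restarts (default 100).
#' @param use_projection Cluster PCA coordinates (default) or raw rows.
#' @return A list of class `structure_grouping` with `assignments`
#'   (data frame: label, group, PC1, PC2), `centroids` (one label per
#'   group), `k`, and the coordinates used.
#' @export
kmeans_groups <- function(sim, k, seed = 1L, nstart = 100L,
                          use_projection = TRUE) {
  n <- nrow(sim)
  if (k > n) stop("k exceeds the number of constructs")
  x <- landscape_coords(sim, use_projection)
  if (k == n) {
    group <- seq_len(n)          # trivial partition: one construct per group
  } else {
    set.seed(seed)
    km <- kmeans(x, centers = k, nstart = nstart, iter.max = 50L)
    # relabel groups by order of first appearance so input order is cosmetic
    first <- order(vapply(seq_len(k),
                          function(g) min(which(km$cluster == g)), 0L))
    relabel <- integer(k)
    relabel[first] <- seq_len(k)
    group <- relabel[km$cluster]
  }
  centroids <- vapply(seq_len(k), function(g) {
    members <- which(group == g)
    ctr <- colMeans(x[members, , drop = FALSE])
    d <- sqrt(rowSums(sweep(x[members, , drop = FALSE], 2, ctr)^2))
    rownames(sim)[members[which.min(d)]]
  }, "")
  proj <- if (use_projection) x else pca_project(sim, 2L)$coords
  structure(list(
    assignments = data.frame(label = rownames(sim), group = group,
                             PC1 = proj[, 1], PC2 = proj[, 2],
                             row.names = NULL),
    centroids = centroids, k = as.integer(k), coords = x),
    class = "structure_grouping")
}

#' @export
print.structure_grouping <- function(x, ...) {
  cat("<structure_grouping> k =", x$k, "\n")
  for (g in seq_len(x$k)) {
    members <- x$assignments$label[x$assignments$group == g]
    cat(sprintf("  group %d (%d members, centroid %s): %s\n", g,
                length(members), x$centroids[g],
                paste(head(members, 8), collapse = ", ")))
  }
  invisible(x)
}
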