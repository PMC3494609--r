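#' Hierarchical agglomerative partition of expression profiles
#'
#' Average-linkage agglomerative clustering on the one-minus-cosine distance
#' between profiles, with the dendrogram cut into exactly `k` clusters.
#' Deterministic for a given input ordering.
#'
#' @param profiles Numeric matrix, one profile per row (gene ids as row
#'   names), typically z-scored.
#' @param k Number of clusters, `1 <= k <= nrow(profiles)`.
#' @return A list of class `clustering`: `k`, `assignments` (named integer
#'   vector), `centroids` (k x conditions matrix of unit-norm rows).
#' @export
hac_partition <- function(profiles, k) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  if (k < 1 || k > nrow(profiles)) stop("k out of range [1, n]")
  if (nrow(profiles) == 1L) {
    assign <- setNames(1L, rownames(profiles))
  } else {
    d <- as.dist(1 - cosine_matrix(profiles, profiles))
    hc <- hclust(d, method = "average")
    assign <- cutree(hc, k = k)
    names(assign) <- rownames(profiles)
  }
  new_clustering(profiles, assign, k)
}

cosine_matrix <- function(a, b) {
  na <- a / sqrt(rowSums(a^2))
  nb <- b / sqrt(rowSums(b^2))
  m <- na %*% t(nb)
  pmin(pmax(m, -1), 1)
}

new_clustering <- function(profiles, assignments, k) {
  centroids <- t(vapply(seq_len(k), function(j) {
    members <- profiles[assignments == j, , drop = FALSE]
    v <- colMeans(members)
    v / sqrt(sum(v^2))
  }, numeric(ncol(profiles))))
  structure(list(k = k, assignments = assignments, centroids = centroids),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("clustering: k =", x$k, "over", length(x$assignments), "profiles;",
      "sizes:", paste(tabulate(x$assignments, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Deterministic spherical k-means initialised by hierarchical clustering
#'
#' Runs k-means with the one-minus-cosine distance (centroid = unit-normed
#' mean of its members), seeded from the [hac_partition()] centroids. The
#' hierarchical initialisation removes the usual random-restart dependence,
#' so repeated runs are bit-identical. Iterates to an assignment fixpoint or
#' `max_iter` sweeps; ties in the assignment step go to the lowest cluster
#' index; a cluster emptied during iteration is re-seeded with the profile
#' farthest (lowest cosine) from its current centroid.
#'
#' @inheritParams hac_partition
#' @param k Number of clusters (default 16).
#' @param max_iter Maximum iterations (default 300).
#' @return A `clustering` (see [hac_partition()]).
#' @export
kmeans_hac <- function(profiles, k = 16, max_iter = 300) {
  init <- hac_partition(profiles, k)
  centroids <- init$centroids
  assign <- init$assignments
  norm_prof <- profiles / sqrt(rowSums(profiles^2))
  for (iter in seq_len(max_iter)) {
    sim <- norm_prof %*% t(centroids)
    new_assign <- apply(sim, 1, which.max)  # which.max: lowest index on ties
    # re-seed empty clusters with the point least similar to its centroid
    empty <- setdiff(seq_len(k), unique(new_assign))
    for (j in empty) {
      fit <- sim[cbind(seq_along(new_assign), new_assign)]
      movable <- which(tabulate(new_assign, k)[new_assign] > 1L)
      worst <- movable[order(fit[movable], movable)][1]
      new_assign[worst] <- j
    }
    converged <- all(new_assign == assign)
    assign <- new_assign
    centroids <- t(vapply(seq_len(k), function(j) {
      v <- colMeans(profiles[assign == j, , drop = FALSE])
      v / sqrt(sum(v^2))
    }, numeric(ncol(profiles))))
    if (converged) break
  }
  names(assign) <- rownames(profiles)
  structure(list(k = k, assignments = assign, centroids = centroids),
            class = "clustering")
}

#' Total within-cluster one-minus-cosine cost
#'
#' @param profiles Profile matrix the clustering was built from.
#' @param cl A `clustering`.
#' @return Sum over profiles of 1 - cosine(profile, its centroid).
#' @export
clustering_cost <- function(profiles, cl) {
  norm_prof <- profiles / sqrt(rowSums(profiles^2))
  sim <- rowSums(norm_prof * cl$centroids[cl$assignments, , drop = FALSE])
  sum(1 - sim)
}

#' Match query clusters against library clusters
#'
#' For each query centroid finds the library centroid with the highest
#' cosine similarity (a BLAST-like best-hit search between two clusterings);
#' a match is mutual when the library cluster's own best hit points back at
#' the query cluster. Best cosines are summarised by mean and sample sd.
#'
#' @param query,library `clustering` objects over the same condition space.
#' @return A list with `matches` (data frame: `query`, `library`, `cosine`,
#'   `mutual`), `mean`, `sd`.
#' @export
match_clusters <- function(query, library) {
  stopifnot(inherits(query, "clustering"), inherits(library, "clustering"))
  sim_ql <- cosine_matrix(query$centroids, library$centroids)
  best_l <- apply(sim_ql, 1, which.max)
  best_q <- apply(t(sim_ql), 1, which.max)  # library -> query direction
  matches <- data.frame(query = seq_len(query$k), library = best_l,
                        cosine = sim_ql[cbind(seq_len(query$k), best_l)],
                        mutual = best_q[best_l] == seq_len(query$k))
  list(matches = matches, mean = mean(matches$cosine),
       sd = if (nrow(matches) > 1) sd(matches$cosine) else NA_real_)
}
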