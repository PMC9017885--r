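#' Reduced (truncated-SVD) representation of variant flexibility profiles
#'
#' Rows of `X` are protein variants, columns are sites (typically the %DFI
#' values at DARC sites). The matrix is factorised by singular value
#' decomposition and each variant is represented by its scores on the top
#' `r` singular pairs (`U_r %*% diag(sigma_r)`, equivalently `X %*% V_r`).
#' Pairwise Euclidean distances between score rows approximate — and at
#' `r = rank(X)` exactly equal — distances between the raw profiles.
#' Component signs are canonicalised so that each right-singular vector's
#' largest-magnitude loading is positive, making the scores deterministic
#' across linear-algebra backends.
#'
#' @param X numeric m x n matrix (variants x sites), no missing entries.
#' @param r number of singular pairs to keep (default 3).
#' @param center subtract column means first (classical PCA); default FALSE.
#' @return m x r score matrix with `X`'s row names; the singular values are
#'   attached as attribute `"singular_values"`.
#' @export
reduced_representation <- function(X, r = 3L, center = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("profile matrix has missing entries")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  s <- svd(X)
  rk <- sum(s$d > max(dim(X)) * .Machine$double.eps * max(s$d, 0))
  if (r < 1L || r > rk) stop("rank exceeded: r must be in 1..", rk)
  flip <- vapply(seq_len(r), function(k) {
    v <- s$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1L))
  scores <- s$u[, seq_len(r), drop = FALSE] %*%
    diag(s$d[seq_len(r)] * flip, r, r)
  rownames(scores) <- rownames(X)
  attr(scores, "singular_values") <- s$d
  scores
}

#' Euclidean distance between two variants in the reduced space
#'
#' @param scores score matrix from [reduced_representation()].
#' @param j1,j2 row indices (or row names).
#' @return non-negative distance.
#' @export
profile_distance <- function(scores, j1, j2) {
  sqrt(sum((scores[j1, ] - scores[j2, ])^2))
}

#' Average-linkage hierarchical clustering of variant profiles
#'
#' Bottom-up agglomerative clustering (UPGMA: inter-cluster distance is the
#' mean of all cross-cluster pairwise distances) on a pairwise distance
#' matrix, typically the score-space distances of
#' [reduced_representation()]. The dendrogram's height axis is the linkage
#' distance.
#'
#' @param D symmetric pairwise distance matrix (or a [stats::dist] object).
#' @return object of class `profile_dendrogram` wrapping the
#'   [stats::hclust()] result, with a merge table and Newick export (see
#'   [dendrogram_newick()]).
#' @export
average_linkage_cluster <- function(D) {
  d <- if (inherits(D, "dist")) D else {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D)) stop("distance matrix must be square")
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
    if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
    stats::as.dist(D)
  }
  if (attr(d, "Size") < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(d, method = "average")
  merges <- data.frame(cluster_a = hc$merge[, 1L], cluster_b = hc$merge[, 2L],
                       height = hc$height)
  structure(list(hclust = hc, merges = merges, labels = hc$labels),
            class = "profile_dendrogram")
}

#' @export
print.profile_dendrogram <- function(x, ...) {
  m <- nrow(x$merges) + 1L
  cat(sprintf("average-linkage dendrogram over %d profiles (heights %.4g..%.4g)\n",
              m, min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Cut a profile dendrogram into k clusters
#'
#' @param dend a `profile_dendrogram`.
#' @param k number of clusters.
#' @return integer cluster assignment per leaf.
#' @export
cut_clusters <- function(dend, k) {
  stats::cutree(dend$hclust, k = k)
}

#' Newick string of a profile dendrogram
#'
#' @param dend a `profile_dendrogram`.
#' @return single Newick-format string with branch lengths.
#' @export
dendrogram_newick <- function(dend) {
  ape::write.tree(ape::as.phylo(dend$hclust))
}

#' Cluster variant DFI-at-DARC-site profiles end to end
#'
#' Convenience wrapper: truncated-SVD scores, pairwise distances, and
#' average-linkage dendrogram in one call.
#'
#' @inheritParams reduced_representation
#' @return list with `scores`, `distances` (m x m matrix) and `dendrogram`.
#' @export
cluster_profiles <- function(X, r = 3L, center = FALSE) {
  scores <- reduced_representation(X, r = r, center = center)
  Dm <- as.matrix(stats::dist(scores))
  list(scores = scores, distances = Dm,
       dendrogram = average_linkage_cluster(Dm))
}
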