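#' Estimate the number of clusters from a sharing matrix
#'
#' Computes the eigenvalues of the symmetrically normalized sharing matrix
#' `D^(-1/2) P D^(-1/2)` (the complement of the normalized graph Laplacian
#' spectrum) and counts the significantly non-zero ones by the eigengap rule:
#' with eigenvalues sorted decreasingly, the cluster count `K` is the position
#' of the largest consecutive gap, where the gap after the smallest eigenvalue
#' is taken against zero.  For an exact block-diagonal sharing matrix each
#' block contributes one unit eigenvalue, so `K` equals the block count.
#'
#' @param sharing a `dcg_sharing` object or symmetric matrix with unit
#'   diagonal and entries in \[0, 1\].
#' @return Integer cluster count in `[1, n]`.
#' @export
estimate_cluster_count <- function(sharing) {
  sharing <- as_sharing(sharing)
  p <- sharing$values
  n <- nrow(p)
  d <- rowSums(p)           # >= 1 thanks to the unit diagonal
  ds <- 1 / sqrt(d)
  np <- p * tcrossprod(ds)  # D^(-1/2) P D^(-1/2)
  ev <- sort(eigen(np, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  gaps <- c(ev[-n] - ev[-1], max(ev[n], 0))
  as.integer(which.max(gaps))
}

#' One level of the connectivity clustering geometry
#'
#' Builds the cluster-sharing probability matrix of a correlation matrix at
#' temperature `T`, estimates the cluster count `K` spectrally and cuts the
#' complete-linkage hierarchical tree on dissimilarity `1 - P` into `K`
#' clusters, so that ROIs with high sharing probability are co-clustered.
#'
#' @param corr a [correlation_matrix()].
#' @param temperature positive focal scale `T`.
#' @param params a [walk_params()] object.
#' @return An object of class `dcg_level` with fields `temperature`, `k` and
#'   `membership` (cluster labels `1..k` named by ROI id).
#' @export
cluster_level <- function(corr, temperature, params = walk_params()) {
  corr <- as_correlation_matrix(corr)
  p <- sharing_matrix(power_transform(corr, temperature), params)
  level_from_sharing(p)
}

# Cut the HC tree of a sharing matrix at its spectrally estimated K.
# Average linkage is used for count-based cuts: when the sharing graph has
# exactly K connected components, the average-linkage cut at K returns the
# components themselves (cross-component dissimilarity is exactly 1), which
# complete linkage does not guarantee for weakly knit blocks.
level_from_sharing <- function(sharing, k = NULL) {
  sharing <- as_sharing(sharing)
  if (is.null(k)) k <- estimate_cluster_count(sharing)
  membership <- cut_sharing_tree(sharing, k = k, method = "average")
  structure(list(temperature = sharing$temperature, k = max(membership),
                 membership = membership, subject_id = sharing$subject_id,
                 group = sharing$group, trial = sharing$trial),
            class = "dcg_level")
}

# HC tree on dissimilarity 1 - P, cut by count or height
cut_sharing_tree <- function(sharing, k = NULL, h = NULL, method = "complete") {
  p <- sharing$values
  hc <- hclust(as.dist(1 - p), method = method)
  membership <- if (is.null(h)) cutree(hc, k = k) else cutree(hc, h = h)
  names(membership) <- sharing$roi_ids
  membership
}

#' @export
print.dcg_level <- function(x, ...) {
  cat("Clustering level at T =", format(x$temperature), "with", x$k,
      "clusters over", length(x$membership), "ROIs\n")
  invisible(x)
}
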