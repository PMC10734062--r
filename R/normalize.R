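#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same intensity distribution: the
#' reference distribution is the across-sample mean of sorted value
#' vectors, and each value is replaced by the reference value at its rank
#' within its own sample. Tied values receive the mean of the reference
#' values at the rank positions the tie occupies, so the map is well
#' defined and idempotent.
#'
#' @param m an [expression_matrix()] on the linear scale with at least two
#'   samples.
#' @return an [expression_matrix()] (linear scale) whose columns all share
#'   the reference distribution.
#' @export
quantile_normalize <- function(m) {
  abort_if(m$scale != "linear",
           "quantile normalization expects linear intensities")
  v <- m$values
  abort_if(ncol(v) < 2L, "need at least 2 samples to normalize against")
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(x) {
    assigned <- ref[rank(x, ties.method = "first")]
    # ties: average the reference values over the occupied rank positions
    stats::ave(assigned, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, m$groups, "linear")
}

#' Pearson correlation matrix between samples
#'
#' Sample-by-sample Pearson correlations of expression profiles, the
#' numbers behind sample-correlation QC heatmaps.
#'
#' @param m an [expression_matrix()] with at least 3 features.
#' @return symmetric matrix with unit diagonal, dimnames the sample ids.
#' @export
sample_correlation_matrix <- function(m) {
  v <- m$values
  abort_if(nrow(v) < 3L, "need at least 3 features")
  sds <- apply(v, 2L, stats::sd)
  flat <- colnames(v)[sds == 0]
  abort_if(length(flat) > 0L, "zero-variance sample(s): %s",
           paste(flat, collapse = ", "))
  r <- stats::cor(v)
  diag(r) <- 1
  r
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Distance is `1 - PCC` between sample profiles; merge heights are
#' non-decreasing for both supported linkages.
#'
#' @param m an [expression_matrix()] with at least 2 samples.
#' @param linkage `"average"` or `"complete"`.
#' @return an `hclust` object over samples.
#' @export
hierarchical_cluster_samples <- function(m,
                                         linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  abort_if(ncol(m$values) < 2L, "need at least 2 samples")
  d <- stats::as.dist(1 - sample_correlation_matrix(m))
  stats::hclust(d, method = linkage)
}

#' Export a sample dendrogram as Newick
#'
#' @param hc an `hclust` object from [hierarchical_cluster_samples()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Principal component scores for samples
#'
#' PCA by singular value decomposition of the feature-centered matrix
#' (features centered, not scaled). The sign of each component is fixed by
#' forcing its largest-magnitude feature loading positive, so scores are
#' reproducible.
#'
#' @param m an [expression_matrix()].
#' @param k number of components, `k <= min(n_samples - 1, n_features)`.
#' @return list with `scores` (samples x k), `variance_fraction` (length k,
#'   non-increasing), and `loadings` (features x k).
#' @export
pca_scores <- function(m, k = 2L) {
  v <- m$values
  kmax <- min(ncol(v) - 1L, nrow(v))
  abort_if(k < 1L || k > kmax,
           "k must be between 1 and %d for this matrix", kmax)
  x <- t(v - rowMeans(v))                       # samples x features, centered
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1L))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k, k), 2L, flip, `*`)
  loadings <- sweep(sv$v, 2L, flip, `*`)
  rownames(scores) <- colnames(v)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- rownames(v)
  colnames(loadings) <- colnames(scores)
  varfrac <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  list(scores = scores, variance_fraction = varfrac, loadings = loadings)
}
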