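#' Variance-stabilizing transformation from a fitted dispersion trend
#'
#' Closed-form transform for the variance model
#' \eqn{v(\mu) = (1 + a_1)\mu + a_0\mu^2} implied by the dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}: integrating \eqn{1/\sqrt{v(\mu)}} gives
#' \deqn{u(x) = \log_2\!\frac{2a_0 x + b + 2\sqrt{a_0(a_0x^2 + bx)}}{4a_0},
#'   \quad b = 1 + a_1,}
#' which is strictly increasing and approaches \eqn{\log_2 x} for large
#' counts. For \eqn{a_0 \to 0} it degenerates to the square-root (Poisson)
#' stabilizer \eqn{2\sqrt{x/b}/\ln 2}. The transform is applied to
#' size-factor-normalized counts.
#'
#' @param counts Numeric matrix (features x samples) or data frame with a
#'   feature column.
#' @param size_factors Optional per-sample size factors (estimated by
#'   median-of-ratios when `NULL`).
#' @param trend Optional dispersion trend `c(a0, a1)`. When `NULL` it is
#'   fitted blind (across all samples) by method of moments plus
#'   gamma-family regression, as in [nb_test()].
#' @return Matrix of transformed values with attributes `trend` and
#'   `size_factors`.
#' @export
vst <- function(counts, size_factors = NULL, trend = NULL) {
  m <- as_count_matrix(counts)
  sf <- size_factors %||% estimate_size_factors_mor(m)
  z <- sweep(m, 2, sf, "/")
  if (is.null(trend)) {
    mu <- rowMeans(z)
    xi <- mean(1 / sf)
    raw <- ifelse(mu > 0, (row_vars(z) - xi * mu) / mu^2, NA_real_)
    trend <- fit_dispersion_trend(mu, raw)
  }
  a0 <- max(trend[[1]], 0)
  a1 <- max(trend[[2]], 0)
  out <- vst_transform(z, a0, a1)
  dimnames(out) <- dimnames(m)
  attr(out, "trend") <- c(a0 = a0, a1 = a1)
  attr(out, "size_factors") <- sf
  out
}

vst_transform <- function(x, a0, a1) {
  b <- 1 + a1
  if (a0 < 1e-8) {
    2 * sqrt(x / b) / log(2)
  } else {
    log2((2 * a0 * x + b + 2 * sqrt(a0 * (a0 * x^2 + b * x))) / (4 * a0))
  }
}

#' Select the most variable features
#'
#' Ranks features by their sample variance of transformed values (the
#' clustering inputs were the 10,000 most variable genes / 500 most variable
#' lincRNAs in the analysis this reproduces). Ties are broken by feature
#' identifier order.
#'
#' @param vst_matrix Numeric matrix, features x samples (typically from
#'   [vst()]).
#' @param k Number of features to keep.
#' @return Tibble: feature, variance, rank (k rows, most variable first).
#' @export
top_variable <- function(vst_matrix, k) {
  if (!is.matrix(vst_matrix)) data_error("`vst_matrix` must be a matrix.")
  k <- check_count(k, "k", min = 1L)
  if (k > nrow(vst_matrix)) config_error("`k` exceeds the number of features.")
  v <- row_vars(vst_matrix)
  ord <- order(-v, rownames(vst_matrix))
  tibble(
    feature = rownames(vst_matrix)[ord][seq_len(k)],
    variance = v[ord][seq_len(k)],
    rank = seq_len(k)
  )
}

#' Hierarchical clustering of samples (Euclidean distance, Ward linkage)
#'
#' Agglomerative clustering of samples on Euclidean distances with Ward's
#' minimum-variance criterion in its `ward.D2` form (distances, not squared
#' distances, as input; heights are non-decreasing along merges).
#'
#' @param vst_matrix Numeric matrix, features x samples.
#' @param features Optional character vector (or [top_variable()] tibble)
#'   restricting the features used.
#' @return An [stats::hclust] object with sample labels.
#' @export
ward_cluster <- function(vst_matrix, features = NULL) {
  if (!is.matrix(vst_matrix)) data_error("`vst_matrix` must be a matrix.")
  if (!is.null(features)) {
    if (is.data.frame(features)) features <- features$feature
    vst_matrix <- vst_matrix[features, , drop = FALSE]
  }
  if (ncol(vst_matrix) < 2L) data_error("Need at least 2 samples.")
  if (!all(is.finite(vst_matrix))) data_error("Non-finite values in the matrix.")
  hclust(dist(t(vst_matrix)), method = "ward.D2")
}

#' Does a dendrogram contain a pure clade of one label?
#'
#' Checks monophyly: whether some internal node's leaf set equals exactly the
#' set of samples carrying `target_label`. Also reports the size of the
#' smallest clade containing all target samples (the target clade itself when
#' pure).
#'
#' @param dendrogram An [stats::hclust] object.
#' @param labels Character vector of sample labels, either named by sample id
#'   or aligned with `dendrogram$labels`.
#' @param target_label The label whose monophyly is tested.
#' @return One-row tibble: target_label, n_target, pure, clade_size.
#' @export
clade_purity <- function(dendrogram, labels, target_label) {
  hc <- dendrogram
  leaf_names <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  if (!is.null(names(labels))) labels <- labels[leaf_names]
  if (length(labels) != length(leaf_names)) {
    data_error("`labels` must cover every leaf of the dendrogram.")
  }
  if (!target_label %in% labels) data_error("`target_label` absent from labels.")
  target_set <- leaf_names[labels == target_label]
  n_nodes <- nrow(hc$merge)
  sets <- vector("list", n_nodes)
  leafset <- function(e) if (e < 0) leaf_names[-e] else sets[[e]]
  pure <- FALSE
  clade_size <- length(leaf_names)
  for (kk in seq_len(n_nodes)) {
    sets[[kk]] <- c(leafset(hc$merge[kk, 1]), leafset(hc$merge[kk, 2]))
    if (all(target_set %in% sets[[kk]]) && length(sets[[kk]]) < clade_size) {
      clade_size <- length(sets[[kk]])
    }
    if (!pure && length(sets[[kk]]) == length(target_set) &&
      setequal(sets[[kk]], target_set)) {
      pure <- TRUE
    }
  }
  if (length(target_set) == length(leaf_names)) pure <- TRUE # root case
  tibble(
    target_label = target_label, n_target = length(target_set),
    pure = pure, clade_size = clade_size
  )
}

#' Project samples by principal components
#'
#' Centered (unscaled) PCA of samples via singular value decomposition.
#' Component signs are fixed by making the largest-magnitude loading of each
#' component positive, so results are fully deterministic.
#'
#' @param vst_matrix Numeric matrix, features x samples.
#' @param features Optional feature subset (character vector or
#'   [top_variable()] tibble).
#' @param n_components Number of components to return.
#' @return List of class `flc_pca`: `scores` (tibble sample_id, PC1, ...),
#'   `explained_variance` (proportions), `loadings`, `zero_variance` flag.
#' @export
pca_project <- function(vst_matrix, features = NULL, n_components = 2L) {
  if (!is.null(features)) {
    if (is.data.frame(features)) features <- features$feature
    vst_matrix <- vst_matrix[features, , drop = FALSE]
  }
  n_components <- check_count(n_components, "n_components", min = 1L)
  if (n_components > min(dim(vst_matrix))) {
    config_error("`n_components` exceeds the matrix rank bound.")
  }
  x <- t(vst_matrix)
  zero_var <- all(row_vars(vst_matrix) == 0)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = rownames(x)), as_tibble(scores)),
    explained_variance = if (sum(ev) > 0) ev[seq_len(k)] / sum(ev) else rep(0, k),
    loadings = loadings,
    zero_variance = zero_var
  ), class = "flc_pca")
}
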