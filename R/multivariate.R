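#' Row-wise Z-score normalization
#'
#' Standardizes each row of a matrix to mean 0 and SD 1 (denominator
#' n - 1), the preprocessing used for cluster heatmaps of compound
#' abundances. Constant rows become all-zero and are flagged.
#'
#' @param m Numeric matrix with at least two columns.
#' @return Matrix of the same shape; attribute `constant_rows` lists
#'   rows with zero variance.
#' @examples
#' zscore_rows(rbind(a = 1:3, b = c(5, 5, 5)))
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least two columns to standardize")
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  z <- (m - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}

#' Principal component analysis by explicit eigendecomposition
#'
#' PCA of a sample-by-variable matrix via eigendecomposition of the
#' covariance (`preprocessing = "center"`) or correlation
#' (`preprocessing = "zscore"`) matrix. The tiny matrices of cultivar
#' studies make the explicit decomposition exact and free of iterative
#' convergence nondeterminism. Sign convention: in each loading
#' column the element of largest magnitude is positive.
#'
#' @param x Numeric sample-by-variable matrix (>= 2 samples,
#'   >= 2 variables).
#' @param preprocessing `"center"` (covariance PCA) or `"zscore"`
#'   (correlation PCA; every variable standardized first).
#' @return Object of class `aroma_pca`: list with `scores`
#'   (sample x component), `loadings` (variable x component,
#'   orthonormal columns), `eigenvalues`,
#'   `explained_variance_ratio`, `preprocessing`, `data` (the input),
#'   and `blocks` (variable block labels, set by [joint_pca()]).
#' @export
run_pca <- function(x, preprocessing = c("center", "zscore")) {
  preprocessing <- match.arg(preprocessing)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two samples")
  if (ncol(x) < 2L) stop("need at least two variables")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (preprocessing == "zscore") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant variable(s) cannot be z-scored: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  xp <- scale(x, center = TRUE, scale = preprocessing == "zscore")
  S <- crossprod(xp) / (nrow(xp) - 1)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(x), paste0("PC", seq_len(ncol(vecs))))
  scores <- xp %*% vecs
  structure(list(scores = scores,
                 loadings = vecs,
                 eigenvalues = vals,
                 explained_variance_ratio = vals / sum(vals),
                 preprocessing = preprocessing,
                 data = x,
                 blocks = NULL),
            class = "aroma_pca")
}

#' @export
print.aroma_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf("PCA (%s): %d samples x %d variables\n", x$preprocessing,
              nrow(x$scores), nrow(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(evr))),
                    100 * evr[seq_len(min(3, length(evr)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Joint PCA of sensory attributes and compound abundances
#'
#' Column-concatenates a sample-by-attribute block of panel means and
#' a sample-by-compound block of abundances, z-scores every variable
#' across samples so the two blocks are commensurable, and runs
#' [run_pca()]. Block membership is carried in the result so
#' co-localization can pair compounds with attributes.
#'
#' @param sensory_means Sample-by-attribute numeric matrix.
#' @param compound_means Sample-by-compound numeric matrix over the
#'   same samples (rownames must match as sets).
#' @return An `aroma_pca` whose `blocks` element labels each variable
#'   `"attribute"` or `"compound"`.
#' @export
joint_pca <- function(sensory_means, compound_means) {
  sensory_means <- as.matrix(sensory_means)
  compound_means <- as.matrix(compound_means)
  if (is.null(rownames(sensory_means)) || is.null(rownames(compound_means))) {
    stop("both blocks need sample rownames")
  }
  if (!setequal(rownames(sensory_means), rownames(compound_means))) {
    stop("sample sets of the two blocks differ")
  }
  compound_means <- compound_means[rownames(sensory_means), , drop = FALSE]
  combined <- cbind(sensory_means, compound_means)
  res <- run_pca(combined, preprocessing = "zscore")
  res$blocks <- stats::setNames(
    rep(c("attribute", "compound"),
        c(ncol(sensory_means), ncol(compound_means))),
    colnames(combined))
  res
}

#' Loading-vector co-localization of variable pairs
#'
#' For each (compound, attribute) pair, measures (i) the angle theta
#' between the two variables' loading vectors restricted to the first
#' `n_components` principal components -- small angles mean the
#' variables contribute to the ordination along the same direction --
#' and (ii) the Pearson correlation r of their raw values across
#' samples. A pair is flagged co-localized when `theta < theta_max`
#' and `r > r_min`. With fewer than 5 samples the correlation has very
#' low power and the pair carries a `small_n` caveat flag.
#'
#' @param pca An `aroma_pca`, typically from [joint_pca()].
#' @param pairs Data frame with columns `compound` and `attribute`
#'   (variable names). Default `NULL`: all compound-by-attribute pairs
#'   of a joint PCA.
#' @param n_components Number of leading components defining the
#'   loading plane (default 2, matching 2-D loading plots).
#' @param theta_max Angle threshold in degrees (default 10).
#' @param r_min Correlation threshold (default 0.9).
#' @return Object of class `colocalization`: data frame with columns
#'   `compound`, `attribute`, `theta`, `r`, `n_samples`,
#'   `co_localized`, `small_n`.
#' @export
colocalize <- function(pca, pairs = NULL, n_components = 2,
                       theta_max = 10, r_min = 0.9) {
  stopifnot(inherits(pca, "aroma_pca"))
  if (n_components > ncol(pca$loadings)) {
    stop("n_components exceeds the available components")
  }
  if (is.null(pairs)) {
    if (is.null(pca$blocks)) {
      stop("`pairs` required when the PCA has no block labels")
    }
    pairs <- expand.grid(
      compound = names(pca$blocks)[pca$blocks == "compound"],
      attribute = names(pca$blocks)[pca$blocks == "attribute"],
      stringsAsFactors = FALSE)
  }
  missing <- setdiff(unique(c(pairs$compound, pairs$attribute)),
                     rownames(pca$loadings))
  if (length(missing)) {
    stop("variable(s) not in the PCA: ", paste(missing, collapse = ", "))
  }
  L <- pca$loadings[, seq_len(n_components), drop = FALSE]
  n_samples <- nrow(pca$scores)
  theta <- r <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    v1 <- L[pairs$compound[i], ]
    v2 <- L[pairs$attribute[i], ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) {
      stop("zero-length loading vector for pair ",
           pairs$compound[i], " / ", pairs$attribute[i])
    }
    cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
    theta[i] <- acos(cosang) * 180 / pi
    r[i] <- stats::cor(pca$data[, pairs$compound[i]],
                       pca$data[, pairs$attribute[i]])
  }
  out <- data.frame(compound = pairs$compound,
                    attribute = pairs$attribute,
                    theta = theta, r = r,
                    n_samples = n_samples,
                    co_localized = theta < theta_max & r > r_min,
                    small_n = n_samples < 5,
                    stringsAsFactors = FALSE)
  structure(out, class = c("colocalization", "data.frame"))
}

#' Agglomerative hierarchical clustering of matrix rows
#'
#' Thin deterministic wrapper over [stats::hclust()]: Euclidean or
#' Manhattan distance, or correlation dissimilarity (1 - r), with
#' average, complete, single, or Ward linkage. Leaf order and
#' tie-breaking are those of `hclust`, which are deterministic for a
#' given input ordering.
#'
#' @param x Numeric matrix; rows are clustered.
#' @param linkage `"average"` (default), `"complete"`, `"single"`,
#'   or `"ward"`.
#' @param metric `"euclidean"` (default), `"manhattan"`, or
#'   `"correlation"`.
#' @return Object of class `aroma_hclust`: list with `order`,
#'   `merge`, `height`, `labels`, and the underlying `hclust` object.
#' @export
hcluster <- function(x, linkage = c("average", "complete", "single", "ward"),
                     metric = c("euclidean", "manhattan", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two items to cluster")
  d <- switch(metric,
    euclidean = stats::dist(x, method = "euclidean"),
    manhattan = stats::dist(x, method = "manhattan"),
    correlation = stats::as.dist(1 - stats::cor(t(x)))
  )
  if (any(!is.finite(d))) stop("non-finite distances")
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(order = hc$order, merge = hc$merge, height = hc$height,
                 labels = hc$labels, hclust = hc),
            class = "aroma_hclust")
}

#' Z-score cluster heatmap decomposition
#'
#' Computes the row-standardized matrix and hierarchical orderings of
#' rows (compounds) and columns (samples) that back a cluster heatmap;
#' plotting is left to the caller (e.g. `stats::heatmap` or pheatmap).
#'
#' @param m Variable-by-sample numeric matrix (e.g. key-odorant mean
#'   abundances).
#' @param linkage,metric Passed to [hcluster()].
#' @return Object of class `cluster_heatmap`: list with `zmatrix`,
#'   `row_order`, `col_order`, `row_linkage`, `col_linkage`,
#'   `constant_rows`.
#' @export
cluster_heatmap <- function(m, linkage = "average", metric = "euclidean") {
  z <- zscore_rows(m)
  rowc <- hcluster(z, linkage = linkage, metric = metric)
  colc <- hcluster(t(z), linkage = linkage, metric = metric)
  structure(list(zmatrix = z,
                 row_order = rowc$order,
                 col_order = colc$order,
                 row_linkage = rowc,
                 col_linkage = colc,
                 constant_rows = attr(z, "constant_rows")),
            class = "cluster_heatmap")
}
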