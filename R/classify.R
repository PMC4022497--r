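# Building blocks of the two-round classifier: standardized (correlation)
# PCA, the seven-feature selection, deterministic restarted k-means with
# k = 2, and the rule mapping clusters to the FLIP/FunC categories.

#' Extract the numeric feature columns of a feature table
#'
#' Accepts either a plain numeric matrix/data frame of features or a table
#' produced by [ecr_feature_table()] (with `id`/`category`/`subcategory`
#' columns), and returns the numeric feature matrix in canonical column
#' order along with ids and labels when present.
#'
#' @param x Feature table, matrix or data frame.
#' @return A list with `values` (numeric matrix), `ids` (character) and
#'   `labels` (character or `NULL`).
#' @export
as_feature_matrix <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x)
  stopifnot(is.data.frame(x))
  feat <- intersect(ECR_FEATURES, names(x))
  if (length(feat) < 2L) {
    stop_input("no recognisable feature columns; expected some of: ",
               paste(ECR_FEATURES, collapse = ", "))
  }
  vals <- as.matrix(x[, feat, drop = FALSE])
  if (!is.numeric(vals)) stop_input("feature columns must be numeric")
  if (any(!is.finite(vals))) stop_input("feature matrix contains missing or non-finite values")
  ids <- if ("id" %in% names(x)) as.character(x$id) else as.character(seq_len(nrow(x)))
  labels <- if ("category" %in% names(x)) as.character(x$category) else NULL
  list(values = vals, ids = ids, labels = labels)
}

#' Drop the regression R^2 column before classification
#'
#' The coefficient of determination contributes little to overall feature
#' variance and is excluded from classification; the remaining seven
#' features are used.  Idempotent on an already-seven-feature input.
#'
#' @param x Feature matrix or data frame.
#' @return The input without the `r2_ddg` column.
#' @export
select_features <- function(x) {
  if (is.data.frame(x)) x[, setdiff(names(x), "r2_ddg"), drop = FALSE]
  else x[, setdiff(colnames(x), "r2_ddg"), drop = FALSE]
}

#' Standardized (correlation-matrix) PCA
#'
#' Each feature is z-scored (sample standard deviation, `n - 1`), and the
#' eigendecomposition of the resulting correlation matrix gives the
#' principal axes.  Scores are the standardized data projected onto the
#' eigenvectors.  Eigenvector signs are fixed so that each component's
#' largest-magnitude loading is positive (sign choice never affects
#' distances or cluster assignments).
#'
#' @param x Numeric feature matrix (rows = interfaces) with column names.
#' @return An object of class `ecr_pca`: `feature_names`, `center`, `scale`,
#'   `eigenvalues` (descending), `eigenvectors` (columns, orthonormal),
#'   `variance_fraction`, and `scores`.
#' @export
standardize_and_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_input("PCA needs at least 3 rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  bad <- !(is.finite(sdv) & sdv > 0)
  if (any(bad)) {
    stop_degenerate("zero-variance feature(s): ",
                    paste(colnames(x)[bad], collapse = ", "))
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  e <- eigen(stats::cor(x), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # deterministic sign convention
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- colnames(x)
  colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  scores <- z %*% vecs
  structure(list(feature_names = colnames(x),
                 center = mu, scale = sdv,
                 eigenvalues = vals,
                 eigenvectors = vecs,
                 variance_fraction = vals / sum(vals),
                 scores = scores),
            class = "ecr_pca")
}

#' @export
print.ecr_pca <- function(x, ...) {
  cat("Standardized PCA over", length(x$feature_names), "features;",
      "PC1+PC2 variance fraction:",
      sprintf("%.1f%%", 100 * sum(x$variance_fraction[1:2])), "\n")
  invisible(x)
}

.km_assign <- function(x, centers) {
  d2 <- .cross_dist2(x, centers)
  max.col(-d2, ties.method = "first")
}

#' Deterministic two-cluster k-means on PC scores
#'
#' Lloyd's algorithm with `restarts` random initializations (two distinct
#' data points each); the solution with the lowest within-cluster sum of
#' squares wins.  Fully deterministic given `seed`; the caller's RNG stream
#' is left untouched.  Clusters are relabelled so cluster 1 has the larger
#' first-coordinate centroid (ties: larger second coordinate).
#'
#' @param scores Numeric matrix of points (typically the `(PC1, PC2)`
#'   scores of an [standardize_and_pca()] fit).
#' @param seed Integer seed (default 1).
#' @param restarts Number of random restarts (default 50).
#' @param iter_max Maximum Lloyd iterations per restart (default 300).
#' @return An object of class `ecr_kmeans`: `assignments` (1/2 per row),
#'   `centroids` (2 x d), `inertia` (total within-cluster sum of squares),
#'   and `degenerate` (`TRUE` when all points coincide and a single cluster
#'   was returned duplicated).
#' @export
kmeans2 <- function(scores, seed = 1L, restarts = 50L, iter_max = 300L) {
  x <- as.matrix(scores)
  if (nrow(x) < 2L) stop_input("k-means with k = 2 needs at least 2 points")
  if (nrow(unique(x)) < 2L) {
    warning("all points identical; k-means degenerate (one empty cluster)",
            call. = FALSE)
    return(structure(list(assignments = rep(1L, nrow(x)),
                          centroids = rbind(x[1L, ], x[1L, ]),
                          inertia = 0, degenerate = TRUE,
                          seed = seed, restarts = restarts),
                     class = "ecr_kmeans"))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- x[sample.int(nrow(x), 2L), , drop = FALSE]
      if (all(init[1L, ] == init[2L, ])) next
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < 2L) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop_degenerate("k-means failed to find two non-empty clusters")
  # canonical label order: cluster 1 = larger first coordinate (then second)
  cen <- best$centers
  o <- order(-cen[, 1L], -cen[, ncol(cen)])
  relab <- match(seq_len(2L), o)
  structure(list(assignments = relab[best$cluster],
                 centroids = unname(cen[o, , drop = FALSE]),
                 inertia = best$tot.withinss,
                 degenerate = FALSE,
                 seed = seed, restarts = restarts),
            class = "ecr_kmeans")
}

#' Designate the FLIP cluster of a clustering
#'
#' FLIP interfaces correlate positively with `sum_ddg`, `n_hot` and
#' `avg_ddg` along PC1.  Each centroid is mapped back through the PCA
#' loadings to (approximate) standardized feature space, and the cluster
#' with the larger sum of reconstructed `sum_ddg + n_hot + avg_ddg` is
#' designated FLIP; exact ties are broken toward the larger reconstructed
#' `intcpt_ddg`.
#'
#' @param pca The `ecr_pca` the scores came from.
#' @param clustering An `ecr_kmeans` over the first score dimensions.
#' @return The index (1 or 2) of the FLIP-designated cluster.
#' @export
assign_flip_cluster <- function(pca, clustering) {
  stopifnot(inherits(pca, "ecr_pca"), inherits(clustering, "ecr_kmeans"))
  d <- ncol(clustering$centroids)
  V <- pca$eigenvectors[, seq_len(d), drop = FALSE]
  recon <- clustering$centroids %*% t(V)   # clusters x features (standardized)
  colnames(recon) <- pca$feature_names
  keyf <- intersect(c("sum_ddg", "n_hot", "avg_ddg"), pca$feature_names)
  s <- if (length(keyf) > 0L) rowSums(recon[, keyf, drop = FALSE]) else recon %*% rep(1, ncol(recon))
  if (s[1L] == s[2L] && "intcpt_ddg" %in% pca$feature_names) {
    s <- recon[, "intcpt_ddg"]
  }
  if (s[1L] == s[2L]) return(1L)  # fully symmetric; arbitrary but logged by caller
  which.max(s)
}
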