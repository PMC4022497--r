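# The two-round classifier: fitting, projection of new interfaces through
# the trained components, and plain-text model serialization.

#' Fit the two-round PCA + k-means interface classifier
#'
#' Round 1 standardizes the seven retained features, performs a
#' correlation-matrix PCA, and clusters the `(PC1, PC2)` scores with k-means
#' (k = 2).  Members of the FLIP-designated cluster are predicted FLIP and
#' removed; round 2 repeats the standardization, PCA and clustering on the
#' remaining interfaces, whose FLIP-designated cluster members are also
#' predicted FLIP.  Everything else is predicted FunC.
#'
#' @param x A feature table ([ecr_feature_table()] output, or any data frame
#'   / matrix containing the feature columns; `r2_ddg` is dropped
#'   automatically).
#' @param labels Optional character vector of `"FLIP"`/`"FunC"` training
#'   labels; defaults to the table's `category` column when present.
#'   Labels are used only for evaluation (and for cluster mapping when
#'   `map_by_labels = TRUE`); the clustering itself is unsupervised.
#' @param seed Integer seed controlling the k-means restarts (round 2 uses
#'   `seed + 1`).
#' @param restarts Random k-means restarts per round (default 50).
#' @param map_by_labels If `TRUE` and labels are available, the FLIP cluster
#'   of each round is the one with the larger fraction of FLIP labels,
#'   instead of the loading-based rule of [assign_flip_cluster()].
#' @return An object of class `ecr_fit` with elements `feature_names`,
#'   `round1`/`round2` (each `pca`, `kmeans`, `flip_cluster`; `round2` may
#'   be `NULL` when too few interfaces remain), `predictions` (data frame:
#'   `id`, `round`, `cluster`, `predicted`, `label`), `confusion` (list of
#'   `ecr_confusion` per round and total, when labels were given), `seed`,
#'   and `restarts`.
#' @seealso [predict.ecr_fit()], [summary.ecr_fit()], [ecr_write_model()]
#' @examples
#' ds <- generate_dataset(n_flip = 30, n_func = 20, seed = 7)
#' fit <- ecr_fit(ds$features, seed = 7)
#' summary(fit)
#' @export
ecr_fit <- function(x, labels = NULL, seed = 1L, restarts = 50L,
                    map_by_labels = FALSE) {
  fm <- as_feature_matrix(x)
  labels <- labels %||% fm$labels
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(fm$values)) {
      stop_input("labels length (", length(labels), ") does not match rows (",
                 nrow(fm$values), ")")
    }
  }
  X <- select_features(fm$values)
  if (nrow(X) < 6L) stop_input("training needs at least 6 interfaces")

  pick_flip <- function(pca, km, rows) {
    if (map_by_labels && !is.null(labels)) {
      fr <- vapply(1:2, function(k)
        mean(labels[rows][km$assignments == k] == "FLIP"), numeric(1L))
      if (fr[1L] == fr[2L]) assign_flip_cluster(pca, km) else which.max(fr)
    } else {
      assign_flip_cluster(pca, km)
    }
  }

  pca1 <- standardize_and_pca(X)
  vf2 <- sum(pca1$variance_fraction[1:2])
  if (vf2 <= 0.80) {
    warning(sprintf("first two principal components explain only %.1f%% of variance (<= 80%%)",
                    100 * vf2), call. = FALSE)
  }
  km1 <- kmeans2(pca1$scores[, 1:2, drop = FALSE], seed = seed, restarts = restarts)
  flip1 <- pick_flip(pca1, km1, seq_len(nrow(X)))

  n <- nrow(X)
  predicted <- rep(NA_character_, n)
  round_of <- integer(n)
  cluster_of <- km1$assignments
  in_flip1 <- km1$assignments == flip1
  predicted[in_flip1] <- "FLIP"
  round_of[in_flip1] <- 1L
  rest <- which(!in_flip1)
  round_of[rest] <- 2L

  round2 <- NULL
  if (length(rest) < 3L) {
    warning("fewer than 3 interfaces left for round 2; remainder predicted FunC",
            call. = FALSE)
    predicted[rest] <- "FunC"
  } else {
    round2 <- tryCatch({
      pca2 <- standardize_and_pca(X[rest, , drop = FALSE])
      km2 <- kmeans2(pca2$scores[, 1:2, drop = FALSE], seed = seed + 1L,
                     restarts = restarts)
      flip2 <- pick_flip(pca2, km2, rest)
      list(pca = pca2, kmeans = km2, flip_cluster = flip2)
    }, ecr_degenerate_error = function(e) {
      warning("round 2 skipped (", conditionMessage(e),
              "); remainder predicted FunC", call. = FALSE)
      NULL
    })
    if (is.null(round2)) {
      predicted[rest] <- "FunC"
    } else {
      cluster_of[rest] <- round2$kmeans$assignments
      predicted[rest] <- ifelse(round2$kmeans$assignments == round2$flip_cluster,
                                "FLIP", "FunC")
    }
  }

  confusion <- NULL
  if (!is.null(labels)) {
    r1 <- confusion_counts(predicted = ifelse(in_flip1, "FLIP", "FunC"),
                           truth = labels)
    confusion <- list(round1 = r1)
    if (!is.null(round2)) {
      confusion$round2 <- confusion_counts(predicted = predicted[rest],
                                           truth = labels[rest])
    }
    confusion$total <- confusion_counts(predicted = predicted, truth = labels)
  }

  structure(list(feature_names = colnames(X),
                 round1 = list(pca = pca1, kmeans = km1, flip_cluster = flip1),
                 round2 = round2,
                 predictions = data.frame(id = fm$ids,
                                          round = round_of,
                                          cluster = cluster_of,
                                          predicted = predicted,
                                          label = if (is.null(labels)) NA_character_ else labels,
                                          stringsAsFactors = FALSE),
                 confusion = confusion,
                 seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 map_by_labels = isTRUE(map_by_labels)),
            class = "ecr_fit")
}

#' @export
print.ecr_fit <- function(x, ...) {
  n <- nrow(x$predictions)
  n_flip <- sum(x$predictions$predicted == "FLIP")
  cat("Two-round PCA + k-means interface classifier (ecr_fit)\n")
  cat("  features: ", paste(x$feature_names, collapse = ", "), "\n", sep = "")
  cat(sprintf("  round 1: PC1+PC2 %.1f%% of variance; FLIP cluster %d\n",
              100 * sum(x$round1$pca$variance_fraction[1:2]),
              x$round1$flip_cluster))
  if (!is.null(x$round2)) {
    cat(sprintf("  round 2: %d interfaces; PC1+PC2 %.1f%% of variance; FLIP cluster %d\n",
                nrow(x$round2$pca$scores),
                100 * sum(x$round2$pca$variance_fraction[1:2]),
                x$round2$flip_cluster))
  } else {
    cat("  round 2: skipped\n")
  }
  cat(sprintf("  predictions: %d FLIP / %d FunC of %d interfaces\n",
              n_flip, n - n_flip, n))
  if (!is.null(x$confusion)) {
    cat(sprintf("  training accuracy %s, MCC %.2f\n",
                fmt_pct(accuracy(x$confusion$total)),
                round_half_up(mcc(x$confusion$total), 2)))
  }
  invisible(x)
}

#' Summarise a fitted classifier as a per-round evaluation table
#'
#' @param object An `ecr_fit` trained with labels.
#' @param ... Unused.
#' @return An `ecr_report` (see [ecr_report()]); printed in a per-round +
#'   total layout with accuracy and Matthews correlation coefficient.
#' @export
summary.ecr_fit <- function(object, ...) {
  if (is.null(object$confusion)) {
    cat("ecr_fit trained without labels; no evaluation available.\n")
    return(invisible(NULL))
  }
  ecr_report(object$confusion$round1, object$confusion[["round2"]])
}

#' Project new interfaces through a trained classifier
#'
#' Rows are standardized with the *training* means and standard deviations,
#' projected through the round-1 eigenvectors, and assigned to the nearest
#' round-1 centroid (Euclidean distance in the `(PC1, PC2)` plane).  Rows
#' not falling in the FLIP cluster are re-projected through the round-2
#' components and assigned to the nearest round-2 centroid.
#'
#' @param object An `ecr_fit`.
#' @param newdata Feature table with the same seven features (an eight-
#'   feature table is reduced automatically).
#' @param type `"class"` (default) for a character vector of
#'   `"FLIP"`/`"FunC"`, or `"table"` for a data frame with per-round
#'   cluster assignments.
#' @param ... Unused.
#' @return Predicted categories, named by interface id.
#' @export
predict.ecr_fit <- function(object, newdata, type = c("class", "table"), ...) {
  type <- match.arg(type)
  fm <- as_feature_matrix(newdata)
  X <- select_features(fm$values)
  if (!identical(colnames(X), object$feature_names)) {
    if (setequal(colnames(X), object$feature_names)) {
      X <- X[, object$feature_names, drop = FALSE]
    } else {
      stop_input("feature mismatch: model uses {",
                 paste(object$feature_names, collapse = ", "),
                 "} but data provides {", paste(colnames(X), collapse = ", "), "}")
    }
  }
  project_scores <- function(pca, X) {
    z <- sweep(sweep(X, 2L, pca$center), 2L, pca$scale, "/")
    (z %*% pca$eigenvectors)[, 1:2, drop = FALSE]
  }
  s1 <- project_scores(object$round1$pca, X)
  a1 <- .km_assign(s1, object$round1$kmeans$centroids)
  predicted <- rep(NA_character_, nrow(X))
  round_of <- integer(nrow(X))
  cluster_of <- a1
  in_flip1 <- a1 == object$round1$flip_cluster
  predicted[in_flip1] <- "FLIP"
  round_of[in_flip1] <- 1L
  rest <- which(!in_flip1)
  round_of[rest] <- 2L
  if (length(rest) > 0L) {
    if (is.null(object$round2)) {
      predicted[rest] <- "FunC"
    } else {
      s2 <- project_scores(object$round2$pca, X[rest, , drop = FALSE])
      a2 <- .km_assign(s2, object$round2$kmeans$centroids)
      cluster_of[rest] <- a2
      predicted[rest] <- ifelse(a2 == object$round2$flip_cluster, "FLIP", "FunC")
    }
  }
  if (type == "class") {
    stats::setNames(predicted, fm$ids)
  } else {
    data.frame(id = fm$ids, round = round_of, cluster = cluster_of,
               predicted = predicted, stringsAsFactors = FALSE)
  }
}

#' Plot the cluster structure of a fitted classifier
#'
#' Scatter of the training scores in the `(PC1, PC2)` plane for the chosen
#' round, with cluster centroids (crosses) and one-standard-deviation
#' circles of the Euclidean distances around each centroid (a plotting aid,
#' not a decision boundary).  Points are coloured by predicted category and
#' shaped by true label when available.
#'
#' @param x An `ecr_fit`.
#' @param round Which round to display (1 or 2).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted score matrix.
#' @export
plot.ecr_fit <- function(x, round = 1, ...) {
  rd <- if (round == 1) x$round1 else x$round2
  if (is.null(rd)) stop_input("round ", round, " is not available in this fit")
  s <- rd$pca$scores[, 1:2, drop = FALSE]
  asg <- rd$kmeans$assignments
  cols <- ifelse(asg == rd$flip_cluster, "forestgreen", "firebrick")
  graphics::plot(s, col = cols, pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = sprintf("Round %d clustering (FLIP cluster in green)", round),
                 ...)
  cen <- rd$kmeans$centroids
  graphics::points(cen, pch = 4, cex = 2, lwd = 2)
  th <- seq(0, 2 * pi, length.out = 200)
  for (k in 1:2) {
    d <- sqrt(rowSums(sweep(s[asg == k, , drop = FALSE], 2L, cen[k, ])^2))
    r <- stats::sd(d)
    if (is.finite(r) && r > 0) {
      graphics::lines(cen[k, 1L] + r * cos(th), cen[k, 2L] + r * sin(th),
                      lty = 2, col = if (k == rd$flip_cluster) "forestgreen" else "firebrick")
    }
  }
  invisible(s)
}

#' Serialize a fitted classifier to plain text
#'
#' Writes the complete model (standardization parameters, eigenvectors,
#' eigenvalues, centroids, FLIP cluster indices, seed and feature order) as
#' R source text with hexadecimal floating-point literals, so that
#' [ecr_read_model()] restores it bit-exactly.
#'
#' @param model An `ecr_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
ecr_write_model <- function(model, path) {
  stopifnot(inherits(model, "ecr_fit"))
  dput(model, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname ecr_write_model
#' @export
ecr_read_model <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: ", path)
  model <- dget(path)
  if (!inherits(model, "ecr_fit")) stop_input("'", path, "' is not a serialized ecr_fit model")
  model
}
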