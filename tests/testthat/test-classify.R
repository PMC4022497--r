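# Standardized PCA, deterministic k-means, FLIP-cluster designation, and
# the two-round fit/projection machinery.

test_that("correlation PCA handles analytic eigenstructures", {
  # two perfectly correlated features: eigenvalues {2, 0}
  set.seed(5)
  a <- rnorm(10)
  p <- standardize_and_pca(cbind(f1 = a, f2 = 3 * a + 1))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)

  # exactly uncorrelated unit-variance design: all eigenvalues 1
  x <- cbind(f1 = c(1, 1, -1, -1), f2 = c(1, -1, 1, -1), f3 = c(1, -1, -1, 1))
  pu <- standardize_and_pca(x)
  expect_equal(pu$eigenvalues, rep(1, 3), tolerance = 1e-12)

  # zero-variance feature is refused by name
  expect_error(standardize_and_pca(cbind(f1 = rnorm(5), dead = rep(2, 5))),
               regexp = "dead", class = "ecr_degenerate_error")
  expect_error(standardize_and_pca(matrix(rnorm(4), 2, 2)),
               class = "ecr_input_error")
})

test_that("PCA eigenpairs match an independent SVD oracle and conserve structure", {
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rnorm(12 * 7), 12, 7,
                dimnames = list(NULL, paste0("f", 1:7)))
    p <- standardize_and_pca(x)
    z <- scale(x)
    sv <- svd(z)
    expect_equal(p$eigenvalues, sv$d^2 / (nrow(x) - 1), tolerance = 1e-8)
    # orthonormality and reconstruction of the standardized data
    expect_equal(crossprod(p$eigenvectors), diag(7), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_lt(max(abs(p$scores %*% t(p$eigenvectors) - z)), 1e-8)
    # trace conservation: correlation eigenvalues sum to the feature count
    expect_equal(sum(p$eigenvalues), 7, tolerance = 1e-10)
  }
})

test_that("select_features drops r2_ddg and is idempotent", {
  ds <- generate_dataset(5, 5, seed = 3)
  fm <- as_feature_matrix(ds$features)
  expect_equal(colnames(fm$values), ECR_FEATURES)
  x7 <- select_features(fm$values)
  expect_equal(ncol(x7), 7L)
  expect_false("r2_ddg" %in% colnames(x7))
  expect_identical(select_features(x7), x7)
})

test_that("kmeans2 separates well-separated clouds and is deterministic", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(40, 10, 0.1), ncol = 2),
               matrix(rnorm(40, -10, 0.1), ncol = 2))
  km <- kmeans2(pts, seed = 1)
  expect_equal(km$assignments, rep(c(1L, 2L), each = 20))
  expect_false(km$degenerate)

  km_b <- kmeans2(pts, seed = 1)
  expect_identical(km, km_b)

  # all-identical points: flagged degenerate with an empty second cluster
  expect_warning(dg <- kmeans2(matrix(1, 5, 2)), "degenerate")
  expect_true(dg$degenerate)
  expect_equal(dg$inertia, 0)

  expect_error(kmeans2(matrix(1, 1, 2)), class = "ecr_input_error")
})

test_that("kmeans2 attains the exhaustive-enumeration global optimum for small n", {
  set.seed(17)
  for (n in 4:8) {
    for (rep in 1:3) {
      pts <- matrix(rnorm(2 * n, sd = 3), n, 2)
      km <- kmeans2(pts, seed = rep)
      bf <- kmeans2_bruteforce(pts)
      expect_equal(km$inertia, bf$inertia, tolerance = 1e-9)
      expect_true(same_partition(km$assignments, bf$assignments))
    }
  }
})

test_that("cluster assignments are invariant under eigenvector sign flips", {
  ds <- generate_dataset(20, 15, seed = 9)
  p <- standardize_and_pca(select_features(as_feature_matrix(ds$features)$values))
  s <- p$scores[, 1:2]
  km <- kmeans2(s, seed = 4)
  km_flipped <- kmeans2(s %*% diag(c(-1, 1)), seed = 4)
  expect_true(same_partition(km$assignments, km_flipped$assignments))
})

test_that("the FLIP-designated cluster is the energetically hot one, antisymmetrically", {
  ds <- generate_dataset(30, 20, seed = 12)
  fm <- as_feature_matrix(ds$features)
  X <- select_features(fm$values)
  p <- standardize_and_pca(X)
  km <- kmeans2(p$scores[, 1:2], seed = 1)
  flip <- assign_flip_cluster(p, km)
  # oracle: the cluster with the larger observed mean of sum_ddg
  means <- tapply(X[, "sum_ddg"], km$assignments, mean)
  expect_equal(flip, as.integer(names(which.max(means))))
  # majority of generator-labeled FLIPs sit in the designated cluster
  expect_gt(mean(km$assignments[fm$labels == "FLIP"] == flip), 0.5)

  # mirrored data: negating every feature flips the designation
  pm <- standardize_and_pca(-X)
  kmm <- kmeans2(pm$scores[, 1:2], seed = 1)
  flipm <- assign_flip_cluster(pm, kmm)
  expect_setequal(which(kmm$assignments == flipm),
                  which(km$assignments != flip))
})

test_that("two-round bookkeeping is exact and the training set recombines", {
  ds <- generate_dataset(40, 25, seed = 6)
  fit <- ecr_fit(ds$features, seed = 6)
  n1 <- sum(fit$predictions$round == 1L)
  n2 <- nrow(fit$round2$pca$scores)
  expect_equal(n1 + n2, nrow(ds$features))

  # removing round-1 cluster members and re-adding reproduces round-2 input:
  # the round-2 PCA de-standardizes back to exactly those feature rows
  X <- select_features(as_feature_matrix(ds$features)$values)
  rest <- which(fit$predictions$round == 2L)
  z2 <- fit$round2$pca$scores %*% t(fit$round2$pca$eigenvectors)
  x2 <- sweep(sweep(z2, 2L, fit$round2$pca$scale, "*"), 2L,
              fit$round2$pca$center, "+")
  expect_equal(unname(x2), unname(X[rest, , drop = FALSE]), tolerance = 1e-8)
})

test_that("projection through a trained model is self-consistent and validates features", {
  ds <- generate_dataset(30, 20, seed = 2)
  fit <- ecr_fit(ds$features, seed = 2)

  # projecting the training matrix reproduces training-time assignments
  pt <- predict(fit, ds$features, type = "table")
  expect_identical(pt$predicted, fit$predictions$predicted)
  expect_identical(pt$round, fit$predictions$round)

  # a row standardizing exactly onto a round-1 centroid lands in that cluster
  p1 <- fit$round1$pca
  cen <- fit$round1$kmeans$centroids[1, ]
  pre_image_z <- p1$eigenvectors[, 1:2] %*% cen      # standardized features
  row <- as.numeric(pre_image_z) * p1$scale + p1$center
  newdata <- as.data.frame(as.list(stats::setNames(row, p1$feature_names)))
  pr <- predict(fit, newdata, type = "table")
  expect_equal(pr$cluster[1], 1L)

  # feature mismatch is an input error
  bad <- ds$features[, setdiff(names(ds$features), c("sum_ddg", "r2_ddg"))]
  expect_error(predict(fit, bad), class = "ecr_input_error")
})

test_that("a held-out synthetic set projects with high accuracy", {
  train <- generate_dataset(100, 60, seed = 1)
  fit <- ecr_fit(train$features, seed = 1)
  holdout <- generate_dataset(100, 60, seed = 2)
  pred <- predict(fit, holdout$features)
  expect_gte(mean(pred == holdout$features$category), 0.85)
})

test_that("label-majority cluster mapping matches the loading rule on separable data", {
  ds <- generate_dataset(30, 20, seed = 4)
  f_rule <- ecr_fit(ds$features, seed = 4)
  f_lab <- ecr_fit(ds$features, seed = 4, map_by_labels = TRUE)
  expect_identical(f_rule$predictions$predicted, f_lab$predictions$predicted)
})

test_that("model serialization round-trips bit-exactly", {
  ds <- generate_dataset(15, 10, seed = 8)
  fit <- ecr_fit(ds$features, seed = 8)
  path <- tempfile(fileext = ".ecr")
  ecr_write_model(fit, path)
  back <- ecr_read_model(path)
  expect_identical(back, fit)
  expect_identical(predict(back, ds$features), predict(fit, ds$features))
  expect_error(ecr_read_model(tempfile()), class = "ecr_input_error")
})
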