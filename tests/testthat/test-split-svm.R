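test_that("semi-supervised distance masks the target part for unlabeled", {
  cen <- list(x_part = c(0), y_part = c(0))
  # labeled example at the centroid
  expect_equal(ss_distance(0, 0, cen, p = c(0.5, 0.5), labeled = TRUE), 0)
  # hand evaluation: 0.5 * 2^2 + 0.5 * 1^2
  expect_equal(ss_distance(2, 1, cen, p = c(0.5, 0.5), labeled = TRUE), 2.5)
  # unlabeled: the target part of the centroid is irrelevant
  cen2 <- list(x_part = c(0), y_part = c(99))
  expect_equal(ss_distance(2, NULL, cen2, p = c(0.5, 0.5), labeled = FALSE),
               ss_distance(2, NULL, cen, p = c(0.5, 0.5), labeled = FALSE))
  expect_error(ss_distance(c(1, 2), 0, cen, c(0.5, 0.5), TRUE), "mismatch")
})

test_that("2-means recovers well-separated groups", {
  set.seed(21)
  Xs <- rbind(matrix(rnorm(20, -10), 10, 2), matrix(rnorm(20, 10), 10, 2))
  Ys <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  p <- scale_clustering_weights(rep(1, 3), 2, 0.5)$p
  km <- kmeans_semisupervised(Xs, Ys, p, iters = 10)
  s <- km$s
  expect_true(all(s[1:10] == s[1]) && all(s[11:20] == s[11]) && s[1] != s[11])
})

test_that("2-means within-cluster distance never increases", {
  set.seed(22)
  for (r in 1:30) {
    n <- sample(15:40, 1); L <- sample(4:n, 1)
    D <- sample(2:5, 1); Tn <- sample(1:3, 1)
    Xs <- matrix(rnorm(n * D), n, D)
    Ys <- matrix(rnorm(L * Tn), L, Tn)
    p <- scale_clustering_weights(runif(D + Tn) + 0.05, D, runif(1))$p
    km <- kmeans_semisupervised(Xs, Ys, p, iters = 10)
    # monotone except immediately after a labeled-starved cluster re-seed
    steps_up <- which(diff(km$objective) > 1e-9) + 1L
    expect_true(all(steps_up %in% km$reseeds))
  }
})

test_that("2-means signals unsplittable nodes", {
  Xs <- matrix(1, 4, 2) # all labeled rows identical in joint space
  Ys <- matrix(0, 4, 1)
  p <- scale_clustering_weights(rep(1, 3), 2, 0.5)$p
  set.seed(1)
  expect_null(kmeans_semisupervised(Xs, Ys, p))
  expect_null(kmeans_semisupervised(Xs[1, , drop = FALSE],
                                    Ys[1, , drop = FALSE], p))
})

test_that("svm objective matches hand computations", {
  Xs <- matrix(rnorm(8), 4, 2)
  y <- c(-1, 1, -1, 1)
  # zero hyperplane: every squared hinge term is 1
  expect_equal(svm_objective(c(0, 0), 0, Xs, y, C = 10), 40)
  # all margins >= 1 leaves only the L1 term
  Xsep <- matrix(c(-2, 2, -3, 3), ncol = 1)
  expect_equal(svm_objective(1, 0, Xsep, c(-1, 1, -1, 1), C = 10), 1)
  # monotone in C
  w <- c(0.3, -0.2)
  expect_gte(svm_objective(w, 0.1, Xs, y, C = 20),
             svm_objective(w, 0.1, Xs, y, C = 10))
})

test_that("svm split separates a linearly separable toy", {
  set.seed(31)
  Xs <- matrix(c(rnorm(12, -10), rnorm(12, 10)), ncol = 1) / 10
  Ys <- matrix(c(rep(-1, 12), rep(1, 12)), ncol = 1)
  p <- scale_clustering_weights(rep(1, 2), 1, 0.5)$p
  cfg <- split_config("svm", omega = 0.5)
  sp <- learn_split_svm(Xs, Ys, p, cfg)
  side <- as.numeric(Xs %*% sp$w + sp$b >= 0)
  expect_true(all(side[1:12] == side[1]) && side[1] != side[13])
})

test_that("svm split is deterministic and degenerates to no-split", {
  set.seed(41)
  Xs <- matrix(rnorm(30), 15, 2)
  Ys <- matrix(rnorm(15), ncol = 1)
  p <- scale_clustering_weights(rep(1, 3), 2, 0.5)$p
  cfg <- split_config("svm", omega = 0.5)
  set.seed(7); a <- learn_split_svm(Xs, Ys, p, cfg)
  set.seed(7); b <- learn_split_svm(Xs, Ys, p, cfg)
  expect_identical(a, b)
  # identical examples cannot be split
  set.seed(8)
  expect_null(learn_split_svm(matrix(0, 6, 2), matrix(0, 6, 1), p, cfg))
})
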