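test_that("a one-tree ensemble without bootstrap equals the single tree", {
  set.seed(161)
  gen <- gen_clustered("STR", n = 80, D = 4, n_clusters = 2, separation = 4,
                       seed = 21)
  ds <- mask_labels(gen$data, L = 40, seed = 22)
  cfg <- split_config("grad", omega = 0.5, seed = 23)
  fo <- spyct_forest(ds, cfg, n_trees = 1, bootstrap = FALSE)
  cfg1 <- cfg
  cfg1$seed <- fo$trees[[1]]$config$seed
  tr <- spyct(ds, cfg1)
  Xn <- matrix(rnorm(40), 10, 4)
  expect_identical(predict(fo, Xn), predict(tr, Xn))
})

test_that("stratified bootstraps keep L labeled and U unlabeled draws", {
  set.seed(171)
  gen <- gen_clustered("BC", n = 60, D = 3, n_clusters = 2, separation = 4,
                       seed = 24)
  ds <- mask_labels(gen$data, L = 12, seed = 25)
  fo <- spyct_forest(ds, split_config("grad", omega = 0.5, seed = 26),
                     n_trees = 8)
  for (tr in fo$trees) {
    expect_equal(tr$n_train, 60)
    # every tree must have been able to form labeled leaves
    for (lf in collect_leaves(tr)) expect_gte(lf$n_labeled, 1)
  }
  # different ensemble seeds give different bootstraps, hence different fits
  fo2 <- spyct_forest(ds, split_config("grad", omega = 0.5, seed = 27),
                      n_trees = 8)
  Xn <- as.matrix(ds$X)
  expect_false(identical(predict(fo, Xn), predict(fo2, Xn)))
})

test_that("ensemble scores are means bounded by member scores", {
  set.seed(181)
  gen <- gen_clustered("MTR", n = 90, D = 4, n_clusters = 3, separation = 4,
                       seed = 28)
  ds <- mask_labels(gen$data, L = 45, seed = 29)
  fo <- spyct_forest(ds, split_config("grad", omega = 0.5, seed = 30),
                     n_trees = 5)
  Xn <- matrix(rnorm(60), 15, 4)
  sc <- predict(fo, Xn)
  member <- lapply(fo$trees, predict, newdata = Xn)
  lo <- Reduce(pmin, member)
  hi <- Reduce(pmax, member)
  expect_true(all(sc >= lo - 1e-12 & sc <= hi + 1e-12))
  expect_equal(sc, Reduce(`+`, member) / 5, tolerance = 1e-12)
})

test_that("feature importances follow the hyperplane-weight formula", {
  # hand-built tree: single root split with w = (3, -1) over 8 examples
  leaf <- list(leaf = TRUE, prototype = 0, n_labeled = 4, n_examples = 4)
  tree <- structure(
    list(root = list(leaf = FALSE, w = c(3, -1), b = 0, mu = c(0, 0),
                     sigma = c(1, 1), center = TRUE, n_examples = 8,
                     left = leaf, right = leaf),
         task = "STR", config = split_config("grad", omega = 1),
         label_order = "y", D = 2L, T = 1L, n_train = 8L, hierarchy = NULL),
    class = "spyct_tree"
  )
  expect_equal(feature_importance(tree), c(0.75, 0.25))
  # leaf-only tree scores zero
  tree0 <- tree
  tree0$root <- leaf
  expect_equal(feature_importance(tree0), c(0, 0))
})

test_that("fitted-tree importances satisfy the node-count identity", {
  set.seed(191)
  gen <- gen_clustered("BC", n = 150, D = 5, n_clusters = 2, separation = 4,
                       seed = 31)
  ds <- mask_labels(gen$data, L = 75, seed = 32)
  tr <- spyct(ds, split_config("grad", omega = 0.5, seed = 33))
  imp <- feature_importance(tr)
  expect_true(all(imp >= 0))
  # sum over features == sum over split nodes of s_n / N, exactly
  N <- tr$root$n_examples
  node_sum <- 0
  walk <- function(node) {
    if (node$leaf) return(invisible(NULL))
    node_sum <<- node_sum + node$n_examples / N
    walk(node$left); walk(node$right)
  }
  walk(tr$root)
  expect_equal(sum(imp), node_sum, tolerance = 1e-12)
  # ensembles average member importances
  fo <- spyct_forest(ds, split_config("grad", omega = 0.5, seed = 34),
                     n_trees = 3)
  expect_equal(feature_importance(fo),
               rowMeans(vapply(fo$trees, feature_importance, numeric(5))))
})
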