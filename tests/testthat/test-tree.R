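test_that("degenerate datasets yield a single-leaf tree", {
  X <- matrix(rnorm(8), 4, 2)
  ds <- semi_dataset(X, matrix(2.5, 1, 1), "STR") # one labeled example
  tr <- spyct(ds, split_config("grad", omega = 0.5, seed = 1))
  expect_equal(tree_depth(tr), 0)
  expect_equal(as.numeric(predict(tr, X)), rep(2.5, 4))
})

test_that("max_depth caps the number of splits on a path", {
  set.seed(101)
  ds <- toy_separable(n_per = 20, L = 30)
  tr <- spyct(ds, split_config("grad", omega = 0.5, max_depth = 1, seed = 2))
  expect_lte(tree_depth(tr), 1)
  tr0 <- spyct(ds, split_config("grad", omega = 0.5, max_depth = 0, seed = 2))
  expect_equal(tree_depth(tr0), 0)
})

test_that("leaf prototypes are column means of raw labeled targets", {
  # depth-0 tree: prototype must be the global labeled mean
  X <- matrix(rnorm(6), 3, 2)
  Y <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)) # one-hot class labels
  colnames(Y) <- c("a", "b", "c")
  ds <- semi_dataset(X, Y, "MCC")
  tr <- spyct(ds, split_config("grad", omega = 1, max_depth = 0, seed = 3))
  expect_equal(unname(predict(tr, X)[1, ]), unname(colMeans(Y)))
  # class proportions decode by argmax, ties to the lowest column index
  expect_equal(unname(predict(tr, X, type = "response")),
               rep(colnames(Y)[which.max(colMeans(Y))], 3))
})

test_that("separable clusters are routed to their own prototypes", {
  set.seed(111)
  ds <- toy_separable(n_per = 25, L = 20)
  for (v in c("grad", "svm")) {
    tr <- spyct(ds, split_config(v, omega = 0.5, seed = 4))
    pred <- predict(tr, matrix(c(-10, 10), ncol = 1), type = "response")
    expect_equal(pred, c(0, 1))
  }
})

test_that("training examples reproduce their leaf's prototype", {
  set.seed(121)
  gen <- gen_clustered("MTR", n = 80, D = 4, n_clusters = 3, separation = 5,
                       seed = 9)
  ds <- mask_labels(gen$data, L = 40, seed = 10)
  tr <- spyct(ds, split_config("grad", omega = 0.5, seed = 11))
  sc <- predict(tr, as.matrix(ds$X))
  leaves <- collect_leaves(tr)
  protos <- unname(unique(do.call(rbind, lapply(leaves, function(l)
    unname(l$prototype)))))
  for (i in seq_len(nrow(sc))) {
    expect_true(any(apply(protos, 1, function(p)
      isTRUE(all.equal(p, unname(sc[i, ]), tolerance = 1e-12)))))
  }
})

test_that("every leaf keeps at least min_leaf_labeled labeled examples", {
  set.seed(131)
  gen <- gen_clustered("BC", n = 120, D = 5, n_clusters = 2, separation = 3,
                       seed = 12)
  ds <- mask_labels(gen$data, L = 60, seed = 13)
  for (mll in c(1L, 5L)) {
    tr <- spyct(ds, split_config("grad", omega = 0.5,
                                 min_leaf_labeled = mll, seed = 14))
    for (lf in collect_leaves(tr)) expect_gte(lf$n_labeled, mll)
  }
})

test_that("tree growth is deterministic given data, config and seed", {
  set.seed(141)
  gen <- gen_clustered("STR", n = 100, D = 4, n_clusters = 2, separation = 4,
                       seed = 15)
  ds <- mask_labels(gen$data, L = 50, seed = 16)
  for (v in c("grad", "svm")) {
    t1 <- spyct(ds, split_config(v, omega = 0.5, seed = 17))
    t2 <- spyct(ds, split_config(v, omega = 0.5, seed = 17))
    expect_identical(tree_structure(t1), tree_structure(t2))
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    save_model(t1, f1); save_model(t2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("prediction rejects mismatched feature counts", {
  ds <- toy_separable(n_per = 10, L = 10)
  tr <- spyct(ds, split_config("grad", omega = 1, seed = 18))
  expect_error(predict(tr, matrix(0, 2, 3)), "columns")
})

test_that("trees fit on sparse feature matrices", {
  set.seed(151)
  gen <- gen_clustered("BC", n = 150, D = 6, n_clusters = 2, separation = 5,
                       sparsity = 0.4, seed = 19)
  Xsp <- Matrix::Matrix(gen$data$X, sparse = TRUE)
  ds <- semi_dataset(Xsp, gen$data$Y, "BC")
  tr <- spyct(ds, split_config("grad", omega = 0.5, seed = 20))
  acc <- mean(predict(tr, as.matrix(Xsp), type = "response") ==
                gen$data$Y[, 1])
  expect_gte(acc, 0.9)
})
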