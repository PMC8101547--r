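test_that("target encodings follow each task's canonical form", {
  # one-hot over sorted classes
  expect_equal(unname(encode_targets(c("b", "a", "b"), "MCC")),
               matrix(c(0, 1, 0, 1, 0, 1), ncol = 2))
  expect_equal(colnames(encode_targets(c("b", "a", "b"), "MCC")), c("a", "b"))
  # regression passes through
  expect_equal(unname(encode_targets(c(1.5, -2.0), "STR")),
               matrix(c(1.5, -2.0), ncol = 1))
  # binary from class labels: second sorted class is positive
  expect_equal(as.numeric(encode_targets(c("no", "yes", "no"), "BC")),
               c(0, 1, 0))
  # unknown class against a fixed class set
  expect_error(encode_targets(c("a", "z"), "MCC", classes = c("a", "b")),
               "unknown class")
  # multi-label from sets
  Y <- encode_targets(list(c("l1", "l2"), "l2"), "MLC")
  expect_equal(unname(Y), matrix(c(1, 0, 1, 1), ncol = 2))
})

test_that("hierarchy-inconsistent label sets are rejected by name", {
  hier <- hierarchy_spec(c("parent", "child"),
                         data.frame(parent = "parent", child = "child"))
  expect_error(encode_targets(list("child"), "HMLC", hierarchy = hier),
               "child")
  ok <- encode_targets(list(c("parent", "child"), "parent"), "HMLC",
                       hierarchy = hier)
  expect_equal(unname(ok), matrix(c(1, 1, 1, 0), ncol = 2))
})

test_that("standardization centers and scales with the population sd", {
  M <- matrix(c(2, 4), ncol = 1)
  st <- standardize_fit(M)
  expect_equal(st$mu, 3)
  expect_equal(st$sigma, 1) # population sd of {2, 4}
  expect_equal(as.numeric(standardize_apply(M, st)), c(-1, 1))
  # zero-variance columns map to zeros with sigma recorded as 1
  Mc <- matrix(5, 3, 1)
  stc <- standardize_fit(Mc)
  expect_equal(stc$sigma, 1)
  expect_equal(as.numeric(standardize_apply(Mc, stc)), c(0, 0, 0))
  expect_error(standardize_fit(M, rows = integer()), "empty")
})

test_that("standardization round-trips and is reproducible", {
  set.seed(3)
  M <- matrix(rnorm(60, sd = 4, mean = 7), 12, 5)
  st <- standardize_fit(M)
  Ms <- standardize_apply(M, st)
  expect_equal(colMeans(Ms), rep(0, 5), tolerance = 1e-12)
  expect_equal(standardize_invert(Ms, st), M, tolerance = 1e-10)
  expect_identical(standardize_apply(M, st), Ms)
})

test_that("sparse features are scaled without centering", {
  X <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(4, 6),
                            dims = c(4, 2))
  st <- standardize_fit(X)
  expect_false(st$center)
  Xs <- standardize_apply(X, st)
  expect_s4_class(Xs, "Matrix")
  expect_equal(sum(Xs == 0), sum(X == 0)) # sparsity pattern preserved
})

test_that("clustering weights split mass 1-omega / omega between blocks", {
  cw <- scale_clustering_weights(c(1, 1, 1), D = 2, omega = 0.75)
  expect_equal(cw$p, c(0.125, 0.125, 0.75))
  expect_equal(scale_clustering_weights(c(1, 1, 1), 2, 1)$p[1:2], c(0, 0))
  expect_equal(scale_clustering_weights(c(1, 1, 1), 2, 0)$p[3], 0)
  expect_error(scale_clustering_weights(c(-1, 1, 1), 2, 0.5), "nonnegative")
  # block sums and idempotence over random cases
  set.seed(11)
  for (r in 1:25) {
    D <- sample(1:6, 1); Tn <- sample(1:4, 1); om <- runif(1)
    p0 <- runif(D + Tn) + 0.01
    p1 <- scale_clustering_weights(p0, D, om)$p
    expect_equal(sum(p1[1:D]), 1 - om, tolerance = 1e-12)
    expect_equal(sum(p1[-(1:D)]), om, tolerance = 1e-12)
    expect_equal(scale_clustering_weights(p1, D, om)$p, p1, tolerance = 1e-12)
  }
})

test_that("hierarchy depths and 0.75^d weights follow the parent-mean rule", {
  chain <- hierarchy_spec(c("r", "a", "b"),
                          data.frame(parent = c("r", "a"),
                                     child = c("a", "b")))
  expect_equal(unname(chain$depth), c(1, 2, 3))
  expect_equal(unname(chain$label_weight), c(0.75, 0.5625, 0.421875))
  # DAG: parents at depths 1 and 2 average to 2.5
  dag <- hierarchy_spec(c("r", "a", "m"),
                        data.frame(parent = c("r", "r", "a"),
                                   child = c("a", "m", "m")))
  expect_equal(unname(dag$depth["m"]), 2.5)
  expect_equal(unname(dag$label_weight["m"]), 0.75^2.5, tolerance = 1e-9)
  # degenerate base gives flat weights
  expect_equal(unname(hierarchy_weights(chain, w0 = 1)), c(1, 1, 1))
  expect_error(
    hierarchy_spec(c("a", "b"),
                   data.frame(parent = c("a", "b"), child = c("b", "a"))),
    "cycle"
  )
})

test_that("hierarchy weights strictly decrease towards the leaves", {
  for (s in 1:5) {
    hier <- gen_hierarchy(12, depth = 4, seed = s)
    for (e in seq_len(nrow(hier$edges))) {
      expect_lt(hier$label_weight[hier$edges$child[e]],
                hier$label_weight[hier$edges$parent[e]])
    }
  }
})

test_that("semi_dataset enforces labeled-first shape and task invariants", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(semi_dataset(X, matrix(c(0, 1, 2), ncol = 1), "BC"), "0/1")
  expect_error(semi_dataset(X, matrix(c(1, 1, 0, 1), 2, 2), "MCC"), "one-hot")
  ds <- semi_dataset(X, matrix(c(0, 1, 1), ncol = 1), "BC")
  expect_equal(ds$L, 3)
  expect_equal(ds$U, 2)
})
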