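# Shared fixtures, built in code.

# Two well-separated 1-D clusters with matching binary targets.
toy_separable <- function(n_per = 10, gap = 10, L = NULL) {
  X <- matrix(c(rnorm(n_per, -gap), rnorm(n_per, gap)), ncol = 1)
  y <- c(rep(0, n_per), rep(1, n_per))
  ord <- sample(2 * n_per) # shuffle so clusters are not index-contiguous
  ds_full <- semi_dataset(X[ord, , drop = FALSE],
                          matrix(y[ord], ncol = 1, dimnames = list(NULL, "y")),
                          task = "BC")
  if (is.null(L)) ds_full else mask_labels(ds_full, L)
}

# Split/leaf skeleton of a tree, ignoring prototypes (for structure
# comparisons under target permutations).
tree_structure <- function(tree) {
  strip <- function(node) {
    if (node$leaf) return(list(leaf = TRUE, n = node$n_examples))
    list(leaf = FALSE, w = node$w, b = node$b,
         left = strip(node$left), right = strip(node$right))
  }
  strip(tree$root)
}

# Two-pass definitional weighted variance: sum a_i (v_i - mean)^2 / A.
wvar_two_pass <- function(v, a) {
  A <- sum(a)
  if (A <= 0) return(0)
  m <- sum(a * v) / A
  sum(a * (v - m)^2) / A
}

# Brute-force LRAP by explicit pairwise counting.
lrap_brute <- function(Y, S, w = rep(1, ncol(Y))) {
  n <- nrow(Y)
  vals <- c()
  for (i in seq_len(n)) {
    true_j <- which(Y[i, ] == 1)
    if (length(true_j) == 0) next
    Wi <- sum(w[true_j])
    acc <- 0
    for (j in true_j) {
      Rij <- 0
      Lij <- 0
      for (k in seq_len(ncol(Y))) {
        if (S[i, k] >= S[i, j]) {
          Rij <- Rij + 1
          if (Y[i, k] == 1) Lij <- Lij + 1
        }
      }
      acc <- acc + w[j] / Wi * Lij / Rij
    }
    vals <- c(vals, acc)
  }
  mean(vals)
}

# Walk a tree collecting leaf fields.
collect_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (node$leaf) {
      out[[length(out) + 1L]] <<- node
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  out
}
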