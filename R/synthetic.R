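#' Generate clustered synthetic data satisfying the cluster assumption
#'
#' Produces a fully labeled dataset whose feature-space clusters align with
#' the targets — the structure the semi-supervised method exploits.
#' Cluster centers sit at the vertices of a scaled simplex so every pair of
#' centers is `separation` apart (in units of the within-cluster standard
#' deviation, which is 1); features are the center plus unit Gaussian
#' noise. Targets are deterministic per cluster: the cluster id (mod 2) for
#' BC, one-hot cluster id for MCC, a fixed random subset of `ceiling(T/2)`
#' labels per cluster for MLC, a hierarchy-consistent path of labels per
#' cluster for HMLC, and a cluster-specific linear response plus noise for
#' STR/MTR. Optionally a fraction of the features carries no cluster signal
#' (`noise_frac`) and a fraction of entries is zeroed (`sparsity`).
#'
#' @param task Task name.
#' @param n Number of examples.
#' @param D Number of features.
#' @param T Number of target columns (defaults per task: 1 for BC/STR,
#'   `n_clusters` for MCC, 6 for MLC, 7 for HMLC, 3 for MTR).
#' @param n_clusters Number of clusters (must not exceed `n`).
#' @param separation Between-center distance in within-cluster sd units.
#' @param noise_frac Fraction of features carrying no cluster signal.
#' @param sparsity Fraction of feature entries set to zero.
#' @param hierarchy Optional `spyct_hierarchy` (HMLC); generated with
#'   [gen_hierarchy()] when omitted.
#' @param hierarchy_depth Depth of the generated hierarchy (HMLC).
#' @param seed Optional seed; identical seeds give identical output.
#' @return List with `data` (a fully labeled [semi_dataset()]) and
#'   `cluster` (true cluster id per example).
#' @export
gen_clustered <- function(task = c("BC", "MCC", "MLC", "HMLC", "STR", "MTR"),
                          n = 500L, D = 10L, T = NULL, n_clusters = 2L,
                          separation = 4, noise_frac = 0, sparsity = 0,
                          hierarchy = NULL, hierarchy_depth = 3L,
                          seed = NULL) {
  task <- match.arg(task)
  stopifnot(n >= 1, D >= 1, n_clusters >= 1, separation >= 0,
            noise_frac >= 0, noise_frac <= 1, sparsity >= 0, sparsity < 1)
  if (n_clusters > n) stop("n_clusters must not exceed n")
  if (is.null(T)) {
    T <- switch(task, BC = 1L, STR = 1L, MCC = n_clusters, MLC = 6L,
                HMLC = 7L, MTR = 3L)
  }
  if (!is.null(seed)) set.seed(seed)
  K <- n_clusters
  D_inf <- max(1L, round(D * (1 - noise_frac)))

  # simplex vertices: separation/sqrt(2) * e_c gives pairwise distance
  # `separation`; falls back to random directions when D_inf < K
  centers <- matrix(0, K, D)
  if (K > 1L) {
    if (D_inf >= K) {
      for (c in seq_len(K)) centers[c, c] <- separation / sqrt(2)
    } else {
      dirs <- matrix(stats::rnorm(K * D_inf), K, D_inf)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      centers[, seq_len(D_inf)] <- dirs * separation / sqrt(2)
    }
  }

  cid <- sample.int(K, n, replace = TRUE)
  X <- centers[cid, , drop = FALSE] + matrix(stats::rnorm(n * D), n, D)
  if (sparsity > 0) X[matrix(stats::runif(n * D) < sparsity, n, D)] <- 0
  colnames(X) <- paste0("x", seq_len(D))

  hier <- NULL
  Y <- switch(task,
    BC = matrix(as.numeric((cid - 1) %% 2), ncol = 1L,
                dimnames = list(NULL, "y")),
    MCC = {
      stopifnot(T >= K)
      Ym <- matrix(0, n, T, dimnames = list(NULL, paste0("c", seq_len(T))))
      Ym[cbind(seq_len(n), cid)] <- 1
      Ym
    },
    MLC = {
      k_on <- ceiling(T / 2)
      sets <- lapply(seq_len(K), function(c) sort(sample.int(T, k_on)))
      Ym <- matrix(0, n, T, dimnames = list(NULL, paste0("l", seq_len(T))))
      for (i in seq_len(n)) Ym[i, sets[[cid[i]]]] <- 1
      Ym
    },
    HMLC = {
      hier <- if (is.null(hierarchy)) {
        gen_hierarchy(T, depth = hierarchy_depth)
      } else {
        hierarchy
      }
      T <- length(hier$labels)
      # per cluster: one random label plus all its ancestors
      anc <- .ancestor_closure(hier)
      picks <- sample.int(T, K, replace = K > T)
      Ym <- matrix(0, n, T, dimnames = list(NULL, hier$labels))
      for (i in seq_len(n)) Ym[i, anc[[picks[cid[i]]]]] <- 1
      Ym
    },
    STR = ,
    MTR = {
      Tn <- if (task == "STR") 1L else T
      a <- matrix(stats::rnorm(K * Tn), K, Tn) * separation
      B <- matrix(stats::rnorm(K * Tn * D_inf), K * Tn, D_inf)
      Ym <- matrix(0, n, Tn)
      for (t in seq_len(Tn)) {
        Bc <- matrix(B[(t - 1) * K + seq_len(K), , drop = FALSE],
                     K, D_inf) / sqrt(D_inf)
        resid <- X[, seq_len(D_inf), drop = FALSE] -
          centers[cid, seq_len(D_inf), drop = FALSE]
        Ym[, t] <- a[cid, t] + rowSums(resid * Bc[cid, , drop = FALSE]) * 0.5 +
          stats::rnorm(n, sd = 0.1)
      }
      colnames(Ym) <- paste0("y", seq_len(Tn))
      Ym
    }
  )
  ds <- semi_dataset(X, Y, task = task, hierarchy = hier)
  list(data = ds, cluster = cid)
}

# Per-label index set {label + all ancestors}, by hierarchy order.
.ancestor_closure <- function(hier) {
  labs <- hier$labels
  parents <- split(hier$edges$parent, factor(hier$edges$child, levels = labs))
  lapply(seq_along(labs), function(i) {
    seen <- character()
    frontier <- labs[i]
    while (length(frontier) > 0L) {
      seen <- union(seen, frontier)
      frontier <- unique(unlist(parents[frontier], use.names = FALSE))
      frontier <- setdiff(frontier, seen)
    }
    match(seen, labs)
  })
}

#' Double the feature set with standard-normal noise features
#'
#' Appends one independently sampled standard-normal feature per original
#' feature, so the feature count doubles; the original columns are
#' unchanged. The indices of the added columns are recorded in the
#' `"noise_cols"` attribute.
#'
#' @param X Feature matrix.
#' @param seed Optional seed.
#' @return Matrix with `2 * ncol(X)` columns.
#' @export
add_noise_features <- function(X, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  D <- ncol(X)
  noise <- matrix(stats::rnorm(nrow(X) * D), nrow(X), D)
  colnames(noise) <- paste0("noise", seq_len(D))
  out <- cbind(X, noise)
  attr(out, "noise_cols") <- D + seq_len(D)
  out
}

#' Mask labels of a fully labeled dataset
#'
#' Uniformly samples `L` examples to keep their labels; the rest become
#' unlabeled. Rows are reordered labeled-first and the permutation back to
#' the original row order is kept in the result's `perm` field.
#'
#' @param data_full A fully labeled [semi_dataset()].
#' @param L Number of examples to keep labeled (`1 <= L <= n`).
#' @param seed Optional seed.
#' @return A [semi_dataset()] with `L` labeled and `n - L` unlabeled rows.
#' @export
mask_labels <- function(data_full, L, seed = NULL) {
  stopifnot(inherits(data_full, "semi_dataset"))
  if (data_full$U != 0L) stop("mask_labels expects a fully labeled dataset")
  n <- data_full$L
  if (L < 1L || L > n) stop("L must be in [1, ", n, "]")
  if (!is.null(seed)) set.seed(seed)
  lab <- sort(sample.int(n, L))
  unl <- setdiff(seq_len(n), lab)
  perm <- c(lab, unl)
  semi_dataset(data_full$X[perm, , drop = FALSE],
               data_full$Y[lab, , drop = FALSE],
               task = data_full$task, hierarchy = data_full$hierarchy,
               perm = perm)
}

#' Generate a random rooted label hierarchy
#'
#' Builds a random rooted tree over `T` labels with maximum depth `depth`:
#' the first `depth` labels form a chain realizing the depth, and every
#' remaining label attaches to a uniformly chosen existing label of depth
#' less than `depth`. With `depth = 1` all labels are top-level.
#'
#' @param T Number of labels (`T >= depth >= 1`).
#' @param depth Maximum depth.
#' @param seed Optional seed; identical seeds give identical edge lists.
#' @return A `spyct_hierarchy`.
#' @export
gen_hierarchy <- function(T, depth = 3L, seed = NULL) {
  stopifnot(T >= 1, depth >= 1)
  if (depth > T) stop("infeasible shape: depth must not exceed T")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("lab%02d", seq_len(T))
  if (depth == 1L) return(hierarchy_spec(labels))
  parent <- character(0)
  child <- character(0)
  node_depth <- rep(NA_real_, T)
  node_depth[1L] <- 1
  for (i in seq_len(depth - 1L)) {
    parent <- c(parent, labels[i])
    child <- c(child, labels[i + 1L])
    node_depth[i + 1L] <- i + 1
  }
  if (T > depth) {
    for (i in (depth + 1L):T) {
      eligible <- which(node_depth[seq_len(i - 1L)] < depth)
      par <- eligible[sample.int(length(eligible), 1L)]
      parent <- c(parent, labels[par])
      child <- c(child, labels[i])
      node_depth[i] <- node_depth[par] + 1
    }
  }
  hierarchy_spec(labels, data.frame(parent = parent, child = child,
                                    stringsAsFactors = FALSE))
}
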