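#' Fit a single semi-supervised oblique predictive clustering tree
#'
#' Grows a binary tree top-down. At every node the features are
#' standardized over the node's examples (all of them, or the labeled ones
#' only when `omega = 1`, in which case unlabeled examples cannot affect
#' split selection) and the targets over the node's labeled examples; the
#' clustering weights are scaled to the supervision degree; and a split
#' hyperplane is learned with the configured variant. The split is accepted
#' only if both children receive at least `min_leaf_labeled` labeled
#' examples and the size-weighted mean of the children's impurities —
#' measured in the parent's standardized space with hard (all-ones)
#' membership — is at most `(1 - imp_reduction)` times the parent's
#' impurity. Otherwise the node
#' becomes a leaf whose prototype is the column-wise mean of the labeled
#' targets. A rejected or degenerate split immediately yields a leaf.
#'
#' @param data A [semi_dataset()].
#' @param config A [split_config()]. When `config$omega == "auto"` the
#'   supervision degree is first selected with [select_omega_cv()].
#' @param ... Passed to [split_config()] when `config` is missing.
#' @return An object of class `spyct_tree`.
#' @export
spyct <- function(data, config = split_config(...), ...) {
  stopifnot(inherits(data, "semi_dataset"), inherits(config, "spyct_config"))
  if (identical(config$omega, "auto")) {
    config$omega <- select_omega_cv(data, config = config)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  root <- .grow_node(data, config, idx = seq_len(data$L + data$U), depth = 0L)
  structure(
    list(root = root, task = data$task, config = config,
         label_order = data$label_order, D = data$D, T = data$T,
         n_train = data$L + data$U, hierarchy = data$hierarchy),
    class = "spyct_tree"
  )
}

# Recursive growth. `idx` is sorted ascending so that (global labeled-first
# ordering) the labeled members of the node are a prefix when features and
# targets are subset consistently.
.grow_node <- function(data, config, idx, depth) {
  L <- data$L
  lab <- idx[idx <= L]
  leaf <- function() {
    proto <- colMeans(data$Y[lab, , drop = FALSE])
    list(leaf = TRUE, prototype = proto, n_labeled = length(lab),
         n_examples = length(idx))
  }
  if (length(lab) < max(2L, 2L * config$min_leaf_labeled) ||
        depth >= config$max_depth || length(idx) < 2L) {
    return(leaf())
  }

  omega <- config$omega
  eff <- if (omega == 1) lab else idx
  Xeff <- data$X[eff, , drop = FALSE]
  st <- standardize_fit(Xeff)
  Xs <- standardize_apply(Xeff, st)
  Yl <- data$Y[lab, , drop = FALSE]
  sty <- standardize_fit(Yl)
  Ys <- standardize_apply(Yl, sty)
  p <- scale_clustering_weights(.base_priorities(data), data$D, omega)$p

  split <- switch(config$variant,
    svm = learn_split_svm(Xs, Ys, p, config),
    grad = learn_split_grad(Xs, Ys, p, config)
  )
  if (is.null(split)) return(leaf())

  XsAll <- standardize_apply(data$X[idx, , drop = FALSE], st)
  z <- as.numeric(XsAll %*% split$w) + split$b
  pos <- z >= 0
  idx_r <- idx[pos]
  idx_l <- idx[!pos]
  lab_in_pos <- pos[match(lab, idx)]
  n_lab_r <- sum(lab_in_pos)
  n_lab_l <- length(lab) - n_lab_r
  if (n_lab_r < config$min_leaf_labeled || n_lab_l < config$min_leaf_labeled) {
    return(leaf())
  }

  # impurity gate, measured in the parent's standardized space with hard
  # all-ones membership (targets restricted to labeled rows)
  ones <- rep(1, length(idx))
  parent_imp <- group_impurity(XsAll, Ys, ones, p)
  if (parent_imp <= 0) return(leaf())
  # size-weighted pooling of the children's impurities, per attribute
  # block (features over all rows, targets over labeled rows). Comparing a
  # child's raw sample variance to the parent's would let any small child
  # pass by chance alone (its variance estimate is biased low), so a
  # per-child gate never stops on structureless targets.
  imp_split <- .pooled_split_impurity(XsAll, Ys, pos, lab_in_pos, p)
  if (imp_split > (1 - config$imp_reduction) * parent_imp) {
    return(leaf())
  }

  left <- .grow_node(data, config, idx_l, depth + 1L)
  right <- .grow_node(data, config, idx_r, depth + 1L)
  list(
    leaf = FALSE, w = split$w, b = split$b,
    mu = st$mu, sigma = st$sigma, center = st$center,
    n_examples = length(idx),
    left = left, right = right
  )
}

# Pooled within-child impurity of a hard split, in the parent's
# standardized space: per feature, the size-weighted mean of the two
# children's population variances (over all rows); per target, the same
# over labeled rows only. Equals the parent impurity minus the
# between-child variance, so it is always <= the parent impurity.
.pooled_split_impurity <- function(XsAll, Ys, pos, lab_in_pos, p) {
  D <- ncol(XsAll)
  Tn <- ncol(Ys)
  px <- p[seq_len(D)]
  py <- p[D + seq_len(Tn)]
  pooled <- function(M, grp, pw) {
    n_r <- sum(grp); n_l <- sum(!grp); n <- n_r + n_l
    v_r <- if (n_r > 0) .wvar_cols(M[grp, , drop = FALSE], rep(1, n_r)) else 0
    v_l <- if (n_l > 0) .wvar_cols(M[!grp, , drop = FALSE], rep(1, n_l)) else 0
    sum(pw * pmax((n_r * v_r + n_l * v_l) / n, 0))
  }
  out <- 0
  if (any(px > 0)) out <- out + pooled(XsAll, pos, px)
  if (any(py > 0)) out <- out + pooled(Ys, lab_in_pos, py)
  out
}

#' @export
print.spyct_tree <- function(x, ...) {
  cat("spyct_tree (", x$task, ", ", x$config$variant,
      " variant, omega = ", format(x$config$omega), "): ",
      .count_nodes(x$root, "leaf"), " leaves, depth ",
      tree_depth(x), "\n", sep = "")
  invisible(x)
}

.count_nodes <- function(node, which = c("leaf", "split")) {
  which <- match.arg(which)
  if (node$leaf) return(as.integer(which == "leaf"))
  as.integer(which == "split") +
    .count_nodes(node$left, which) + .count_nodes(node$right, which)
}

#' Depth of a fitted tree
#'
#' Number of split nodes on the longest root-to-leaf path (0 for a
#' leaf-only tree).
#'
#' @param tree A `spyct_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  depth_rec <- function(node) {
    if (node$leaf) return(0L)
    1L + max(depth_rec(node$left), depth_rec(node$right))
  }
  depth_rec(tree$root)
}

#' Predict with a fitted tree
#'
#' Routes each row through the tree: at a split node the row's features are
#' standardized with the node's stored parameters and sent to the positive
#' child when `w . x_std + b >= 0`, else to the negative child. Returns the
#' leaf prototypes as a score matrix; use [decode_predictions()] (or
#' `type = "response"`) for task-level predictions.
#'
#' @param object A `spyct_tree`.
#' @param newdata Numeric matrix with `D` columns.
#' @param type `"score"` for the raw prototype matrix, `"response"` for the
#'   decoded prediction.
#' @param threshold Decoding threshold for BC/MLC/HMLC.
#' @param ... Unused.
#' @return Score matrix `n x T`, or the decoded predictions.
#' @export
predict.spyct_tree <- function(object, newdata, type = c("score", "response"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$D) {
    stop("newdata has ", ncol(newdata), " columns; model expects ", object$D)
  }
  n <- nrow(newdata)
  scores <- matrix(NA_real_, n, object$T)
  colnames(scores) <- object$label_order
  route <- function(node, rows) {
    if (length(rows) == 0L) return(invisible(NULL))
    if (node$leaf) {
      scores[rows, ] <<- matrix(node$prototype, length(rows), object$T,
                                byrow = TRUE)
      return(invisible(NULL))
    }
    Xr <- newdata[rows, , drop = FALSE]
    Xstd <- if (node$center) {
      sweep(sweep(Xr, 2L, node$mu, "-"), 2L, node$sigma, "/")
    } else {
      sweep(as.matrix(Xr), 2L, node$sigma, "/")
    }
    z <- as.numeric(Xstd %*% node$w) + node$b
    pos <- z >= 0
    route(node$left, rows[!pos])
    route(node$right, rows[pos])
    invisible(NULL)
  }
  route(object$root, seq_len(n))
  if (type == "score") scores
  else decode_predictions(scores, object$task, threshold = threshold)
}
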