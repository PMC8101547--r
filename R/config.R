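#' Split-learning configuration
#'
#' Bundles all tunable parameters of tree growth. Defaults follow the
#' standard SPYCT configuration: unlimited depth, one labeled example per
#' leaf, splits accepted only when they reduce impurity by at least 5% in
#' one of the subsets, regularization strength `C = 10`, at most 100
#' hyperplane optimization iterations and 10 clustering iterations, and
#' Adam constants beta1 = 0.9, beta2 = 0.999, eps = 1e-8.
#'
#' @param variant Split learner: `"grad"` (gradient descent on the fuzzy
#'   impurity objective) or `"svm"` (semi-supervised 2-means followed by an
#'   L1-regularized squared-hinge SVM).
#' @param omega Degree of supervision in `[0, 1]`, or `"auto"` to select it
#'   by internal cross-validation over `{0, 0.25, 0.5, 0.75, 1}`. `omega = 0`
#'   grows the tree without supervision (target impurity ignored);
#'   `omega = 1` is fully supervised (unlabeled examples do not affect split
#'   selection).
#' @param C Positive regularization strength (larger = weaker regularization).
#' @param opt_iters Maximum hyperplane optimization iterations.
#' @param clust_iters Maximum k-means iterations (SVM variant).
#' @param adam_lr Adam step size (gradient variant).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment/stability constants.
#' @param min_leaf_labeled Minimum labeled examples required in each leaf.
#' @param max_depth Maximum number of split nodes on any root-to-leaf path
#'   (`Inf` = unlimited).
#' @param imp_reduction Fraction in `[0, 1)`: a split is accepted only if at
#'   least one child's impurity is at most `(1 - imp_reduction)` times the
#'   parent's.
#' @param svm_tol Relative objective-change tolerance for the SVM solver.
#' @param seed Integer seed controlling all randomness, or `NULL`.
#' @return An object of class `spyct_config`.
#' @export
split_config <- function(variant = c("grad", "svm"),
                         omega = "auto",
                         C = 10,
                         opt_iters = 100L,
                         clust_iters = 10L,
                         adam_lr = 0.1,
                         adam_beta1 = 0.9,
                         adam_beta2 = 0.999,
                         adam_eps = 1e-8,
                         min_leaf_labeled = 1L,
                         max_depth = Inf,
                         imp_reduction = 0.05,
                         svm_tol = 1e-4,
                         seed = NULL) {
  variant <- match.arg(variant)
  if (is.character(omega)) {
    if (!identical(omega, "auto")) {
      stop("`omega` must be a number in [0, 1] or \"auto\"")
    }
  } else {
    stopifnot(is.numeric(omega), length(omega) == 1L, omega >= 0, omega <= 1)
  }
  stopifnot(
    is.numeric(C), C > 0,
    opt_iters >= 1, clust_iters >= 1,
    adam_lr > 0, adam_beta1 >= 0, adam_beta1 < 1,
    adam_beta2 >= 0, adam_beta2 < 1, adam_eps > 0,
    min_leaf_labeled >= 1,
    max_depth >= 0,
    imp_reduction >= 0, imp_reduction < 1,
    svm_tol > 0
  )
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(
    list(
      variant = variant, omega = omega, C = C,
      opt_iters = as.integer(opt_iters), clust_iters = as.integer(clust_iters),
      adam_lr = adam_lr, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
      adam_eps = adam_eps,
      min_leaf_labeled = as.integer(min_leaf_labeled),
      max_depth = max_depth, imp_reduction = imp_reduction,
      svm_tol = svm_tol,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "spyct_config"
  )
}

#' @export
print.spyct_config <- function(x, ...) {
  cat("spyct split configuration\n")
  cat("  variant:", x$variant, " omega:", format(x$omega), "\n")
  cat("  C:", x$C, " opt_iters:", x$opt_iters,
      " clust_iters:", x$clust_iters, "\n")
  cat("  min_leaf_labeled:", x$min_leaf_labeled,
      " max_depth:", x$max_depth,
      " imp_reduction:", x$imp_reduction, "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
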