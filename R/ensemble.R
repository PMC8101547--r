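#' Fit a bagging ensemble of oblique predictive clustering trees
#'
#' Trains `n_trees` trees (default 50), each on a stratified bootstrap:
#' `L` draws with replacement from the labeled rows and `U` draws with
#' replacement from the unlabeled rows, so every tree sees the original
#' labeled/unlabeled proportions and can always form leaves. Per-tree seeds
#' are derived from the ensemble seed. Predictions are averaged over trees.
#'
#' @param data A [semi_dataset()].
#' @param config A [split_config()]. `omega = "auto"` selects the
#'   supervision degree once for the whole ensemble by internal
#'   cross-validation (with `cv_n_trees` trees per candidate fit).
#' @param n_trees Number of trees (>= 1).
#' @param bootstrap If `FALSE`, every tree is fit on the full sample
#'   (useful for degenerate-ensemble checks).
#' @param cv_n_trees Trees per candidate fit during `omega` selection.
#' @param ... Passed to [split_config()] when `config` is missing.
#' @return An object of class `spyct_forest`.
#' @export
spyct_forest <- function(data, config = split_config(...), n_trees = 50L,
                         bootstrap = TRUE, cv_n_trees = n_trees, ...) {
  stopifnot(inherits(data, "semi_dataset"), inherits(config, "spyct_config"),
            n_trees >= 1L)
  if (identical(config$omega, "auto")) {
    config$omega <- select_omega_cv(data, config = config,
                                    n_trees = cv_n_trees)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, n_trees)
  L <- data$L; U <- data$U
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    if (bootstrap) {
      lab_idx <- sort(sample.int(L, L, replace = TRUE))
      unl_idx <- if (U > 0) sort(sample.int(U, U, replace = TRUE)) else integer()
      Xb <- data$X[c(lab_idx, L + unl_idx), , drop = FALSE]
      Yb <- data$Y[lab_idx, , drop = FALSE]
      db <- semi_dataset(Xb, Yb, task = data$task, hierarchy = data$hierarchy)
    } else {
      db <- data
    }
    cfg_t <- config
    cfg_t$seed <- seeds[t]
    trees[[t]] <- spyct(db, cfg_t)
  }
  structure(
    list(trees = trees, task = data$task, config = config,
         label_order = data$label_order, D = data$D, T = data$T,
         n_trees = n_trees, hierarchy = data$hierarchy),
    class = "spyct_forest"
  )
}

#' @export
print.spyct_forest <- function(x, ...) {
  cat("spyct_forest (", x$task, ", ", x$config$variant,
      " variant, omega = ", format(x$config$omega), "): ",
      x$n_trees, " trees\n", sep = "")
  invisible(x)
}

#' Predict with a bagging ensemble
#'
#' Member trees' score matrices are averaged, then decoded per task as in
#' [predict.spyct_tree()].
#'
#' @inheritParams predict.spyct_tree
#' @param object A `spyct_forest`.
#' @export
predict.spyct_forest <- function(object, newdata,
                                 type = c("score", "response"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  acc <- NULL
  for (tr in object$trees) {
    sc <- predict(tr, newdata, type = "score")
    acc <- if (is.null(acc)) sc else acc + sc
  }
  scores <- acc / length(object$trees)
  if (type == "score") scores
  else decode_predictions(scores, object$task, threshold = threshold)
}

#' Hyperplane-weight feature importances
#'
#' For a single tree, each split node `s` contributes
#' `(s_n / N) * |s_w| / ||s_w||_1`, where `s_n` is the number of training
#' examples that reached the node and `N` the total number of training
#' examples; contributions are summed over split nodes, so splits high in
#' the tree (affecting more examples) weigh more. For an ensemble the
#' per-tree vectors are averaged. A leaf-only tree scores all zeros, and
#' the importances sum exactly to `sum over split nodes of s_n / N`.
#'
#' @param model A `spyct_tree` or `spyct_forest`.
#' @return Nonnegative numeric vector of length `D`.
#' @export
feature_importance <- function(model) {
  if (inherits(model, "spyct_forest")) {
    imps <- vapply(model$trees, feature_importance, numeric(model$D))
    return(rowMeans(imps))
  }
  stopifnot(inherits(model, "spyct_tree"))
  imp <- rep(0, model$D)
  N <- model$root$n_examples
  walk <- function(node) {
    if (node$leaf) return(invisible(NULL))
    aw <- abs(node$w)
    tot <- sum(aw)
    if (tot > 0) imp <<- imp + (node$n_examples / N) * aw / tot
    walk(node$left)
    walk(node$right)
    invisible(NULL)
  }
  walk(model$root)
  imp
}
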