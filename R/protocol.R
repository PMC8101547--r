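#' Select the supervision degree by internal cross-validation
#'
#' Partitions the labeled examples into `folds` folds; all unlabeled
#' examples join every training fold. For each candidate `omega` a model is
#' fit on each training fold and scored on the held-out labeled examples
#' with the task's outer metric (R-squared for regression, F1 for binary /
#' multi-class, weighted LRAP for multi-label tasks). The `omega` with the
#' best mean score wins; ties go to the largest `omega` (more supervision).
#'
#' @param data A [semi_dataset()].
#' @param grid Candidate values, default `{0, 0.25, 0.5, 0.75, 1}`.
#' @param folds Number of folds (default 3); requires `L >= folds`.
#' @param config A [split_config()] used for the candidate fits (its
#'   `omega` is overridden per candidate).
#' @param n_trees Trees per candidate fit (1 = single tree).
#' @param seed Seed for fold assignment and candidate fits (default:
#'   `config$seed`).
#' @return The selected `omega`, with the per-candidate mean scores
#'   attached as the `"scores"` attribute.
#' @export
select_omega_cv <- function(data, grid = c(0, 0.25, 0.5, 0.75, 1),
                            folds = 3L, config = split_config(),
                            n_trees = 1L, seed = config$seed) {
  stopifnot(inherits(data, "semi_dataset"))
  grid <- sort(unique(as.numeric(grid)))
  stopifnot(all(grid >= 0 & grid <= 1), length(grid) >= 1L)
  if (length(grid) == 1L) return(grid)
  L <- data$L
  if (L < folds) {
    stop("L = ", L, " labeled examples is fewer than folds = ", folds,
         "; use fewer folds")
  }
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), L))
  fit_seeds <- sample.int(.Machine$integer.max, folds)
  unl_rows <- if (data$U > 0) L + seq_len(data$U) else integer()

  scores <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    test_lab <- which(fold_id == f)
    train_lab <- which(fold_id != f)
    Xtr <- data$X[c(train_lab, unl_rows), , drop = FALSE]
    Ytr <- data$Y[train_lab, , drop = FALSE]
    dtr <- semi_dataset(Xtr, Ytr, task = data$task,
                        hierarchy = data$hierarchy)
    Xte <- as.matrix(data$X[test_lab, , drop = FALSE])
    Yte <- data$Y[test_lab, , drop = FALSE]
    for (g in seq_along(grid)) {
      cfg <- config
      cfg$omega <- grid[g]
      cfg$seed <- fit_seeds[f]
      model <- if (n_trees > 1L) {
        spyct_forest(dtr, cfg, n_trees = n_trees)
      } else {
        spyct(dtr, cfg)
      }
      sc <- predict(model, Xte, type = "score")
      scores[g, f] <- tryCatch(
        as.numeric(.task_score(data$task, Yte, sc,
                               hierarchy = data$hierarchy)),
        error = function(e) NA_real_
      )
    }
  }
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  mean_scores[is.nan(mean_scores)] <- -Inf
  best <- max(mean_scores)
  # ties -> largest omega
  sel <- grid[max(which(mean_scores >= best - 1e-12))]
  attr(sel, "scores") <- stats::setNames(mean_scores, format(grid))
  sel
}

#' Label-masking inductive cross-validation protocol
#'
#' Splits a fully labeled dataset into `folds` test folds. For each fold,
#' the remaining examples form the training set, of which `L` randomly
#' chosen examples keep their labels and the rest become unlabeled. Every
#' example is tested exactly once, on a model that never saw it, labeled or
#' unlabeled.
#'
#' @param data_full A fully labeled [semi_dataset()] (`U = 0`).
#' @param L Number of labeled examples per training split; must not exceed
#'   the training-fold size.
#' @param folds Number of folds (default 10).
#' @param seed Optional seed.
#' @return List of `folds` elements, each with `train` (a `semi_dataset`
#'   with `L` labeled rows), `test_X`, `test_Y`, `test_idx` (row indices in
#'   `data_full`) and `labeled_idx`.
#' @export
mask_labels_protocol <- function(data_full, L, folds = 10L, seed = NULL) {
  stopifnot(inherits(data_full, "semi_dataset"))
  if (data_full$U != 0L) stop("protocol requires a fully labeled dataset")
  n <- data_full$L
  min_train <- n - ceiling(n / folds)
  if (L > min_train) {
    stop("L = ", L, " exceeds the smallest training-fold size (", min_train,
         ")")
  }
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    lab_sel <- sort(sample(train_idx, L))
    unl_sel <- setdiff(train_idx, lab_sel)
    Xtr <- data_full$X[c(lab_sel, unl_sel), , drop = FALSE]
    Ytr <- data_full$Y[lab_sel, , drop = FALSE]
    out[[f]] <- list(
      train = semi_dataset(Xtr, Ytr, task = data_full$task,
                           hierarchy = data_full$hierarchy,
                           perm = c(lab_sel, unl_sel)),
      test_X = as.matrix(data_full$X[test_idx, , drop = FALSE]),
      test_Y = data_full$Y[test_idx, , drop = FALSE],
      test_idx = test_idx,
      labeled_idx = lab_sel
    )
  }
  out
}
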