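#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. For multi-target
#' matrices the unweighted mean of per-target scores is returned, with the
#' per-target vector attached as the `"per_target"` attribute.
#'
#' @param y True values (vector, or matrix for multi-target).
#' @param yhat Predicted values, same shape.
#' @return R-squared (<= 1); errors when `y` is constant.
#' @export
r2_score <- function(y, yhat) {
  if (is.matrix(y) || is.data.frame(y)) {
    y <- as.matrix(y); yhat <- as.matrix(yhat)
    stopifnot(identical(dim(y), dim(yhat)))
    per <- vapply(seq_len(ncol(y)),
                  function(j) r2_score(y[, j], yhat[, j]), numeric(1))
    out <- mean(per)
    attr(out, "per_target") <- per
    return(out)
  }
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("R^2 undefined: constant true values")
  1 - sum((y - yhat)^2) / ss_tot
}

#' F1 score (binary or macro-averaged)
#'
#' Per-class F1 is `2 * precision * recall / (precision + recall)`, defined
#' as 0 when a class has neither predicted nor true positives. `"binary"`
#' returns the positive-class F1 of a two-class problem; `"macro"`
#' averages per-class F1 over all classes, unweighted.
#'
#' @param y_true,y_pred Class labels (vectors of equal length). For
#'   `"binary"`, 0/1 with 1 the positive class, or two-level factors whose
#'   second sorted level is positive.
#' @param average `"binary"` or `"macro"`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(y_true, y_pred, average = c("macro", "binary")) {
  average <- match.arg(average)
  if (length(y_true) == 0L) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  f1_class <- function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (tp + fp + fn == 0L) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  if (average == "binary") {
    if (length(classes) > 2L) stop("binary F1 requires two classes")
    pos <- classes[length(classes)]
    f1_class(pos)
  } else {
    per <- vapply(classes, f1_class, numeric(1))
    out <- mean(per)
    attr(out, "per_class") <- per
    out
  }
}

#' Weighted label ranking average precision
#'
#' For each example `i` and each of its true labels `j`, let `R_ij` be the
#' number of labels the scores rank at or above label `j`, and `L_ij` the
#' number of those that are true labels of `i`. The metric averages
#' `sum_j (w_j / W_i) * (L_ij / R_ij)` over examples, with `W_i` the total
#' weight of example `i`'s true labels. Equal label weights give the
#' standard label ranking average precision; hierarchical tasks use the
#' depth weights `0.75^d`. Rows without any positive label are skipped
#' with a warning.
#'
#' @param Y 0/1 label matrix `n x T`.
#' @param S Score matrix `n x T`.
#' @param label_weights Nonnegative label weight vector (default: equal).
#' @return LRAP in `[0, 1]`.
#' @export
lrap_weighted <- function(Y, S, label_weights = NULL) {
  Y <- as.matrix(Y); S <- as.matrix(S)
  stopifnot(identical(dim(Y), dim(S)))
  Tn <- ncol(Y)
  if (is.null(label_weights)) label_weights <- rep(1, Tn)
  stopifnot(length(label_weights) == Tn)
  if (any(label_weights < 0)) stop("label weights must be nonnegative")
  pos_rows <- which(rowSums(Y) > 0)
  if (length(pos_rows) < nrow(Y)) {
    warning(nrow(Y) - length(pos_rows),
            " example(s) without positive labels skipped in LRAP")
  }
  if (length(pos_rows) == 0L) stop("no examples with positive labels")
  total <- 0
  for (i in pos_rows) {
    yi <- Y[i, ]
    si <- S[i, ]
    true_j <- which(yi == 1)
    Wi <- sum(label_weights[true_j])
    acc <- 0
    for (j in true_j) {
      ge <- si >= si[j]
      Rij <- sum(ge)
      Lij <- sum(ge & yi == 1)
      acc <- acc + label_weights[j] / Wi * Lij / Rij
    }
    total <- total + acc
  }
  total / length(pos_rows)
}

# Task-appropriate score (higher is better) used by internal CV.
.task_score <- function(task, Y_true, scores, hierarchy = NULL) {
  switch(task,
    STR = ,
    MTR = r2_score(Y_true, scores),
    BC = f1_score(Y_true[, 1L], as.numeric(scores[, 1L] >= 0.5),
                  average = "binary"),
    MCC = {
      true_cls <- max.col(Y_true, ties.method = "first")
      pred_cls <- max.col(scores, ties.method = "first")
      f1_score(true_cls, pred_cls, average = "macro")
    },
    MLC = lrap_weighted(Y_true, scores),
    HMLC = lrap_weighted(Y_true, scores,
                         label_weights = unname(hierarchy$label_weight))
  )
}
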