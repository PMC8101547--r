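#' Partially labeled dataset
#'
#' Container for semi-supervised learning: features for `L + U` examples
#' with the labeled examples occupying the first `L` rows, and an encoded
#' target matrix for the labeled rows only.
#'
#' @param X Numeric feature matrix `(L+U) x D`, dense or a sparse
#'   `Matrix::dgCMatrix`. Labeled rows come first.
#' @param Y Numeric encoded target matrix `L x T` (see [encode_targets()]).
#' @param task One of `"STR"`, `"MTR"`, `"BC"`, `"MCC"`, `"MLC"`, `"HMLC"`.
#' @param hierarchy A `spyct_hierarchy` (required for `"HMLC"`, whose labels
#'   must match `colnames(Y)` exactly).
#' @param perm Optional integer vector mapping the rows of `X` back to their
#'   positions in an original source (kept by readers that reorder
#'   labeled-first).
#' @return An object of class `semi_dataset` with fields `X`, `Y`, `L`, `U`,
#'   `D`, `T`, `task`, `hierarchy`, `label_order`, `perm`.
#' @export
semi_dataset <- function(X, Y, task, hierarchy = NULL, perm = NULL) {
  task <- match.arg(task, c("STR", "MTR", "BC", "MCC", "MLC", "HMLC"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!inherits(X, "Matrix")) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
  }
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  L <- nrow(Y)
  n <- nrow(X)
  if (L < 1L) stop("at least one labeled example is required (L >= 1)")
  if (n < L) stop("X has fewer rows than Y: labeled rows must be the first L rows of X")
  if (ncol(X) < 1L || ncol(Y) < 1L) stop("D >= 1 and T >= 1 required")
  if (anyNA(Y)) stop("Y must not contain missing values")
  if (task == "BC") {
    if (ncol(Y) != 1L) stop("BC requires a single target column")
    if (!all(Y %in% c(0, 1))) stop("BC targets must be 0/1")
  }
  if (task == "MCC") {
    if (!all(Y %in% c(0, 1)) || !all(abs(rowSums(Y) - 1) < 1e-12)) {
      stop("MCC targets must be one-hot rows")
    }
  }
  if (task %in% c("MLC", "HMLC") && !all(Y %in% c(0, 1))) {
    stop(task, " targets must be 0/1 indicators")
  }
  if (task == "HMLC") {
    if (is.null(hierarchy)) stop("HMLC requires a hierarchy")
    stopifnot(inherits(hierarchy, "spyct_hierarchy"))
    if (is.null(colnames(Y)) || !identical(colnames(Y), hierarchy$labels)) {
      stop("HMLC target columns must match the hierarchy labels exactly")
    }
    .check_hierarchy_consistent(Y, hierarchy)
  } else {
    hierarchy <- NULL
  }
  if (!is.null(perm)) stopifnot(length(perm) == n)
  structure(
    list(
      X = X, Y = Y, L = L, U = n - L, D = ncol(X), T = ncol(Y),
      task = task, hierarchy = hierarchy,
      label_order = colnames(Y), perm = perm
    ),
    class = "semi_dataset"
  )
}

#' @export
print.semi_dataset <- function(x, ...) {
  cat("semi_dataset (", x$task, "): ", x$L, " labeled + ", x$U,
      " unlabeled examples, ", x$D, " features, ", x$T, " target column",
      if (x$T > 1) "s", if (inherits(x$X, "Matrix")) ", sparse features",
      "\n", sep = "")
  invisible(x)
}

#' Encode raw targets into the numeric matrix a tree predicts
#'
#' Each task has a canonical numeric encoding: regression targets are kept
#' as-is, binary classes become a single 0/1 column, multi-class labels
#' become one-hot indicators over the sorted class names, and (hierarchical)
#' multi-label sets become 0/1 indicator matrices. Column order is
#' deterministic: sorted class/label names, or the hierarchy's label order
#' for HMLC.
#'
#' @param raw Raw targets: a numeric vector/matrix (STR/MTR), a vector of
#'   class labels or 0/1 values (BC), a factor/character vector (MCC), or a
#'   list of character label sets / a named 0/1 matrix (MLC/HMLC).
#' @param task Task name, as in [semi_dataset()].
#' @param hierarchy `spyct_hierarchy` (HMLC only): fixes column order and
#'   is used to verify hierarchy consistency.
#' @param classes Optional fixed class vector (BC/MCC) so that encodings at
#'   prediction time match training; unknown classes raise an error.
#' @param labels Optional fixed label universe (MLC).
#' @return Numeric matrix `L x T` with column names.
#' @export
encode_targets <- function(raw, task, hierarchy = NULL, classes = NULL,
                           labels = NULL) {
  task <- match.arg(task, c("STR", "MTR", "BC", "MCC", "MLC", "HMLC"))
  switch(task,
    STR = {
      y <- as.numeric(raw)
      matrix(y, ncol = 1L, dimnames = list(NULL, "y"))
    },
    MTR = {
      Y <- as.matrix(raw)
      storage.mode(Y) <- "double"
      if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
      Y
    },
    BC = {
      v <- if (is.factor(raw)) as.character(raw) else raw
      if (is.numeric(v) || is.logical(v)) {
        v <- as.numeric(v)
        if (!all(v %in% c(0, 1))) stop("numeric BC targets must be 0/1")
        matrix(v, ncol = 1L, dimnames = list(NULL, "y"))
      } else {
        cls <- if (is.null(classes)) sort(unique(v)) else classes
        if (length(cls) != 2L) stop("BC requires exactly two classes")
        unknown <- setdiff(unique(v), cls)
        if (length(unknown) > 0L) {
          stop("unknown class value(s): ", paste(unknown, collapse = ", "))
        }
        matrix(as.numeric(v == cls[2L]), ncol = 1L,
               dimnames = list(NULL, cls[2L]))
      }
    },
    MCC = {
      v <- as.character(raw)
      cls <- if (is.null(classes)) sort(unique(v)) else as.character(classes)
      unknown <- setdiff(unique(v), cls)
      if (length(unknown) > 0L) {
        stop("unknown class value(s): ", paste(unknown, collapse = ", "))
      }
      Y <- matrix(0, nrow = length(v), ncol = length(cls),
                  dimnames = list(NULL, cls))
      Y[cbind(seq_along(v), match(v, cls))] <- 1
      Y
    },
    MLC = ,
    HMLC = {
      if (task == "HMLC") {
        if (is.null(hierarchy)) stop("HMLC encoding requires a hierarchy")
        labs <- hierarchy$labels
      } else if (!is.null(labels)) {
        labs <- as.character(labels)
      } else if (is.matrix(raw) || is.data.frame(raw)) {
        labs <- colnames(raw)
        if (is.null(labs)) stop("indicator-matrix targets need column names")
      } else {
        labs <- sort(unique(unlist(raw)))
      }
      if (is.matrix(raw) || is.data.frame(raw)) {
        raw <- as.matrix(raw)
        unknown <- setdiff(colnames(raw), labs)
        if (length(unknown) > 0L) {
          stop("unknown label column(s): ", paste(unknown, collapse = ", "))
        }
        Y <- matrix(0, nrow = nrow(raw), ncol = length(labs),
                    dimnames = list(NULL, labs))
        Y[, colnames(raw)] <- raw
      } else {
        stopifnot(is.list(raw))
        Y <- matrix(0, nrow = length(raw), ncol = length(labs),
                    dimnames = list(NULL, labs))
        for (i in seq_along(raw)) {
          set_i <- as.character(raw[[i]])
          unknown <- setdiff(set_i, labs)
          if (length(unknown) > 0L) {
            stop("unknown label(s) in example ", i, ": ",
                 paste(unknown, collapse = ", "))
          }
          Y[i, set_i] <- 1
        }
      }
      if (!all(Y %in% c(0, 1))) stop("label indicators must be 0/1")
      if (task == "HMLC") .check_hierarchy_consistent(Y, hierarchy)
      Y
    }
  )
}

#' Decode prototype scores into task-level predictions
#'
#' Leaf prototypes are column means of labeled targets, so they are used
#' directly for regression, thresholded at 0.5 for binary and (hierarchical)
#' multi-label tasks, and decoded by argmax for multi-class (ties go to the
#' lowest column index).
#'
#' @param scores Numeric score matrix `n x T` (column names = label order).
#' @param task Task name.
#' @param threshold Score threshold for BC/MLC/HMLC decoding.
#' @return STR: numeric vector. MTR: numeric matrix. BC: 0/1 vector (or the
#'   positive class name when columns are named). MCC: character vector of
#'   class names. MLC/HMLC: 0/1 indicator matrix.
#' @export
decode_predictions <- function(scores, task, threshold = 0.5) {
  task <- match.arg(task, c("STR", "MTR", "BC", "MCC", "MLC", "HMLC"))
  scores <- as.matrix(scores)
  switch(task,
    STR = as.numeric(scores[, 1L]),
    MTR = scores,
    BC = as.numeric(scores[, 1L] >= threshold),
    MCC = {
      cls <- colnames(scores)
      idx <- apply(scores, 1L, which.max) # which.max: first max, lowest index
      if (is.null(cls)) idx else cls[idx]
    },
    MLC = ,
    HMLC = {
      out <- (scores >= threshold) * 1
      dimnames(out) <- dimnames(scores)
      out
    }
  )
}
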