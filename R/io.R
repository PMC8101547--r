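#' Read a partially labeled dataset from CSV
#'
#' Reads a UTF-8 CSV with a header row. Target columns are named
#' explicitly; the remaining columns are features and must be numeric. An
#' example is unlabeled iff ALL of its target cells are empty; rows with
#' some-but-not-all empty target cells are rejected, since the method
#' assumes examples are fully labeled or fully unlabeled. Rows are
#' reordered labeled-first; the original row order is kept in the returned
#' dataset's `perm` field.
#'
#' With `sparse = TRUE` the features file is a triplet CSV with columns
#' `row,col,value` (1-based indices) and the targets come from a separate
#' CSV (`targets_path`) with a `row` column plus the target columns; rows
#' absent from the targets file are unlabeled.
#'
#' @param path Features(+targets) CSV path.
#' @param target_cols Character vector of target column names.
#' @param task Task name.
#' @param hierarchy_path Optional hierarchy edge-list file (HMLC).
#' @param sparse Triplet-format features (see Details).
#' @param targets_path Targets CSV (sparse mode only).
#' @param dims Optional `c(n, D)` for sparse mode (default: inferred from
#'   the largest indices).
#' @return A [semi_dataset()].
#' @export
read_dataset_csv <- function(path, target_cols, task, hierarchy_path = NULL,
                             sparse = FALSE, targets_path = NULL,
                             dims = NULL) {
  task <- match.arg(task, c("STR", "MTR", "BC", "MCC", "MLC", "HMLC"))
  hier <- NULL
  if (sparse) {
    trip <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("row", "col", "value") %in% names(trip))) {
      stop("sparse features CSV needs columns row, col, value")
    }
    if (is.null(dims)) dims <- c(max(trip$row), max(trip$col))
    X <- Matrix::sparseMatrix(i = trip$row, j = trip$col, x = trip$value,
                              dims = dims)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (is.null(targets_path)) stop("sparse mode requires targets_path")
    tg <- utils::read.csv(targets_path, stringsAsFactors = FALSE)
    if (!"row" %in% names(tg)) stop("targets CSV needs a 'row' column")
    missing_cols <- setdiff(target_cols, names(tg))
    if (length(missing_cols) > 0L) {
      stop("target column(s) not found: ", paste(missing_cols, collapse = ", "))
    }
    lab_rows <- tg$row
    raw_targets <- tg[, target_cols, drop = FALSE]
    n <- nrow(X)
    unl_rows <- setdiff(seq_len(n), lab_rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing_cols <- setdiff(target_cols, names(df))
    if (length(missing_cols) > 0L) {
      stop("target column(s) not found: ", paste(missing_cols, collapse = ", "))
    }
    feat_cols <- setdiff(names(df), target_cols)
    if (length(feat_cols) == 0L) stop("no feature columns")
    X <- matrix(NA_real_, nrow(df), length(feat_cols),
                dimnames = list(NULL, feat_cols))
    for (j in seq_along(feat_cols)) {
      v <- suppressWarnings(as.numeric(df[[feat_cols[j]]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1L]
        stop("non-numeric feature cell at row ", bad, ", column '",
             feat_cols[j], "'")
      }
      X[, j] <- v
    }
    tmat <- as.matrix(df[, target_cols, drop = FALSE])
    empty <- tmat == "" | is.na(tmat)
    all_empty <- rowSums(empty) == ncol(tmat)
    any_empty <- rowSums(empty) > 0
    partial <- which(any_empty & !all_empty)
    if (length(partial) > 0L) {
      stop("row ", partial[1L], " has partially missing targets; ",
           "examples must be fully labeled or fully unlabeled")
    }
    lab_rows <- which(!all_empty)
    unl_rows <- which(all_empty)
    raw_targets <- as.data.frame(tmat[lab_rows, , drop = FALSE],
                                 stringsAsFactors = FALSE)
  }
  if (length(lab_rows) == 0L) stop("no labeled examples in ", path)

  if (!is.null(hierarchy_path)) {
    hier <- read_hierarchy(hierarchy_path)
    if (task == "HMLC") {
      missing_lab <- setdiff(target_cols, hier$labels)
      if (length(missing_lab) > 0L) {
        stop("target column(s) absent from the hierarchy: ",
             paste(missing_lab, collapse = ", "))
      }
      hier <- hierarchy_spec(target_cols,
                             hier$edges[hier$edges$parent %in% target_cols &
                                          hier$edges$child %in% target_cols, ,
                                        drop = FALSE])
    }
  } else if (task == "HMLC") {
    stop("HMLC requires hierarchy_path")
  }

  Y <- .parse_targets(raw_targets, task, hier)
  perm <- c(lab_rows, unl_rows)
  semi_dataset(X[perm, , drop = FALSE], Y, task = task, hierarchy = hier,
               perm = perm)
}

# Convert raw (character or numeric) target columns to the encoded matrix.
.parse_targets <- function(raw, task, hier) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (task %in% c("STR", "MTR", "BC", "MLC", "HMLC")) {
    num <- lapply(raw, function(v) suppressWarnings(as.numeric(v)))
    bad <- vapply(num, anyNA, logical(1))
    if (any(bad)) {
      stop("non-numeric target cell in column '", names(raw)[bad][1L], "'")
    }
    M <- do.call(cbind, num)
    colnames(M) <- names(raw)
    switch(task,
      STR = encode_targets(M[, 1L], "STR"),
      MTR = encode_targets(M, "MTR"),
      BC = encode_targets(M[, 1L], "BC"),
      MLC = encode_targets(M, "MLC"),
      HMLC = encode_targets(M, "HMLC", hierarchy = hier)
    )
  } else { # MCC: single column of class labels
    if (ncol(raw) != 1L) stop("MCC expects a single target column")
    encode_targets(raw[[1L]], "MCC")
  }
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset_csv()] (dense mode): features plus encoded
#' target columns; unlabeled rows get empty target cells.
#'
#' @param data A [semi_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "semi_dataset"))
  X <- as.matrix(data$X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  tnames <- data$label_order
  if (is.null(tnames)) tnames <- paste0("y", seq_len(data$T))
  tmat <- matrix("", nrow(X), data$T, dimnames = list(NULL, tnames))
  tmat[seq_len(data$L), ] <- format(data$Y, digits = 17, trim = TRUE,
                                    scientific = FALSE)
  df <- data.frame(X, tmat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- model persistence -----------------------------------------------------

.node_to_list <- function(node) {
  if (node$leaf) {
    list(leaf = TRUE, prototype = node$prototype,
         n_labeled = node$n_labeled, n_examples = node$n_examples)
  } else {
    list(leaf = FALSE, w = node$w, b = node$b, mu = node$mu,
         sigma = node$sigma, center = node$center,
         n_examples = node$n_examples,
         left = .node_to_list(node$left), right = .node_to_list(node$right))
  }
}

.node_from_list <- function(lst) {
  if (isTRUE(lst$leaf)) {
    list(leaf = TRUE, prototype = as.numeric(lst$prototype),
         n_labeled = as.integer(lst$n_labeled),
         n_examples = as.integer(lst$n_examples))
  } else {
    list(leaf = FALSE, w = as.numeric(lst$w), b = as.numeric(lst$b),
         mu = as.numeric(lst$mu), sigma = as.numeric(lst$sigma),
         center = isTRUE(lst$center),
         n_examples = as.integer(lst$n_examples),
         left = .node_from_list(lst$left),
         right = .node_from_list(lst$right))
  }
}

.tree_to_list <- function(tree) {
  list(task = tree$task, label_order = tree$label_order,
       D = tree$D, T = tree$T, n_train = tree$n_train,
       config = tree$config[setdiff(names(tree$config), NULL)],
       root = .node_to_list(tree$root))
}

.tree_from_list <- function(lst) {
  cfg <- lst$config
  config <- split_config(
    variant = cfg$variant, omega = cfg$omega, C = cfg$C,
    opt_iters = cfg$opt_iters, clust_iters = cfg$clust_iters,
    adam_lr = cfg$adam_lr, adam_beta1 = cfg$adam_beta1,
    adam_beta2 = cfg$adam_beta2, adam_eps = cfg$adam_eps,
    min_leaf_labeled = cfg$min_leaf_labeled,
    max_depth = if (is.null(cfg$max_depth) || is.character(cfg$max_depth))
      Inf else cfg$max_depth,
    imp_reduction = cfg$imp_reduction, svm_tol = cfg$svm_tol,
    seed = if (length(cfg$seed) == 1L) cfg$seed else NULL
  )
  structure(
    list(root = .node_from_list(lst$root), task = lst$task,
         config = config,
         label_order = if (is.null(lst$label_order)) NULL
           else as.character(lst$label_order),
         D = as.integer(lst$D), T = as.integer(lst$T),
         n_train = as.integer(lst$n_train), hierarchy = NULL),
    class = "spyct_tree"
  )
}

#' Save / load a fitted model as JSON
#'
#' Models are serialized to a single JSON document (nested split/leaf
#' nodes, standardization vectors, configuration and label order) at full
#' numeric precision, so a saved-and-reloaded model predicts identically
#' and two fits with the same seed produce byte-identical files.
#'
#' @param model A `spyct_tree` or `spyct_forest`.
#' @param path JSON file path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  doc <- if (inherits(model, "spyct_forest")) {
    list(format = "spyctree-model", version = 1L, type = "forest",
         task = model$task, label_order = model$label_order,
         D = model$D, T = model$T, n_trees = model$n_trees,
         trees = lapply(model$trees, .tree_to_list))
  } else if (inherits(model, "spyct_tree")) {
    list(format = "spyctree-model", version = 1L, type = "tree",
         tree = .tree_to_list(model))
  } else {
    stop("not a spyctree model")
  }
  # max_depth = Inf is not representable in JSON
  doc <- rapply(doc, function(x) {
    if (is.numeric(x) && length(x) == 1L && is.infinite(x)) "Inf" else x
  }, how = "replace")
  # I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "spyctree-model")) {
    stop("not a spyctree model file: ", path)
  }
  if (identical(doc$type, "tree")) {
    .tree_from_list(doc$tree)
  } else {
    trees <- lapply(doc$trees, .tree_from_list)
    structure(
      list(trees = trees, task = doc$task,
           config = trees[[1L]]$config,
           label_order = if (is.null(doc$label_order)) NULL
             else as.character(doc$label_order),
           D = as.integer(doc$D), T = as.integer(doc$T),
           n_trees = as.integer(doc$n_trees), hierarchy = NULL),
      class = "spyct_forest"
    )
  }
}
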