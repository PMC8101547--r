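#' Label hierarchy for hierarchical multi-label classification
#'
#' Builds a rooted label DAG from a parent->child edge list and computes the
#' depth and clustering weight of every label. Top-level labels (those with
#' no parent) have depth 1; every other label's depth is the mean of its
#' parents' depths plus one, so the rule extends to DAGs where a label has
#' several parents. The weight of a label at depth d is `w0^d` (default
#' `0.75^d`), giving labels higher in the hierarchy more influence.
#'
#' @param labels Character vector of label names (column order of the
#'   encoded target matrix).
#' @param edges Two-column data.frame or matrix of parent->child edges;
#'   may be empty (all labels top-level). Duplicate edges are collapsed.
#' @param w0 Base of the depth weighting, in `(0, 1]`.
#' @return An object of class `spyct_hierarchy` with components `labels`,
#'   `edges`, `depth` and `label_weight`.
#' @export
hierarchy_spec <- function(labels, edges = NULL, w0 = 0.75) {
  labels <- as.character(labels)
  stopifnot(length(labels) >= 1L, !anyDuplicated(labels))
  stopifnot(is.numeric(w0), w0 > 0, w0 <= 1)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("parent", "child")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
    edges <- unique(edges)
    unknown <- setdiff(unique(c(edges$parent, edges$child)), labels)
    if (length(unknown) > 0L) {
      stop("hierarchy edge refers to unknown label(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  parents <- split(edges$parent, factor(edges$child, levels = labels))
  depth <- .hierarchy_depths(labels, parents)
  structure(
    list(labels = labels, edges = edges, depth = depth,
         w0 = w0, label_weight = w0^depth),
    class = "spyct_hierarchy"
  )
}

# Topological depth computation; stops with a cycle witness if the edge
# list is not a DAG.
.hierarchy_depths <- function(labels, parents) {
  n <- length(labels)
  depth <- stats::setNames(rep(NA_real_, n), labels)
  state <- stats::setNames(integer(n), labels) # 0 unvisited, 1 in-stack, 2 done
  visit <- function(lab, stack) {
    if (state[[lab]] == 1L) {
      cyc <- c(stack[which(stack == lab)[1L]:length(stack)], lab)
      stop("label hierarchy contains a cycle: ",
           paste(cyc, collapse = " -> "))
    }
    if (state[[lab]] == 2L) return(invisible(NULL))
    state[[lab]] <<- 1L
    pars <- parents[[lab]]
    if (is.null(pars) || length(pars) == 0L) {
      depth[[lab]] <<- 1
    } else {
      for (p in pars) visit(p, c(stack, lab))
      depth[[lab]] <<- mean(depth[pars]) + 1
    }
    state[[lab]] <<- 2L
    invisible(NULL)
  }
  for (lab in labels) visit(lab, character())
  depth
}

#' Depth-based label weights
#'
#' Returns the per-label weight vector `w0^depth` for a hierarchy, the
#' weighting used both in the weighted label-ranking metric and as the
#' target block of the clustering weights for hierarchical tasks.
#'
#' @param hier A `spyct_hierarchy`.
#' @param w0 Base of the exponential weighting (default 0.75).
#' @return Named numeric vector of weights, one per label.
#' @export
hierarchy_weights <- function(hier, w0 = 0.75) {
  stopifnot(inherits(hier, "spyct_hierarchy"))
  stats::setNames(w0^hier$depth, hier$labels)
}

#' @export
print.spyct_hierarchy <- function(x, ...) {
  cat("spyct label hierarchy:", length(x$labels), "labels,",
      nrow(x$edges), "edges, max depth",
      format(max(x$depth)), "\n")
  invisible(x)
}

# Checks that every positive label's parents are also positive.
# Y is a 0/1 matrix with columns ordered as hier$labels.
.check_hierarchy_consistent <- function(Y, hier) {
  if (nrow(hier$edges) == 0L) return(invisible(TRUE))
  ci <- match(hier$edges$child, hier$labels)
  pi <- match(hier$edges$parent, hier$labels)
  for (e in seq_along(ci)) {
    bad <- Y[, ci[e]] > Y[, pi[e]]
    if (any(bad)) {
      stop("hierarchy-inconsistent label set: label '", hier$labels[ci[e]],
           "' present without its parent '", hier$labels[pi[e]],
           "' (row ", which(bad)[1L], ")")
    }
  }
  invisible(TRUE)
}

#' Read a label hierarchy from an edge-list file
#'
#' Parses a text file with one `parent<TAB>child` edge per line. Blank
#' lines and `#` comments are ignored; duplicate edges are collapsed.
#'
#' @param path File path.
#' @param labels Optional label universe (column names of the targets). If
#'   omitted, the labels are those appearing in the file, in order of first
#'   appearance.
#' @param w0 Weight base, see [hierarchy_spec()].
#' @return A `spyct_hierarchy`.
#' @export
read_hierarchy <- function(path, labels = NULL, w0 = 0.75) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    if (is.null(labels)) stop("empty hierarchy file and no labels given")
    return(hierarchy_spec(labels, NULL, w0 = w0))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop("malformed hierarchy line ", bad[1L],
         " (expected parent<TAB>child): ", lines[bad[1L]])
  }
  edges <- data.frame(
    parent = vapply(parts, `[[`, "", 1L),
    child = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  if (is.null(labels)) {
    labels <- unique(c(rbind(edges$parent, edges$child)))
  }
  hierarchy_spec(labels, edges, w0 = w0)
}

#' Write a hierarchy edge list to a file
#'
#' @param hier A `spyct_hierarchy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hier, path) {
  stopifnot(inherits(hier, "spyct_hierarchy"))
  writeLines(paste(hier$edges$parent, hier$edges$child, sep = "\t"), path)
  invisible(path)
}
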