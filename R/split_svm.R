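#' Semi-supervised distance to a cluster centroid
#'
#' Squared distance weighted by the clustering weights. Labeled examples
#' measure both the feature and the target part of the centroid; unlabeled
#' examples measure the feature part only.
#'
#' @param x Feature vector (standardized, length `D`).
#' @param y Target vector (standardized, length `T`) or `NULL`.
#' @param centroid List with `x_part` (length `D`) and `y_part` (length `T`).
#' @param p Scaled clustering-weight vector, length `D + T`.
#' @param labeled Logical: is the example labeled?
#' @return Nonnegative distance.
#' @export
ss_distance <- function(x, y, centroid, p, labeled) {
  D <- length(centroid$x_part)
  Tn <- length(centroid$y_part)
  if (length(x) != D || length(p) != D + Tn) {
    stop("ss_distance: dimension mismatch")
  }
  d <- sum(p[seq_len(D)] * (x - centroid$x_part)^2)
  if (labeled) {
    if (length(y) != Tn) stop("ss_distance: dimension mismatch")
    d <- d + sum(p[D + seq_len(Tn)] * (y - centroid$y_part)^2)
  }
  d
}

# Distances of all examples to one centroid, vectorized.
# Uses the expansion |x - c|^2_p = x^2.p - 2 x.(p*c) + sum(p*c^2) so sparse
# feature matrices stay sparse.
.dist_all <- function(Xs, Xs2, Ys, Ys2, cx, cy, px, py) {
  n <- nrow(Xs)
  L <- nrow(Ys)
  d <- as.numeric(Xs2 %*% px) - 2 * as.numeric(Xs %*% (px * cx)) +
    sum(px * cx * cx)
  d[seq_len(L)] <- d[seq_len(L)] +
    as.numeric(Ys2 %*% py) - 2 * as.numeric(Ys %*% (py * cy)) +
    sum(py * cy * cy)
  d
}

#' Semi-supervised 2-means clustering
#'
#' Groups the examples into two clusters over the joint (feature, target)
#' space. Initial centroids are two distinct labeled examples chosen at
#' random. Each iteration assigns every example to the nearer centroid
#' under [ss_distance()] (distance ties are broken uniformly at random) and
#' recomputes centroids: feature parts as means over all members, target
#' parts as means over labeled members only. A cluster that loses all
#' members, or all labeled members, is re-seeded from a random labeled
#' example. Iteration stops early when the assignment is unchanged.
#'
#' @param Xs Standardized features `(L+U) x D`, labeled rows first.
#' @param Ys Standardized targets `L x T`.
#' @param p Scaled clustering weights, length `D + T`.
#' @param iters Maximum iterations (default 10).
#' @return `NULL` when fewer than two distinct labeled seeds exist
#'   ("unsplittable"); otherwise a list with the 0/1 assignment `s`,
#'   `objective` (the within-cluster distance total after each assignment
#'   pass; non-increasing except immediately after a re-seed) and
#'   `reseeds`, the indices of assignment passes preceded by a re-seed.
#' @export
kmeans_semisupervised <- function(Xs, Ys, p, iters = 10L) {
  n <- nrow(Xs)
  L <- nrow(Ys)
  D <- ncol(Xs)
  Tn <- ncol(Ys)
  stopifnot(length(p) == D + Tn, n >= L, iters >= 1)
  if (L < 2L) return(NULL)
  px <- p[seq_len(D)]
  py <- p[D + seq_len(Tn)]
  Xs2 <- Xs * Xs
  Ys2 <- Ys * Ys

  joint_row <- function(i) c(as.numeric(Xs[i, ]), Ys[i, ])
  seeds <- NULL
  for (try in seq_len(10L)) {
    cand <- sample.int(L, 2L)
    if (!isTRUE(all.equal(joint_row(cand[1L]), joint_row(cand[2L]),
                          tolerance = 0))) {
      seeds <- cand
      break
    }
  }
  if (is.null(seeds)) {
    # exhaustive fallback before declaring the node unsplittable
    found <- FALSE
    for (i in seq_len(L - 1L)) {
      if (!isTRUE(all.equal(joint_row(i), joint_row(i + 1L), tolerance = 0))) {
        seeds <- c(i, i + 1L)
        found <- TRUE
        break
      }
    }
    if (!found && !isTRUE(all.equal(joint_row(1L), joint_row(L),
                                    tolerance = 0))) {
      seeds <- c(1L, L)
      found <- TRUE
    }
    if (!found) return(NULL)
  }
  cx0 <- as.numeric(Xs[seeds[1L], ]); cy0 <- as.numeric(Ys[seeds[1L], ])
  cx1 <- as.numeric(Xs[seeds[2L], ]); cy1 <- as.numeric(Ys[seeds[2L], ])

  s <- rep(-1L, n)
  objective <- numeric(0)
  reseeds <- integer(0)
  reseed_pending <- FALSE
  for (it in seq_len(iters)) {
    if (reseed_pending) {
      reseeds <- c(reseeds, it)
      reseed_pending <- FALSE
    }
    d0 <- .dist_all(Xs, Xs2, Ys, Ys2, cx0, cy0, px, py)
    d1 <- .dist_all(Xs, Xs2, Ys, Ys2, cx1, cy1, px, py)
    s_new <- as.integer(d1 < d0)
    tie <- which(d1 == d0)
    if (length(tie) > 0L) {
      s_new[tie] <- sample(c(0L, 1L), length(tie), replace = TRUE)
    }
    objective <- c(objective, sum(ifelse(s_new == 1L, d1, d0)))
    if (identical(s_new, s)) break
    s <- s_new
    for (cl in c(0L, 1L)) {
      memb <- which(s == cl)
      lab <- memb[memb <= L]
      if (length(memb) == 0L || length(lab) == 0L) {
        r <- sample.int(L, 1L)
        memb <- r
        lab <- r
        reseed_pending <- TRUE
      }
      cx <- as.numeric(Matrix::colMeans(Xs[memb, , drop = FALSE]))
      cy <- colMeans(Ys[lab, , drop = FALSE])
      if (cl == 0L) { cx0 <- cx; cy0 <- cy } else { cx1 <- cx; cy1 <- cy }
    }
  }
  if (length(unique(s)) < 2L) return(NULL)
  list(s = s, objective = objective, reseeds = reseeds)
}

#' L1-regularized squared-hinge SVM objective
#'
#' `||w||_1 + C * sum(max(0, 1 - y * (X w + b))^2)` with labels
#' `y in {-1, +1}`.
#'
#' @param w Weight vector, length `D`.
#' @param b Bias.
#' @param Xs Feature matrix `n x D`.
#' @param y_pm Label vector in `{-1, +1}`.
#' @param C Regularization strength.
#' @return Objective value.
#' @export
svm_objective <- function(w, b, Xs, y_pm, C) {
  z <- as.numeric(Xs %*% w) + b
  sum(abs(w)) + C * sum(pmax(0, 1 - y_pm * z)^2)
}

# Proximal-gradient (ISTA) solver for the L1-regularized squared-hinge
# objective, with backtracking line search on the smooth part. Soft
# thresholding applies to w only; b is unpenalized.
.solve_l1_svm <- function(Xs, y_pm, C, opt_iters = 100L, tol = 1e-4) {
  n <- nrow(Xs)
  D <- ncol(Xs)
  w <- rep(0, D)
  b <- 0
  smooth <- function(w, b) {
    r <- pmax(0, 1 - y_pm * (as.numeric(Xs %*% w) + b))
    list(h = C * sum(r^2), r = r)
  }
  sm <- smooth(w, b)
  obj <- sum(abs(w)) + sm$h
  t_step <- 1
  for (it in seq_len(opt_iters)) {
    gz <- -2 * C * sm$r * y_pm
    gw <- as.numeric(Matrix::crossprod(Xs, gz))
    gb <- sum(gz)
    repeat {
      w_new <- sign(w - t_step * gw) * pmax(abs(w - t_step * gw) - t_step, 0)
      b_new <- b - t_step * gb
      sm_new <- smooth(w_new, b_new)
      dw <- w_new - w
      db <- b_new - b
      if (sm_new$h <= sm$h + sum(gw * dw) + gb * db +
            (sum(dw^2) + db^2) / (2 * t_step) + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    obj_new <- sum(abs(w_new)) + sm_new$h
    rel <- abs(obj - obj_new) / max(abs(obj), 1e-12)
    w <- w_new; b <- b_new; sm <- sm_new; obj <- obj_new
    if (rel < tol) break
    t_step <- min(t_step * 1.25, 1e6)
  }
  list(w = w, b = b, objective = obj)
}

#' Learn one oblique split with the SVM variant
#'
#' Clusters the node's examples into two groups by semi-supervised 2-means
#' over the weighted (feature, target) space, then approximates the cluster
#' partition with a sparse linear separator over the features by minimizing
#' the L1-regularized squared-hinge objective (cluster indicators mapped to
#' -1/+1 labels).
#'
#' @inheritParams kmeans_semisupervised
#' @param config A `spyct_config`.
#' @return List `(w, b)` in standardized-feature coordinates, or `NULL`
#'   when the node is unsplittable or the learned hyperplane leaves one
#'   side empty.
#' @export
learn_split_svm <- function(Xs, Ys, p, config) {
  km <- kmeans_semisupervised(Xs, Ys, p, iters = config$clust_iters)
  if (is.null(km)) return(NULL)
  y_pm <- 2 * km$s - 1
  fit <- .solve_l1_svm(Xs, y_pm, config$C,
                       opt_iters = config$opt_iters, tol = config$svm_tol)
  z <- as.numeric(Xs %*% fit$w) + fit$b
  side <- z >= 0
  if (all(side) || !any(side)) return(NULL)
  list(w = fit$w, b = fit$b)
}
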