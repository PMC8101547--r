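#' Weighted mean and weighted variance
#'
#' `weighted_variance(v, a)` is the population-style weighted variance
#' `mean(v^2, a) - mean(v, a)^2` with `mean(v, a) = sum(a * v) / sum(a)`.
#' When the total weight is zero (an empty fuzzy group) the variance is
#' defined as 0.
#'
#' @param v Numeric vector.
#' @param a Nonnegative weight vector of the same length.
#' @return A single number.
#' @export
weighted_mean <- function(v, a) {
  A <- sum(a)
  if (A <= 0) return(0)
  sum(a * v) / A
}

#' @rdname weighted_mean
#' @export
weighted_variance <- function(v, a) {
  A <- sum(a)
  if (A <= 0) return(0)
  m1 <- sum(a * v) / A
  m2 <- sum(a * v * v) / A
  max(m2 - m1 * m1, 0)
}

# Column-wise weighted variances of a matrix under weights a (no clamping;
# tiny negative values from cancellation are tolerated by callers).
.wvar_cols <- function(M, a, A = sum(a)) {
  if (A <= 1e-12) return(rep(0, ncol(M)))
  m1 <- as.numeric(Matrix::crossprod(M, a)) / A
  m2 <- as.numeric(Matrix::crossprod(M * M, a)) / A
  m2 - m1 * m1
}

#' Impurity of one fuzzy group
#'
#' The impurity of a group with membership weights `s` is the priority-
#' weighted sum of per-attribute weighted variances: features are weighted
#' over all examples, targets over the labeled examples only (the first
#' `nrow(Ys)` entries of `s`). The negative group's impurity is obtained by
#' passing `1 - s`.
#'
#' @param Xs Standardized feature matrix `(L+U) x D`.
#' @param Ys Standardized target matrix `L x T` (labeled rows).
#' @param s Membership weights in `[0, 1]`, length `L + U`.
#' @param p Scaled clustering-weight vector of length `D + T`.
#' @return Nonnegative impurity value.
#' @export
group_impurity <- function(Xs, Ys, s, p) {
  D <- ncol(Xs)
  Tn <- ncol(Ys)
  L <- nrow(Ys)
  stopifnot(length(p) == D + Tn, length(s) == nrow(Xs), nrow(Xs) >= L)
  px <- p[seq_len(D)]
  py <- p[D + seq_len(Tn)]
  imp <- 0
  if (any(px > 0)) imp <- imp + sum(px * .wvar_cols(Xs, s))
  if (any(py > 0)) imp <- imp + sum(py * .wvar_cols(Ys, s[seq_len(L)]))
  max(imp, 0)
}

#' Fitness of an oblique split hyperplane
#'
#' For a hyperplane `(w, b)` the fuzzy membership is `s = sigmoid(Xs w + b)`
#' and the fitness is the size-weighted impurity of the two fuzzy groups,
#' `S * imp(s, p) + (L + U - S) * imp(1 - s, p)` with `S = sum(s)`. The size
#' factors steer the search towards balanced splits. The function is
#' differentiable in `(w, b)`; [split_fitness_grad()] returns the analytic
#' gradient.
#'
#' @inheritParams group_impurity
#' @param w Weight vector of length `D`.
#' @param b Bias scalar.
#' @return Nonnegative fitness value (lower is better).
#' @export
split_fitness <- function(w, b, Xs, Ys, p) {
  s <- stats::plogis(as.numeric(Xs %*% w) + b)
  n <- nrow(Xs)
  S <- sum(s)
  S * group_impurity(Xs, Ys, s, p) +
    (n - S) * group_impurity(Xs, Ys, 1 - s, p)
}

#' @rdname split_fitness
#' @return For `split_fitness_grad`: a list with the fitness `value`,
#'   `grad_w` (length `D`) and `grad_b` (scalar).
#' @export
split_fitness_grad <- function(w, b, Xs, Ys, p) {
  .fitness_grad_impl(w, b, .fitness_precomp(Xs, Ys, p))
}

# Per-split precomputation shared by all optimizer iterations: squared
# matrices, column sums (the negative group's weighted sums are the
# complements of the positive group's) and the w-independent row terms
# Xs^2 p_x and Ys^2 p_y appearing in the gradient.
.fitness_precomp <- function(Xs, Ys, p) {
  D <- ncol(Xs)
  Tn <- ncol(Ys)
  px <- p[seq_len(D)]
  py <- p[D + seq_len(Tn)]
  Xs2 <- Xs * Xs
  Ys2 <- Ys * Ys
  list(
    Xs = Xs, Ys = Ys, Xs2 = Xs2, Ys2 = Ys2, px = px, py = py,
    use_x = any(px > 0), use_y = any(py > 0),
    csx = as.numeric(Matrix::colSums(Xs)),
    csx2 = as.numeric(Matrix::colSums(Xs2)),
    csy = colSums(Ys), csy2 = colSums(Ys2),
    qx = as.numeric(Xs2 %*% px), qy = as.numeric(Ys2 %*% py),
    n = nrow(Xs), L = nrow(Ys)
  )
}

# Shared implementation. Uses, for weights a over rows,
# d var(v, a) / d a_i = ((v_i - m1)^2 - var) / A, expanded so that the
# row-wise term is a matrix-vector product.
.fitness_grad_impl <- function(w, b, pc) {
  Xs <- pc$Xs; Ys <- pc$Ys
  n <- pc$n; L <- pc$L
  px <- pc$px; py <- pc$py
  z <- as.numeric(Xs %*% w) + b
  s <- stats::plogis(z)
  S <- sum(s)
  sl <- s[seq_len(L)]
  Sl <- sum(sl)

  t1 <- if (pc$use_x) as.numeric(Matrix::crossprod(Xs, s)) else NULL
  t2 <- if (pc$use_x) as.numeric(Matrix::crossprod(pc$Xs2, s)) else NULL
  u1 <- if (pc$use_y) as.numeric(Matrix::crossprod(Ys, sl)) else NULL
  u2 <- if (pc$use_y) as.numeric(Matrix::crossprod(pc$Ys2, sl)) else NULL

  # imp and d imp / d a for one group; xs1/xs2 = weighted column sums of
  # Xs and Xs^2 under this group's weights (complements for 1 - s)
  group <- function(Ax, Ay, xs1, xs2, ys1, ys2) {
    imp <- 0
    g <- rep(0, n)
    if (pc$use_x && Ax > 1e-12) {
      m1 <- xs1 / Ax
      varx <- xs2 / Ax - m1 * m1
      imp <- imp + sum(px * varx)
      g <- g + (pc$qx - 2 * as.numeric(Xs %*% (px * m1)) +
                  sum(px * m1 * m1) - sum(px * varx)) / Ax
    }
    if (pc$use_y && Ay > 1e-12) {
      m1 <- ys1 / Ay
      vary <- ys2 / Ay - m1 * m1
      imp <- imp + sum(py * vary)
      gl <- (pc$qy - 2 * as.numeric(Ys %*% (py * m1)) +
               sum(py * m1 * m1) - sum(py * vary)) / Ay
      g[seq_len(L)] <- g[seq_len(L)] + gl
    }
    list(imp = imp, g = g)
  }

  pos <- group(S, Sl, t1, t2, u1, u2)
  neg <- group(n - S, L - Sl,
               if (pc$use_x) pc$csx - t1, if (pc$use_x) pc$csx2 - t2,
               if (pc$use_y) pc$csy - u1, if (pc$use_y) pc$csy2 - u2)
  value <- S * pos$imp + (n - S) * neg$imp
  dfds <- pos$imp - neg$imp + S * pos$g - (n - S) * neg$g
  dz <- dfds * s * (1 - s)
  list(
    value = value,
    grad_w = as.numeric(Matrix::crossprod(Xs, dz)),
    grad_b = sum(dz)
  )
}
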