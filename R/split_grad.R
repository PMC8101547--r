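#' Learn one oblique split with the gradient variant
#'
#' Minimizes `||w||_{1/2} + C * f(w, b)` with Adam, where `f` is the fuzzy
#' size-weighted two-group impurity ([split_fitness()]) and the sparsity
#' penalty is the smoothed quasi-norm `sum(sqrt(|w_i| + 1e-8))`. Weights
#' are initialized from a standard normal scaled by `1/sqrt(D)`, the bias
#' at 0. The iterate with the lowest objective seen is returned. The hard
#' partition thresholds the fuzzy membership at 0.5 (sigmoid argument at
#' 0), ties going to the positive side. Dense features run through the
#' compiled core; sparse features through the R implementation.
#'
#' @param Xs Standardized features `(L+U) x D`, labeled rows first.
#' @param Ys Standardized targets `L x T`.
#' @param p Scaled clustering weights, length `D + T`.
#' @param config A `spyct_config` (uses `C`, `opt_iters`, `adam_*`).
#' @return List `(w, b)` in standardized-feature coordinates, or `NULL`
#'   when the hard partition leaves one side empty.
#' @export
learn_split_grad <- function(Xs, Ys, p, config) {
  D <- ncol(Xs)
  w0 <- stats::rnorm(D) / sqrt(D)
  best <- if (inherits(Xs, "Matrix")) {
    .learn_split_grad_r(Xs, Ys, p, w0, config)
  } else {
    .cpp_learn_split_grad(Xs, Ys, p, w0, config$C, config$opt_iters,
                          config$adam_lr, config$adam_beta1,
                          config$adam_beta2, config$adam_eps)
  }
  best$w <- as.numeric(best$w)
  z <- as.numeric(Xs %*% best$w) + best$b
  side <- z >= 0
  if (all(side) || !any(side)) return(NULL)
  list(w = best$w, b = best$b, objective = best$objective)
}

# Reference Adam loop in R (also the sparse-input path).
.learn_split_grad_r <- function(Xs, Ys, p, w0, config) {
  eps_pen <- 1e-8
  pc <- .fitness_precomp(Xs, Ys, p)
  w <- w0
  b <- 0
  mw <- rep(0, length(w)); vw <- rep(0, length(w))
  mb <- 0; vb <- 0
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  eps <- config$adam_eps; lr <- config$adam_lr
  C <- config$C
  best <- NULL
  for (it in seq_len(config$opt_iters + 1L)) {
    fg <- .fitness_grad_impl(w, b, pc)
    obj <- sum(sqrt(abs(w) + eps_pen)) + C * fg$value
    if (!is.finite(obj)) {
      stop("non-finite split objective at Adam iteration ", it)
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(w = w, b = b, objective = obj)
    }
    if (it > config$opt_iters) break
    gw <- sign(w) / (2 * sqrt(abs(w) + eps_pen)) + C * fg$grad_w
    gb <- C * fg$grad_b
    mw <- b1 * mw + (1 - b1) * gw
    vw <- b2 * vw + (1 - b2) * gw^2
    mb <- b1 * mb + (1 - b1) * gb
    vb <- b2 * vb + (1 - b2) * gb^2
    corr1 <- 1 - b1^it
    corr2 <- 1 - b2^it
    w <- w - lr * (mw / corr1) / (sqrt(vw / corr2) + eps)
    b <- b - lr * (mb / corr1) / (sqrt(vb / corr2) + eps)
  }
  best
}
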