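#' Fit a per-column standardization
#'
#' Computes column means and population standard deviations over a row
#' subset (for target columns: the labeled rows). Zero-variance columns get
#' sigma = 1 so they standardize to zeros. Sparse feature matrices are
#' scaled only (no centering), which preserves sparsity; dense matrices are
#' centered and scaled.
#'
#' @param M Numeric matrix (dense or `Matrix` sparse).
#' @param rows Row subset to fit on (default all rows); must be non-empty.
#' @param center Whether to subtract the mean (default: dense yes, sparse no).
#' @return List with `mu`, `sigma` and `center`, class `spyct_standardization`.
#' @export
standardize_fit <- function(M, rows = seq_len(nrow(M)),
                            center = !inherits(M, "Matrix")) {
  if (length(rows) == 0L) stop("standardize_fit: empty row subset")
  Msub <- M[rows, , drop = FALSE]
  mu <- as.numeric(Matrix::colMeans(Msub))
  # population variance: E[x^2] - mu^2
  m2 <- as.numeric(Matrix::colMeans(Msub * Msub))
  v <- pmax(m2 - mu^2, 0)
  sigma <- sqrt(v)
  sigma[sigma < 1e-12] <- 1
  if (!center) mu <- rep(0, length(mu))
  structure(list(mu = mu, sigma = sigma, center = center),
            class = "spyct_standardization")
}

#' Apply a stored standardization
#'
#' @param M Matrix whose columns match the fitted standardization.
#' @param st A `spyct_standardization` from [standardize_fit()].
#' @return Standardized matrix of the same shape (sparse in, sparse out when
#'   no centering is involved).
#' @export
standardize_apply <- function(M, st) {
  stopifnot(inherits(st, "spyct_standardization"))
  if (ncol(M) != length(st$mu)) {
    stop("standardize_apply: expected ", length(st$mu), " columns, got ",
         ncol(M))
  }
  if (inherits(M, "Matrix")) {
    out <- M %*% Matrix::Diagonal(x = 1 / st$sigma)
    if (st$center && any(st$mu != 0)) {
      out <- out - matrix(st$mu / st$sigma, nrow(M), ncol(M), byrow = TRUE)
    }
    out
  } else {
    out <- sweep(M, 2L, st$sigma, "/")
    if (st$center) out <- sweep(out, 2L, st$mu / st$sigma, "-")
    out
  }
}

#' Invert a standardization (dense matrices)
#'
#' @param Ms Standardized matrix.
#' @param st The `spyct_standardization` used to produce it.
#' @return Matrix on the original scale.
#' @export
standardize_invert <- function(Ms, st) {
  stopifnot(inherits(st, "spyct_standardization"))
  out <- sweep(as.matrix(Ms), 2L, st$sigma, "*")
  if (st$center) out <- sweep(out, 2L, st$mu, "+")
  out
}
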