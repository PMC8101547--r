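#' Scale clustering weights to a supervision degree
#'
#' Clustering weights prioritize the `D + T` clustering attributes
#' (features, then targets) when a split is scored. The supervision degree
#' `omega` fixes how the total mass is divided: the feature block is scaled
#' to sum to `1 - omega` and the target block to sum to `omega`, preserving
#' proportions within each block. `omega = 0` ignores target impurity
#' (unsupervised growth); `omega = 1` ignores feature impurity (fully
#' supervised, unlabeled examples have no influence).
#'
#' @param p_raw Nonnegative vector of length `D + T` of unscaled priorities
#'   (uniform by default within each block; depth weights for HMLC targets).
#' @param D Number of feature attributes (first block).
#' @param omega Supervision degree in `[0, 1]`.
#' @return List with `p` (scaled weights), `omega`, `D`, `T`; class
#'   `spyct_weights`.
#' @export
scale_clustering_weights <- function(p_raw, D, omega) {
  p_raw <- as.numeric(p_raw)
  stopifnot(length(p_raw) > D, D >= 1, omega >= 0, omega <= 1)
  if (any(p_raw < 0)) stop("clustering weights must be nonnegative")
  Tn <- length(p_raw) - D
  fb <- p_raw[seq_len(D)]
  tb <- p_raw[D + seq_len(Tn)]
  if (omega < 1) {
    s <- sum(fb)
    if (s <= 0) stop("feature-block weights sum to 0 but omega < 1")
    fb <- fb * (1 - omega) / s
  } else {
    fb <- rep(0, D)
  }
  if (omega > 0) {
    s <- sum(tb)
    if (s <= 0) stop("target-block weights sum to 0 but omega > 0")
    tb <- tb * omega / s
  } else {
    tb <- rep(0, Tn)
  }
  structure(list(p = c(fb, tb), omega = omega, D = D, T = Tn),
            class = "spyct_weights")
}

# Unscaled per-attribute priorities for a dataset: uniform over features;
# uniform over targets except HMLC, where the depth weights 0.75^d apply.
.base_priorities <- function(data) {
  tb <- if (data$task == "HMLC") {
    unname(data$hierarchy$label_weight)
  } else {
    rep(1, data$T)
  }
  c(rep(1, data$D), tb)
}
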