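#' Scatter matrix and mean vector of selected features
#'
#' Computes the mean vector and the unnormalized scatter matrix
#' `S = sum_i (x_i - mean)(x_i - mean)^T` over sample vectors (n times the
#' biased covariance), plus per-feature normalization scales
#' `sqrt(diag(S)/n)` (the biased standard deviations).
#'
#' @param x Matrix of sample vectors (n x p), typically the selected
#'   feature columns of the training split.
#' @return Object of class `scatter_summary`: `mean`, `scatter`, `scale`,
#'   `n`, `zero_variance` (logical per feature).
#' @export
scatter_summary <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1) stop("need at least one sample vector")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- crossprod(xc)            # sum of centered outer products
  if (n < 2) warning("single sample: scatter matrix is identically zero")
  scale <- sqrt(diag(s) / n)
  zero_var <- scale <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(zero_var)) scale[zero_var] <- 1  # pass through centered
  structure(list(mean = mu, scatter = s, scale = scale, n = n,
                 zero_variance = zero_var),
            class = "scatter_summary")
}

#' Normalize features by a fitted scatter summary
#'
#' Column-wise affine map `(x - mean) / scale`; on the data the summary was
#' fitted on this gives mean 0 and biased variance 1 per column.
#' Zero-variance columns are centered with scale 1.
#'
#' @param x Feature matrix with the summary's column count.
#' @param summary A [scatter_summary()] fitted on the training split.
#' @return Normalized matrix.
#' @export
normalize_features <- function(x, summary) {
  x <- as.matrix(x)
  if (ncol(x) != length(summary$mean)) {
    stop("dimension mismatch: summary was fitted on a different feature set")
  }
  sweep(sweep(x, 2, summary$mean), 2, summary$scale, "/")
}

#' Invert [normalize_features()]
#' @param z Normalized matrix.
#' @param summary The fitting [scatter_summary()].
#' @export
denormalize_features <- function(z, summary) {
  sweep(sweep(as.matrix(z), 2, summary$scale, "*"), 2, summary$mean, "+")
}

#' Whiten features by the full scatter matrix
#'
#' Optional alternative to per-feature scaling: multiplies centered
#' features by the inverse symmetric square root of `scatter/n`
#' (eigenvalues floored at a small ridge for stability).
#'
#' @param x Feature matrix.
#' @param summary A [scatter_summary()].
#' @param ridge Eigenvalue floor (default 1e-8).
#' @export
whiten_features <- function(x, summary, ridge = 1e-8) {
  xc <- sweep(as.matrix(x), 2, summary$mean)
  eig <- eigen(summary$scatter / summary$n, symmetric = TRUE)
  w <- eig$vectors %*% diag(1 / sqrt(pmax(eig$values, ridge)),
                            length(eig$values)) %*% t(eig$vectors)
  xc %*% w
}
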