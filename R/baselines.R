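# Classical linear compression baselines. PCA projects mean-centered beats
# onto the top-k principal directions; the SVD variant projects raw
# (uncentered) beats onto the top-k right singular vectors of the training
# matrix. Both reduce a beat of length n to k coefficients and are used as
# drop-in replacements for the learned compressor in benchmarks.

#' Fit a PCA compressor
#'
#' @param train_beats Numeric matrix (n_beats x beat_length) of training
#'   beats (or a [beat_dataset()]).
#' @param k Number of components to keep (<= beat_length).
#' @return A `pca_basis` list with the training mean and the k principal
#'   directions (columns, orthonormal).
#' @export
pca_fit <- function(train_beats, k) {
  X <- if (inherits(train_beats, "beat_dataset")) train_beats$beats
       else as.matrix(train_beats)
  if (nrow(X) < 2) stop("PCA needs at least 2 training beats")
  k <- as.integer(k)
  if (k < 1 || k > ncol(X)) stop("k must be in [1, beat_length]")
  if (k > min(nrow(X) - 1, ncol(X)))
    stop("k = ", k, " exceeds the PCA rank limit min(n_beats - 1, ",
         "beat_length) = ", min(nrow(X) - 1, ncol(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(center = pc$center, rotation = pc$rotation[, seq_len(k),
                                                            drop = FALSE],
                 sdev = pc$sdev[seq_len(k)], k = k),
            class = "pca_basis")
}

#' Project beats onto a fitted PCA basis
#'
#' @param basis A [pca_fit()] result.
#' @param beats Matrix or [beat_dataset()] with the training beat length.
#' @return Matrix (n_beats x k) of principal-component scores.
#' @export
pca_transform <- function(basis, beats) {
  stopifnot(inherits(basis, "pca_basis"))
  X <- if (inherits(beats, "beat_dataset")) beats$beats else as.matrix(beats)
  if (ncol(X) != length(basis$center))
    stop("beat length ", ncol(X), " does not match the fitted basis (",
         length(basis$center), ")")
  sweep(X, 2, basis$center, "-") %*% basis$rotation
}

#' Fit an SVD compressor
#'
#' Right singular vectors of the raw (uncentered) training matrix.
#'
#' @inheritParams pca_fit
#' @return An `svd_basis` list with the k right singular vectors (columns)
#'   and singular values.
#' @export
svd_fit <- function(train_beats, k) {
  X <- if (inherits(train_beats, "beat_dataset")) train_beats$beats
       else as.matrix(train_beats)
  if (nrow(X) < 2) stop("SVD needs at least 2 training beats")
  k <- as.integer(k)
  if (k < 1 || k > ncol(X)) stop("k must be in [1, beat_length]")
  if (k > min(dim(X)))
    stop("k = ", k, " exceeds the SVD rank limit min(n_beats, beat_length) = ",
         min(dim(X)))
  s <- svd(X, nu = 0, nv = k)
  structure(list(v = s$v, d = s$d[seq_len(min(k, length(s$d)))], k = k),
            class = "svd_basis")
}

#' Project beats onto a fitted SVD basis
#'
#' @param basis An [svd_fit()] result.
#' @inheritParams pca_transform
#' @return Matrix (n_beats x k) of coefficients.
#' @export
svd_transform <- function(basis, beats) {
  stopifnot(inherits(basis, "svd_basis"))
  X <- if (inherits(beats, "beat_dataset")) beats$beats else as.matrix(beats)
  if (ncol(X) != nrow(basis$v))
    stop("beat length ", ncol(X), " does not match the fitted basis (",
         nrow(basis$v), ")")
  X %*% basis$v
}
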