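#' Fit a PCA feature model on training spectra
#'
#' Computes the top-`J` principal axes of the empirical covariance of the
#' mean-centered training spectra, via singular value decomposition of the
#' centered data matrix (numerically stabler than forming the covariance).
#' The eigenvector sign is fixed by making the largest-magnitude loading of
#' every component positive, so fits are reproducible across linear-algebra
#' backends.  The model is fit on training spectra only; test spectra are
#' centered with the training mean at projection time.
#'
#' @param train a [thz_dataset()] (or numeric matrix, samples x subbands).
#' @param J number of components to keep, `1 <= J <= min(N - 1, I)` and no
#'   larger than the numerical rank of the centered data.
#' @return An object of class `pca_model` with fields `mean_spectrum`,
#'   `loadings` (I x J, orthonormal), `eigenvalues` (variances of the PCs,
#'   non-increasing), `explained_ratio`, `n_train`, `total_variance`.
#' @examples
#' d <- generate_dataset(2, 5, 60, seed = 3)
#' m <- fit_pca(d, 2)
#' m$explained_ratio
#' @export
fit_pca <- function(train, J) {
  X <- if (inherits(train, "thz_dataset")) train$absorbance else as.matrix(train)
  N <- nrow(X); I <- ncol(X)
  if (J < 1 || J > min(N - 1, I))
    stop("J must satisfy 1 <= J <= min(N - 1, I) = ", min(N - 1, I))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(N - 1, I))
  eig_all <- sv$d[seq_len(min(N - 1, I))]^2 / (N - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (J > rank)
    stop("J = ", J, " exceeds the numerical rank of the centered data (",
         rank, ")")
  V <- sv$v[, seq_len(J), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(J)) {
    p <- which.max(abs(V[, j]))
    if (V[p, j] < 0) V[, j] <- -V[, j]
  }
  total <- sum(eig_all)
  structure(list(mean_spectrum = mu, loadings = V,
                 eigenvalues = eig_all[seq_len(J)],
                 explained_ratio = eig_all[seq_len(J)] / total,
                 n_train = N, total_variance = total),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", ncol(x$loadings), " components over ",
      length(x$mean_spectrum), " subbands; explained variance ",
      format(100 * sum(x$explained_ratio), digits = 6), "%\n", sep = "")
  invisible(x)
}

#' Project spectra onto a fitted PCA model
#'
#' Centers `X` with the training mean and projects onto the loadings:
#' `scores = (X - mean) %*% loadings`.
#'
#' @param model a [fit_pca()] result.
#' @param X a [thz_dataset()] or numeric matrix/vector with `I` columns.
#' @return Numeric score matrix, samples x J.
#' @export
pca_project <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(X, "thz_dataset")) X <- X$absorbance
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$mean_spectrum))
    stop("X has ", ncol(X), " columns; model expects ",
         length(model$mean_spectrum))
  sweep(X, 2, model$mean_spectrum) %*% model$loadings
}

#' Reconstruct spectra from PCA scores
#'
#' @param model a [fit_pca()] result.
#' @param scores numeric matrix, samples x J.
#' @return Numeric matrix of reconstructed spectra (exact when `J` spans
#'   the full rank of the training data and scores came from
#'   [pca_project()]).
#' @export
pca_reconstruct <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  sweep(scores %*% t(model$loadings), 2, model$mean_spectrum, "+")
}
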