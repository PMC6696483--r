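#' Kernel parameter vector
#'
#' Parameters of the kernel menu used by the classifier, collected in one
#' validated object: the polynomial degree `d` and offset `beta0`, the
#' perceptron gains `beta0`/`beta1`, the Gaussian radial-basis-function
#' width `sigma2`, and the soft-margin penalty `C`.
#'
#' Kernel forms:
#' \itemize{
#'   \item polynomial: \eqn{k(z_r, z_s) = (z_r^T z_s + \beta_0)^d},
#'     \eqn{d \ge 1}, \eqn{\beta_0 \ge 0};
#'   \item grbf: \eqn{k(z_r, z_s) = \exp(-\|z_r - z_s\|^2 / (2\sigma^2))},
#'     \eqn{\sigma^2 > 0};
#'   \item perceptron: \eqn{k(z_r, z_s) = \tanh(\beta_0 z_r^T z_s + \beta_1)},
#'     \eqn{\beta_0, \beta_1 > 0}.
#' }
#'
#' @param family one of `"polynomial"`, `"grbf"`, `"perceptron"`.
#' @param d polynomial degree, integer >= 1.
#' @param beta0 polynomial offset (>= 0) / perceptron gain (> 0).
#' @param beta1 perceptron offset, > 0.
#' @param sigma2 GRBF width parameter, > 0.
#' @param C soft-margin box bound on the dual variables, > 0 (default 1).
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(family = c("grbf", "polynomial", "perceptron"),
                          d = 2, beta0 = 1, beta1 = 1, sigma2 = 1, C = 1) {
  family <- match.arg(family)
  if (family == "polynomial" && (d < 1 || d != round(d) || beta0 < 0))
    stop("polynomial kernel requires integer d >= 1 and beta0 >= 0")
  if (family == "grbf" && sigma2 <= 0)
    stop("grbf kernel requires sigma2 > 0")
  if (family == "perceptron" && (beta0 <= 0 || beta1 <= 0))
    stop("perceptron kernel requires beta0 > 0 and beta1 > 0")
  if (C <= 0) stop("soft-margin parameter C must be > 0")
  structure(list(family = family, d = as.integer(d), beta0 = beta0,
                 beta1 = beta1, sigma2 = sigma2, C = C),
            class = "kernel_params")
}

#' Evaluate a kernel for one pair of score vectors
#'
#' @param k a [kernel_params()].
#' @param zr,zs numeric vectors of equal length.
#' @return A single kernel value.
#' @examples
#' kernel_value(kernel_params("grbf", sigma2 = 1), c(0, 0), c(1, 1))
#' @export
kernel_value <- function(k, zr, zs) {
  if (length(zr) != length(zs)) stop("zr and zs must have equal length")
  if (!all(is.finite(zr)) || !all(is.finite(zs)))
    stop("non-finite kernel inputs")
  drop(kernel_matrix(k, matrix(zr, 1), matrix(zs, 1)))
}

#' Kernel (Gram) matrix between score sets
#'
#' For GRBF and polynomial kernels the matrix over a single set is
#' symmetric positive semi-definite (Mercer kernels); the sigmoid
#' perceptron kernel is not PSD in general.
#'
#' @param k a [kernel_params()].
#' @param Z numeric matrix, rows are score vectors.
#' @param Z2 optional second matrix; if given, the cross-kernel
#'   `K[i, j] = k(Z[i, ], Z2[j, ])` is returned.
#' @return Numeric matrix `nrow(Z) x nrow(Z2 %||% Z)`.
#' @export
kernel_matrix <- function(k, Z, Z2 = NULL) {
  stopifnot(inherits(k, "kernel_params"))
  Z <- as.matrix(Z)
  sym <- is.null(Z2)
  Z2 <- if (sym) Z else as.matrix(Z2)
  if (!all(is.finite(Z)) || !all(is.finite(Z2)))
    stop("non-finite kernel inputs")
  if (k$family == "grbf") {
    K <- exp(-cross_sqdist(Z, Z2) / (2 * k$sigma2))
  } else {
    G <- tcrossprod(Z, Z2)
    K <- switch(k$family,
                polynomial = (G + k$beta0)^k$d,
                perceptron = tanh(k$beta0 * G + k$beta1))
  }
  if (sym) K <- (K + t(K)) / 2  # remove round-off asymmetry
  K
}

# squared Euclidean cross-distances, clipped at zero against round-off
cross_sqdist <- function(Z, Z2) {
  D <- outer(rowSums(Z^2), rowSums(Z2^2), "+") - 2 * tcrossprod(Z, Z2)
  pmax(D, 0)
}

#' Solve the soft-margin SVM dual by sequential minimal optimization
#'
#' Minimizes `1/2 lambda' H lambda - e' lambda` subject to
#' `y' lambda = 0` and `0 <= lambda_r <= C`, where
#' `H = (y y') * K`, using SMO with maximal-KKT-violation pair selection.
#' The bias is averaged over free support vectors (those with
#' `0 < lambda < C`), falling back to the midpoint of the KKT bounds when
#' none are free.
#'
#' @param K symmetric kernel matrix over the training set.
#' @param y numeric labels in `{-1, +1}`; both classes must be present.
#' @param C soft-margin box bound, > 0.
#' @param tol KKT violation tolerance (default 1e-3; tighten for
#'   high-precision solutions).
#' @param max_iter cap on pair updates (default `500 * R + 10000`).
#' @return List with `lambda`, `b`, `objective` (dual objective value),
#'   `iterations`, `converged`.
#' @export
solve_dual <- function(K, y, C = 1, tol = 1e-3, max_iter = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (length(y) != n) stop("length(y) must match nrow(K)")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(max_iter)) max_iter <- 500L * n + 10000L
  res <- smo_solve_cpp(K, as.numeric(y), C, tol, as.integer(max_iter))
  if (!res$converged)
    stop("SMO did not converge within ", max_iter,
         " pair updates (KKT gap ", format(res$kkt_gap, digits = 4), ")")
  list(lambda = res$alpha, b = res$b, objective = res$objective,
       iterations = res$iterations, converged = res$converged)
}

#' Train a binary kernel SVM on PC scores
#'
#' @param Z numeric score matrix (samples x J).
#' @param y labels in `{-1, +1}`.
#' @param kernel a [kernel_params()] (its `C` field is the soft margin).
#' @param tol SMO tolerance passed to [solve_dual()].
#' @param positive_class optional class id recorded on the model.
#' @return An object of class `binary_svm` storing the support vectors,
#'   their dual coefficients `lambda_r * y_r`, the bias, and the kernel.
#'   Vectors with `lambda <= 1e-8` are dropped.
#' @export
svm_train <- function(Z, y, kernel, tol = 1e-3, positive_class = NA_integer_) {
  Z <- as.matrix(Z)
  K <- kernel_matrix(kernel, Z)
  sol <- solve_dual(K, y, C = kernel$C, tol = tol)
  sv <- which(sol$lambda > 1e-8)
  structure(list(support_vectors = Z[sv, , drop = FALSE],
                 dual_coeffs = sol$lambda[sv] * y[sv],
                 lambda = sol$lambda[sv],
                 bias = sol$b,
                 kernel = kernel,
                 positive_class = positive_class,
                 objective = sol$objective,
                 n_train = length(y)),
            class = "binary_svm")
}

#' @export
print.binary_svm <- function(x, ...) {
  cat("<binary_svm> ", nrow(x$support_vectors), "/", x$n_train,
      " support vectors, ", x$kernel$family, " kernel, b = ",
      format(x$bias, digits = 4), "\n", sep = "")
  invisible(x)
}

#' SVM decision values
#'
#' `f(z) = sum_r lambda_r y_r k(x_r, z) + b`; the predicted side is
#' `sign(f)`.
#'
#' @param model a [svm_train()] result.
#' @param Z score vector or matrix with `J` columns.
#' @return Numeric vector of decision values, one per row of `Z`.
#' @export
decision_value <- function(model, Z) {
  stopifnot(inherits(model, "binary_svm"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != ncol(model$support_vectors))
    stop("Z has ", ncol(Z), " columns; model expects ",
         ncol(model$support_vectors))
  if (nrow(model$support_vectors) == 0)
    return(rep(model$bias, nrow(Z)))
  Kx <- kernel_matrix(model$kernel, Z, model$support_vectors)
  drop(Kx %*% model$dual_coeffs) + model$bias
}
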