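#' Misclassification count
#'
#' Number of positions where the predicted label differs from the truth —
#' the integer-valued objective minimized when learning kernel parameters.
#'
#' @param predicted,truth equal-length label vectors.
#' @return Integer count >= 0.
#' @export
mcr <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  sum(predicted != truth)
}

# Map an unconstrained search vector to kernel parameters via the
# elementwise exponential (all tunable kernel parameters are positive).
# The polynomial degree, if free, is rounded to the nearest integer >= 1.
ztilde_to_params <- function(ztilde, kernel, free) {
  if (length(ztilde) != length(free))
    stop("ztilde length must match the number of free parameters")
  if (any(!is.finite(ztilde))) stop("non-finite search vector")
  vals <- exp(ztilde)
  p <- unclass(kernel)
  for (i in seq_along(free)) {
    v <- vals[i]
    if (free[i] == "d") v <- max(1, round(v))
    p[[free[i]]] <- v
  }
  kernel_params(p$family, d = p$d, beta0 = p$beta0, beta1 = p$beta1,
                sigma2 = p$sigma2, C = p$C)
}

# Build a cached cross-validated-MCR objective over a binary task.
# For each fold the train/train and validation/train pairwise statistics
# (squared distances for the GRBF, inner products otherwise) are
# precomputed once, so each objective evaluation costs one elementwise
# kernel transform plus one SMO solve per fold.
make_cv_objective <- function(Z, y, folds, kernel, free = "sigma2",
                              svm_tol = 1e-3) {
  Z <- as.matrix(Z)
  stopifnot(length(y) == nrow(Z), all(y %in% c(-1, 1)))
  fold_ids <- sort(unique(folds))
  cache <- lapply(fold_ids, function(f) {
    tr <- folds != f; va <- folds == f
    Ztr <- Z[tr, , drop = FALSE]; Zva <- Z[va, , drop = FALSE]
    if (kernel$family == "grbf") {
      list(A_tr = cross_sqdist(Ztr, Ztr), A_va = cross_sqdist(Zva, Ztr),
           y_tr = y[tr], y_va = y[va])
    } else {
      list(A_tr = tcrossprod(Ztr), A_va = tcrossprod(Zva, Ztr),
           y_tr = y[tr], y_va = y[va])
    }
  })
  apply_kernel <- function(k, A) {
    switch(k$family,
           grbf = exp(-A / (2 * k$sigma2)),
           polynomial = (A + k$beta0)^k$d,
           perceptron = tanh(k$beta0 * A + k$beta1))
  }
  function(ztilde) {
    k <- ztilde_to_params(ztilde, kernel, free)
    total <- 0L
    for (fc in cache) {
      pred <- tryCatch({
        K <- apply_kernel(k, fc$A_tr)
        K <- (K + t(K)) / 2
        sol <- solve_dual(K, fc$y_tr, C = k$C, tol = svm_tol)
        sv <- sol$lambda > 1e-8
        f_va <- drop(apply_kernel(k, fc$A_va)[, sv, drop = FALSE] %*%
                       (sol$lambda[sv] * fc$y_tr[sv])) + sol$b
        ifelse(f_va > 0, 1, -1)
      }, error = function(e) {
        warning("SVM training failed in CV fold (", conditionMessage(e),
                "); scoring fold as fully misclassified", call. = FALSE)
        -fc$y_va
      })
      total <- total + mcr(pred, fc$y_va)
    }
    total
  }
}

#' Cross-validated misclassification objective for kernel training
#'
#' Maps the unconstrained search vector to kernel parameters through the
#' elementwise exponential (guaranteeing positivity), trains a binary
#' kernel SVM on each cross-validation training split, and returns the
#' summed misclassification count over the validation splits.
#' Deterministic given the fold assignment.
#'
#' @param ztilde unconstrained numeric vector, one entry per free
#'   parameter.
#' @param Z score matrix (samples x J).
#' @param y labels in `{-1, +1}`.
#' @param folds fold assignment from [stratified_folds()].
#' @param kernel a [kernel_params()] template supplying the fixed
#'   parameters.
#' @param free names of the parameters exposed to the search (subset of
#'   `d`, `beta0`, `beta1`, `sigma2`, `C`); default `"sigma2"`.
#' @param svm_tol SMO tolerance used inside the CV loop.
#' @return Integer misclassification count (>= 0).
#' @export
cv_mcr_objective <- function(ztilde, Z, y, folds,
                             kernel = kernel_params("grbf"),
                             free = "sigma2", svm_tol = 1e-3) {
  make_cv_objective(Z, y, folds, kernel, free, svm_tol)(ztilde)
}

#' Nelder-Mead simplex minimization
#'
#' Derivative-free direct search with the classical reflection (1),
#' expansion (2), contraction (0.5) and shrink (0.5) coefficients.  A
#' one-dimensional search uses the degenerate two-vertex simplex.  Because
#' the kernel-training objective is an integer count with large flat
#' plateaus, termination combines three rules: simplex diameter below
#' `tol`, an iteration cap, and a stall rule (no improvement of the best
#' vertex over `stall_iter` consecutive iterations).
#'
#' @param f objective function of a numeric vector.
#' @param x0 numeric starting point.
#' @param tol simplex diameter tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param step initial simplex edge length (default 0.5).
#' @param stall_iter plateau stall cap; default `20 * length(x0)`.
#' @return List with `x` (best vertex), `value`, `iterations`,
#'   `evaluations`, and `converged` (`TRUE` unless stopped by the
#'   iteration cap).
#' @examples
#' nelder_mead(function(x) (x - 2)^2, 0)$x
#' @export
nelder_mead <- function(f, x0, tol = 1e-6, max_iter = 500, step = 0.5,
                        stall_iter = NULL) {
  x0 <- as.numeric(x0)
  n <- length(x0)
  if (is.null(stall_iter)) stall_iter <- 20L * n
  fx0 <- f(x0)
  if (!is.finite(fx0)) stop("objective is non-finite at the starting point")
  nev <- 1L

  verts <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) verts[i + 1, i] <- verts[i + 1, i] + step
  fv <- c(fx0, apply(verts[-1, , drop = FALSE], 1, f))
  nev <- nev + n

  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5
  iter <- 0L; stall <- 0L; converged <- FALSE

  repeat {
    ord <- order(fv)
    verts <- verts[ord, , drop = FALSE]; fv <- fv[ord]
    diam <- max(sqrt(rowSums(sweep(verts, 2, verts[1, ])^2)))
    if (diam < tol || stall >= stall_iter) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    best_before <- fv[1]

    centroid <- colMeans(verts[seq_len(n), , drop = FALSE])
    xr <- centroid + alpha * (centroid - verts[n + 1, ])
    fr <- f(xr); nev <- nev + 1L
    if (fr < fv[1]) {
      xe <- centroid + gamma * (xr - centroid)
      fe <- f(xe); nev <- nev + 1L
      if (fe < fr) { verts[n + 1, ] <- xe; fv[n + 1] <- fe }
      else         { verts[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      verts[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      if (fr < fv[n + 1]) { # outside contraction
        xc <- centroid + rho * (xr - centroid)
        fc <- f(xc); nev <- nev + 1L
        accept <- fc <= fr
      } else {              # inside contraction
        xc <- centroid - rho * (xr - centroid)
        fc <- f(xc); nev <- nev + 1L
        accept <- fc < fv[n + 1]
      }
      if (accept) { verts[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {        # shrink towards the best vertex
        for (i in 2:(n + 1)) {
          verts[i, ] <- verts[1, ] + sigma * (verts[i, ] - verts[1, ])
          fv[i] <- f(verts[i, ]); nev <- nev + 1L
        }
      }
    }
    stall <- if (min(fv) < best_before) 0L else stall + 1L
  }
  best <- which.min(fv)
  list(x = verts[best, ], value = fv[best], iterations = iter,
       evaluations = nev, converged = converged)
}

# Locate the lower edge of the plateau of the integer-valued objective
# that contains z_best, by step-down search plus bisection, and return a
# point `backoff` log-units above the edge (still on the plateau).  If a
# lower objective value is encountered while descending it is adopted and
# the descent continues from there, so the refined point is never worse.
refine_plateau <- function(obj, z_best, f_best, step = 0.5, backoff = 1,
                           lo_limit = log(1e-8), tol = 0.05) {
  z <- z_best; f0 <- f_best
  repeat {
    cand <- z - step
    if (cand < lo_limit) { below <- lo_limit; f_below <- NA; break }
    fc <- obj(cand)
    if (fc < f0) { f0 <- fc; z <- cand; next }   # descent found a better plateau
    if (fc > f0) { below <- cand; f_below <- fc; break }
    z <- cand
  }
  # bisect between `below` (off the plateau or at the limit) and `z` (on it)
  lo <- below; hi <- z
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (obj(mid) == f0) hi <- mid else lo <- mid
  }
  edge <- hi
  cand <- edge + backoff
  f_cand <- obj(cand)
  if (f_cand <= f0) list(z = cand, value = f_cand)
  else list(z = z, value = f0)
}

#' Learn kernel parameters by multi-start Nelder-Mead over CV-MCR
#'
#' Draws `n_starts` seeded initial points (each free parameter's log drawn
#' uniformly from `init_range`), runs [nelder_mead()] on the
#' cross-validated misclassification objective from each, and returns the
#' best final point; ties are broken by start order.  Because the
#' objective is a count bounded below by zero, the start loop terminates
#' early once a zero-misclassification point is found (later starts cannot
#' improve on it).
#'
#' Because the objective is an integer count, its minimizers form plateaus
#' — for the GRBF width an interval of log sigma^2 values with identical
#' CV error, often extending to very smooth kernels.  CV error alone
#' cannot distinguish points on the plateau, but for open-set use the
#' choice matters: an overly wide kernel keeps responding positively far
#' from its class and silently claims unseen compounds.  With a single
#' free parameter the search therefore ends with a plateau-regularization
#' step (`refine = TRUE`): the lower edge of the best plateau is located
#' by bisection and the returned parameter sits one log-unit above the
#' edge — the tightest kernel the CV data support, with a safety margin
#' against resampling variation.
#'
#' @param Z score matrix (samples x J).
#' @param y labels in `{-1, +1}`.
#' @param n_folds CV folds, stratified within each binary class
#'   (default 2).
#' @param n_starts number of initializations (default 30).
#' @param seed integer seed for folds and initial points.
#' @param kernel [kernel_params()] template for the fixed parameters
#'   (default GRBF with `C = 1`).
#' @param free free parameter names (default `"sigma2"`).
#' @param init_range range of the log-scale uniform initial draw,
#'   default `log(c(1e-3, 1e3))`.
#' @param nm_tol,nm_max_iter Nelder-Mead tolerances.
#' @param svm_tol SMO tolerance inside CV.
#' @param folds optional explicit fold assignment (overrides
#'   `n_folds`/`seed`-based folds).
#' @param refine logical; apply the plateau-regularization step after the
#'   multi-start search (single free parameter only).  Default `TRUE`.
#' @return An object of class `opt_result`: `best_params`, `best_cv_mcr`,
#'   `best_ztilde`, `start_results` (one row per executed start),
#'   `n_folds`, `seed`, `folds`.
#' @export
train_kernel_multistart <- function(Z, y, n_folds = 2, n_starts = 30,
                                    seed = 1,
                                    kernel = kernel_params("grbf", C = 1),
                                    free = "sigma2",
                                    init_range = log(c(1e-3, 1e3)),
                                    nm_tol = 1e-4, nm_max_iter = 200,
                                    svm_tol = 1e-3, folds = NULL,
                                    refine = TRUE) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed = seed)
  obj <- make_cv_objective(Z, y, folds, kernel, free, svm_tol)
  dim <- length(free)
  set.seed(mix_seed(seed, 503L))
  inits <- matrix(runif(n_starts * dim, init_range[1], init_range[2]),
                  nrow = n_starts, byrow = TRUE)
  rows <- vector("list", n_starts)
  best_i <- NA_integer_; best_val <- Inf
  for (s in seq_len(n_starts)) {
    res <- nelder_mead(obj, inits[s, ], tol = nm_tol, max_iter = nm_max_iter)
    rows[[s]] <- data.frame(start = s,
                            init = I(list(inits[s, ])),
                            final = I(list(res$x)),
                            objective = res$value)
    if (res$value < best_val) { best_val <- res$value; best_i <- s }
    if (best_val == 0) break
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  best_z <- rows$final[[best_i]]
  if (refine && length(free) == 1) {
    ref <- refine_plateau(obj, best_z, best_val)
    rows <- rbind(rows, data.frame(start = NA_integer_,
                                   init = I(list(best_z)),
                                   final = I(list(ref$z)),
                                   objective = ref$value))
    best_z <- ref$z
    best_val <- min(best_val, ref$value)
  }
  structure(list(best_params = ztilde_to_params(best_z, kernel, free),
                 best_cv_mcr = as.integer(best_val),
                 best_ztilde = best_z,
                 start_results = rows,
                 free = free, n_folds = n_folds, seed = seed,
                 folds = folds),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat("<opt_result> best CV misclassifications: ", x$best_cv_mcr, " (",
      nrow(x$start_results), " starts run); free: ",
      paste(x$free, collapse = ", "), " -> ",
      paste(format(exp(x$best_ztilde), digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
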