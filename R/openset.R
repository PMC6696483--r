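#' Train a one-vs-all open-set ensemble
#'
#' Fits PCA on the training spectra, then trains one binary kernel SVM per
#' known class (that class vs. the rest), learning each machine's kernel
#' parameters by multi-start Nelder-Mead over the cross-validated
#' misclassification count ([train_kernel_multistart()]).  The ensemble
#' classifies into the known classes plus an extra "unknown" class
#' `C + 1`; samples claimed by several machines are adjudicated by a
#' k-nearest-neighbour vote in PC space.
#'
#' @param train a labeled [thz_dataset()] with at least 2 classes.
#' @param J number of principal components (default 35).
#' @param n_folds CV folds for kernel training (default 2).
#' @param n_starts Nelder-Mead initializations per machine (default 30).
#' @param seed integer seed for folds and initializations.
#' @param kernel [kernel_params()] template (default GRBF, `C = 1`).
#' @param free free kernel parameters (default `"sigma2"`).
#' @param knn_k neighbours for the ambiguity vote; must be odd
#'   (default 3).
#' @param adapt logical; `FALSE` skips kernel training and uses the
#'   template parameters as-is (the untrained-kernel baseline).
#' @param ... further arguments passed to [train_kernel_multistart()].
#' @return An object of class `openset_ensemble` with fields `models`
#'   (one [svm_train()] model per class), `pca`, `class_ids`,
#'   `unknown_class_id`, `knn_k`, `train_scores`, `train_labels`,
#'   `opt_results`.
#' @export
train_ensemble <- function(train, J = 35, n_folds = 2, n_starts = 30,
                           seed = 1, kernel = kernel_params("grbf", C = 1),
                           free = "sigma2", knn_k = 3, adapt = TRUE, ...) {
  stopifnot(inherits(train, "thz_dataset"))
  if (knn_k < 1 || knn_k %% 2 == 0) stop("knn_k must be odd and >= 1")
  class_ids <- sort(unique(train$labels[train$labels > 0]))
  if (length(class_ids) < 2) stop("need at least 2 known classes")
  counts <- table(train$labels)
  small <- class_ids[counts[as.character(class_ids)] < n_folds]
  if (length(small) > 0)
    stop("class ", paste(small, collapse = ", "), " has fewer than ",
         n_folds, " samples; cannot build CV folds")

  pca <- fit_pca(train, J)
  Z <- pca_project(pca, train)
  models <- vector("list", length(class_ids))
  opts <- vector("list", length(class_ids))
  for (i in seq_along(class_ids)) {
    cl <- class_ids[i]
    y <- ifelse(train$labels == cl, 1, -1)
    k_cl <- kernel
    if (adapt) {
      opt <- tryCatch(
        train_kernel_multistart(Z, y, n_folds = n_folds,
                                n_starts = n_starts,
                                seed = mix_seed(seed, 601L, cl),
                                kernel = kernel, free = free, ...),
        error = function(e) stop("kernel training failed for class ", cl,
                                 ": ", conditionMessage(e)))
      k_cl <- opt$best_params
      opts[[i]] <- opt
    }
    models[[i]] <- tryCatch(
      svm_train(Z, y, k_cl, positive_class = cl),
      error = function(e) stop("SVM training failed for class ", cl, ": ",
                               conditionMessage(e)))
  }
  structure(list(models = models, pca = pca, class_ids = class_ids,
                 unknown_class_id = max(class_ids) + 1L,
                 knn_k = as.integer(knn_k),
                 train_scores = Z, train_labels = train$labels,
                 opt_results = opts),
            class = "openset_ensemble")
}

#' @export
print.openset_ensemble <- function(x, ...) {
  cat("<openset_ensemble> ", length(x$models), " one-vs-all machines (",
      x$models[[1]]$kernel$family, "), unknown class id ",
      x$unknown_class_id, ", kNN k = ", x$knn_k, "\n", sep = "")
  invisible(x)
}

# majority kNN vote among the claiming classes, Euclidean metric in PC
# space; vote ties broken by the smallest mean neighbour distance
knn_adjudicate <- function(ensemble, z, claimants) {
  pool <- which(ensemble$train_labels %in% claimants)
  d <- sqrt(colSums((t(ensemble$train_scores[pool, , drop = FALSE]) - z)^2))
  k <- min(ensemble$knn_k, length(pool))
  nn <- order(d)[seq_len(k)]
  votes <- table(ensemble$train_labels[pool][nn])
  top <- as.integer(names(votes)[votes == max(votes)])
  if (length(top) == 1) return(top)
  means <- vapply(top, function(cl)
    mean(d[nn][ensemble$train_labels[pool][nn] == cl]), numeric(1))
  top[which.min(means)]
}

#' Classify spectra with an open-set ensemble
#'
#' Each spectrum is projected onto the PCA model and scored by all binary
#' machines.  Exactly one positive decision value assigns its class; none
#' assigns the unknown class `C + 1`; several trigger a k-nearest-
#' neighbour vote (Euclidean metric in PC space) restricted to the
#' training samples of the claiming classes.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param X a [thz_dataset()], spectrum vector, or matrix of spectra
#'   (rows).
#' @return Integer vector of assigned class ids in
#'   `{class_ids, unknown_class_id}` with attribute `n_claims` (number of
#'   positive machines per sample).
#' @export
classify_samples <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "openset_ensemble"))
  Z <- pca_project(ensemble$pca, X)
  f <- vapply(ensemble$models, function(m) decision_value(m, Z),
              numeric(nrow(Z)))
  if (nrow(Z) == 1) f <- matrix(f, nrow = 1)
  out <- integer(nrow(Z))
  nclaims <- integer(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    claim <- which(f[i, ] > 0)
    nclaims[i] <- length(claim)
    out[i] <- if (length(claim) == 0) {
      ensemble$unknown_class_id
    } else if (length(claim) == 1) {
      ensemble$class_ids[claim]
    } else {
      knn_adjudicate(ensemble, Z[i, ], ensemble$class_ids[claim])
    }
  }
  attr(out, "n_claims") <- nclaims
  out
}

#' @rdname classify_samples
#' @param spectrum a single spectrum (numeric vector of length I).
#' @export
classify_sample <- function(ensemble, spectrum) {
  res <- classify_samples(ensemble, matrix(spectrum, nrow = 1))
  structure(res[1], n_claims = attr(res, "n_claims")[1])
}

#' Run the full leave-one-class-out open-set evaluation protocol
#'
#' For every class in turn, that class is withheld from training and plays
#' the unknown compound: the ensemble is trained once on the remaining
#' classes, then evaluated on a grid of test sets of `n_test` samples in
#' which the withheld class contributes a fraction ranging over
#' `fractions` (composed from a separate test pool via
#' [compose_test_set()], so training is independent of test composition).
#' A withheld-class sample counts as correct iff it is assigned the
#' unknown class `C + 1`; known-class samples count as correct iff
#' assigned their true class.
#'
#' @param train_pool labeled [thz_dataset()] used for training (all
#'   classes).
#' @param test_pool labeled [thz_dataset()] the test sets are drawn from
#'   (typically a later measurement session of the same compounds).
#' @param fractions outer-class fraction grid, default
#'   `seq(0, 1, by = 0.1)` (11 scenarios).
#' @param n_test test-set size per cell, default 30.
#' @param holdout_classes classes to withhold in turn; default all.
#' @param seed integer seed driving fold assignment, Nelder-Mead starts
#'   and test-set composition.
#' @param verbose print per-holdout progress.
#' @param ... arguments passed to [train_ensemble()] (`J`, `n_folds`,
#'   `n_starts`, `kernel`, `adapt`, ...).
#' @return An object of class `protocol_result`: `cells` (data.frame with
#'   one row per holdout x fraction: accuracy %, correct/unknown counts),
#'   and `grand_mean_accuracy` (%).
#' @export
run_protocol <- function(train_pool, test_pool,
                         fractions = seq(0, 1, by = 0.1), n_test = 30,
                         holdout_classes = NULL, seed = 1, verbose = FALSE,
                         ...) {
  stopifnot(inherits(train_pool, "thz_dataset"),
            inherits(test_pool, "thz_dataset"))
  all_classes <- sort(unique(train_pool$labels[train_pool$labels > 0]))
  if (length(all_classes) < 3) stop("protocol needs at least 3 classes")
  if (is.null(holdout_classes)) holdout_classes <- all_classes

  cells <- list()
  for (hold in holdout_classes) {
    ens <- train_ensemble(subset_samples(train_pool,
                                         train_pool$labels != hold),
                          seed = mix_seed(seed, 701L, hold), ...)
    known_pool <- subset_samples(test_pool,
                                 test_pool$labels != hold &
                                   test_pool$labels > 0)
    outer_pool <- subset_samples(test_pool, test_pool$labels == hold)
    for (fr in fractions) {
      ts <- compose_test_set(known_pool, outer_pool, n_test = n_test,
                             outer_fraction = fr,
                             seed = mix_seed(seed, 809L, hold,
                                             round(100 * fr)))
      pred <- classify_samples(ens, ts)
      truth <- ifelse(ts$labels == hold, ens$unknown_class_id, ts$labels)
      n_ok <- sum(pred == truth)
      cells[[length(cells) + 1]] <- data.frame(
        holdout = hold, outer_fraction = fr, n_test = n_test,
        n_correct = n_ok,
        n_unknown_assigned = sum(pred == ens$unknown_class_id),
        accuracy = 100 * n_ok / n_test)
    }
    if (verbose)
      message("holdout class ", hold, ": mean accuracy ",
              format(mean(vapply(utils::tail(cells, length(fractions)),
                                 function(c) c$accuracy, numeric(1))),
                     digits = 5), "%")
  }
  cells <- do.call(rbind, cells)
  structure(list(cells = cells,
                 grand_mean_accuracy = mean(cells$accuracy),
                 fractions = fractions,
                 holdout_classes = holdout_classes),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> ", nrow(x$cells), " cells (",
      length(x$holdout_classes), " holdouts x ", length(x$fractions),
      " outer fractions); grand mean accuracy ",
      format(x$grand_mean_accuracy, digits = 6), "%\n", sep = "")
  invisible(x)
}
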