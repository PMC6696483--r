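#' Save a trained open-set ensemble to a directory
#'
#' Writes a plain-text representation: an `ensemble.json` header (kernel
#' parameters, biases, class ids, kNN settings, PCA metadata) plus CSV
#' matrices for the PCA mean and loadings, each machine's support vectors
#' with dual coefficients, and the retained training scores used by the
#' kNN adjudicator.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "openset_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- ensemble$pca
  header <- list(
    format = "openthz-ensemble",
    version = 1L,
    class_ids = ensemble$class_ids,
    unknown_class_id = ensemble$unknown_class_id,
    knn_k = ensemble$knn_k,
    pca = list(J = ncol(p$loadings), I = length(p$mean_spectrum),
               eigenvalues = p$eigenvalues,
               explained_ratio = p$explained_ratio,
               n_train = p$n_train, total_variance = p$total_variance),
    models = lapply(ensemble$models, function(m)
      list(positive_class = m$positive_class, bias = m$bias,
           n_train = m$n_train, kernel = unclass(m$kernel))))
  jsonlite::write_json(header, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(data.frame(mean = p$mean_spectrum),
            file.path(dir, "pca_mean.csv"), row.names = FALSE)
  write.csv(as.data.frame(p$loadings), file.path(dir, "pca_loadings.csv"),
            row.names = FALSE)
  write.csv(data.frame(label = ensemble$train_labels,
                       as.data.frame(ensemble$train_scores)),
            file.path(dir, "train_scores.csv"), row.names = FALSE)
  for (m in ensemble$models) {
    df <- data.frame(dual_coeff = m$dual_coeffs, lambda = m$lambda,
                     as.data.frame(m$support_vectors))
    write.csv(df, file.path(dir, sprintf("model_class%d_sv.csv",
                                         m$positive_class)),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Load an open-set ensemble saved by [save_ensemble()]
#'
#' @param dir directory written by [save_ensemble()].
#' @return An `openset_ensemble`.
#' @export
load_ensemble <- function(dir) {
  if (!file.exists(file.path(dir, "ensemble.json")))
    stop("not an openthz ensemble directory (no ensemble.json): ", dir)
  hd <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                            simplifyVector = TRUE)
  if (!identical(hd$format, "openthz-ensemble"))
    stop("not an openthz ensemble directory: ", dir)
  loadings <- as.matrix(read.csv(file.path(dir, "pca_loadings.csv")))
  dimnames(loadings) <- NULL
  pca <- structure(list(
    mean_spectrum = read.csv(file.path(dir, "pca_mean.csv"))$mean,
    loadings = loadings,
    eigenvalues = hd$pca$eigenvalues,
    explained_ratio = hd$pca$explained_ratio,
    n_train = hd$pca$n_train, total_variance = hd$pca$total_variance),
    class = "pca_model")
  ts <- read.csv(file.path(dir, "train_scores.csv"))
  models <- lapply(seq_len(nrow(hd$models)), function(i) {
    mi <- hd$models[i, ]
    sv <- read.csv(file.path(dir, sprintf("model_class%d_sv.csv",
                                          mi$positive_class)))
    Z <- as.matrix(sv[, -(1:2), drop = FALSE]); dimnames(Z) <- NULL
    k <- mi$kernel
    structure(list(support_vectors = Z, dual_coeffs = sv$dual_coeff,
                   lambda = sv$lambda, bias = mi$bias,
                   kernel = kernel_params(k$family, d = k$d, beta0 = k$beta0,
                                          beta1 = k$beta1, sigma2 = k$sigma2,
                                          C = k$C),
                   positive_class = as.integer(mi$positive_class),
                   n_train = mi$n_train),
              class = "binary_svm")
  })
  Zt <- as.matrix(ts[, -1, drop = FALSE]); dimnames(Zt) <- NULL
  structure(list(models = models, pca = pca,
                 class_ids = as.integer(hd$class_ids),
                 unknown_class_id = as.integer(hd$unknown_class_id),
                 knn_k = as.integer(hd$knn_k),
                 train_scores = Zt, train_labels = as.integer(ts$label),
                 opt_results = NULL),
            class = "openset_ensemble")
}
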