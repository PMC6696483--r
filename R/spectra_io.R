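#' Read spectra (and optionally labels) from CSV
#'
#' The spectra file is comma-separated with a mandatory header: the first
#' column `wavenumber_cm-1` holds the wavenumber grid, every further column
#' is one sample's absorbance spectrum (column name = sample id).  The
#' optional labels file has columns `sample_id,class_label`.  Samples with
#' no label row get label 0 (unlabeled).  Decimal separator is `.`;
#' encoding UTF-8.
#'
#' @param spectra_path path to the spectra CSV.
#' @param labels_path optional path to the labels CSV.
#' @return A [thz_dataset()].
#' @export
read_spectra <- function(spectra_path, labels_path = NULL) {
  if (!file.exists(spectra_path)) stop("spectra file not found: ", spectra_path)
  raw <- read.csv(spectra_path, header = TRUE, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("spectra file must have a wavenumber column and ",
                          "at least one sample column")
  ids <- colnames(raw)[-1]
  if (anyDuplicated(ids))
    stop("duplicated sample ids in spectra header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(raw)))
  bad <- which(is.na(num) & !(toupper(as.matrix(raw)) %in% c("NA")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell in spectra file at data row ", bad[1, 1],
         ", column '", colnames(raw)[bad[1, 2]], "'")
  if (anyNA(num))
    stop("missing value in spectra file at data row ",
         which(is.na(num), arr.ind = TRUE)[1, 1])
  wn <- num[, 1]
  X <- t(num[, -1, drop = FALSE])

  labels <- rep(0L, length(ids))
  class_names <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
    lab <- read.csv(labels_path, header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
    if (!all(c("sample_id", "class_label") %in% colnames(lab)))
      stop("labels file must have columns sample_id,class_label")
    if (anyDuplicated(lab$sample_id))
      stop("duplicated sample ids in labels file: ",
           paste(unique(lab$sample_id[duplicated(lab$sample_id)]), collapse = ", "))
    m <- match(ids, lab$sample_id)
    as_int <- suppressWarnings(as.integer(lab$class_label))
    if (anyNA(as_int)) {
      # string labels: code by first appearance order
      class_names <- unique(lab$class_label)
      codes <- match(lab$class_label, class_names)
    } else {
      codes <- as_int
    }
    labels[!is.na(m)] <- codes[m[!is.na(m)]]
  }
  thz_dataset(wn, X, labels, class_names = class_names, sample_ids = ids)
}

#' Write spectra (and optionally labels) to CSV
#'
#' Inverse of [read_spectra()]; values are written with full double
#' precision so a write/read round trip is the identity to ~1e-15
#' relative error.
#'
#' @param dataset a [thz_dataset()].
#' @param spectra_path output path for the spectra CSV.
#' @param labels_path optional output path for the labels CSV.
#' @return `dataset`, invisibly.
#' @export
write_spectra <- function(dataset, spectra_path, labels_path = NULL) {
  stopifnot(inherits(dataset, "thz_dataset"))
  chr <- matrix(formatC(t(dataset$absorbance), digits = 17, format = "g"),
                nrow = ncol(dataset$absorbance))
  df <- data.frame(formatC(dataset$wavenumbers, digits = 17, format = "g"),
                   chr, check.names = FALSE)
  colnames(df) <- c("wavenumber_cm-1", dataset$sample_ids)
  write.csv(df, spectra_path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  if (!is.null(labels_path)) {
    lab <- data.frame(sample_id = dataset$sample_ids,
                      class_label = dataset$labels)
    write.csv(lab, labels_path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(dataset)
}

#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` folds separately within every class,
#' so per-class fold sizes differ by at most one.  The assignment is a
#' seeded, reproducible permutation.
#'
#' @param labels integer class labels (every distinct value is a stratum).
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold indices in `1..n_folds`, one per sample.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  set.seed(mix_seed(seed, 307L))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds)
      stop("class ", cl, " has only ", length(idx),
           " samples; cannot build ", n_folds, " folds")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# round-half-away-from-zero, so outer-class counts on a fraction grid are
# reproducible across platforms (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compose a mixed known/outer test set
#'
#' Draws `round(outer_fraction * n_test)` samples (round half away from
#' zero) from the outer pool — spectra of a compound absent from training —
#' and fills the remainder from the known pool with classes as balanced as
#' divisibility allows (classes cycled in label order, then the whole test
#' set shuffled).  Sampling is without replacement and seeded.
#'
#' @param known_pool a [thz_dataset()] of known-class spectra.
#' @param outer_pool a [thz_dataset()] of outer-class spectra.
#' @param n_test total test-set size, default 30.
#' @param outer_fraction fraction of outer-class samples in `[0, 1]`.
#' @param seed integer seed.
#' @return A [thz_dataset()] of `n_test` spectra with their true labels.
#' @export
compose_test_set <- function(known_pool, outer_pool, n_test = 30,
                             outer_fraction = 0, seed = 1) {
  stopifnot(inherits(known_pool, "thz_dataset"),
            outer_fraction >= 0, outer_fraction <= 1)
  n_outer <- as.integer(round_half_away(outer_fraction * n_test))
  n_known <- n_test - n_outer
  set.seed(mix_seed(seed, 401L))

  pick_outer <- integer(0)
  if (n_outer > 0) {
    if (is.null(outer_pool) || nrow(outer_pool$absorbance) < n_outer)
      stop("outer pool too small: need ", n_outer, " samples")
    pick_outer <- sample(seq_len(nrow(outer_pool$absorbance)), n_outer)
  }
  pick_known <- integer(0)
  if (n_known > 0) {
    classes <- sort(unique(known_pool$labels[known_pool$labels > 0]))
    if (length(classes) == 0) stop("known pool has no labeled samples")
    want <- table(factor(rep_len(classes, n_known), levels = classes))
    for (cl in classes) {
      idx <- which(known_pool$labels == cl)
      k <- as.integer(want[as.character(cl)])
      if (k == 0) next
      if (length(idx) < k)
        stop("known pool class ", cl, " too small: need ", k, " samples")
      pick_known <- c(pick_known, sample(idx, k))
    }
  }
  known <- if (n_known > 0) subset_samples(known_pool, pick_known) else NULL
  outer <- if (n_outer > 0) subset_samples(outer_pool, pick_outer) else NULL
  X <- rbind(if (!is.null(known)) known$absorbance,
             if (!is.null(outer)) outer$absorbance)
  lab <- c(if (!is.null(known)) known$labels, if (!is.null(outer)) outer$labels)
  ids <- c(if (!is.null(known)) known$sample_ids,
           if (!is.null(outer)) outer$sample_ids)
  perm <- sample.int(n_test)
  thz_dataset(known_pool$wavenumbers, X[perm, , drop = FALSE], lab[perm],
              class_names = known_pool$class_names, sample_ids = ids[perm])
}
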