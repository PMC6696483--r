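#' Spectra dataset container
#'
#' Bundles an absorbance matrix with its wavenumber grid and class labels.
#' Rows of `absorbance` are samples, columns are subbands (wavenumber bins).
#' Label 0 marks an unlabeled sample; labels 1..C index known classes.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, one per subband.
#' @param absorbance numeric matrix, samples x subbands; all values finite.
#' @param labels integer vector of class ids (0 = unlabeled), one per sample.
#'   Defaults to all 0.
#' @param class_names optional character vector naming classes 1..C.
#' @param sample_ids optional character vector of sample identifiers; default
#'   `s1, s2, ...`.
#' @return An object of class `thz_dataset` with fields `wavenumbers`,
#'   `absorbance`, `labels`, `class_names`, `sample_ids`.
#' @examples
#' d <- thz_dataset(seq(10, 70, length.out = 5),
#'                  matrix(rnorm(10), 2, 5), labels = c(1L, 2L))
#' nrow(d$absorbance)
#' @export
thz_dataset <- function(wavenumbers, absorbance, labels = NULL,
                        class_names = NULL, sample_ids = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (length(wavenumbers) != ncol(absorbance))
    stop("length(wavenumbers) must equal ncol(absorbance)")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  if (!all(is.finite(absorbance)))
    stop("absorbance contains non-finite values")
  n <- nrow(absorbance)
  if (is.null(labels)) labels <- rep(0L, n)
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("labels must have one entry per spectrum (", n, ")")
  if (any(labels < 0))
    stop("labels must be >= 0 (0 = unlabeled)")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 labels = labels, class_names = class_names,
                 sample_ids = as.character(sample_ids)),
            class = "thz_dataset")
}

#' @export
print.thz_dataset <- function(x, ...) {
  cl <- sort(unique(x$labels[x$labels > 0]))
  cat("<thz_dataset> ", nrow(x$absorbance), " spectra x ",
      ncol(x$absorbance), " subbands, ",
      format(min(x$wavenumbers), digits = 4), "-",
      format(max(x$wavenumbers), digits = 4), " cm^-1, ",
      length(cl), " labeled classes\n", sep = "")
  invisible(x)
}

#' Subset a spectra dataset by sample index
#'
#' @param dataset a [thz_dataset()].
#' @param idx integer or logical index over samples.
#' @return A `thz_dataset` with the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "thz_dataset"))
  thz_dataset(dataset$wavenumbers,
              dataset$absorbance[idx, , drop = FALSE],
              dataset$labels[idx],
              class_names = dataset$class_names,
              sample_ids = dataset$sample_ids[idx])
}
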