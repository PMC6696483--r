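#' Noise and variability configuration for synthetic spectra
#'
#' Controls the stochastic components layered on top of a class template
#' when a spectrum is sampled: multiplicative amplitude jitter per peak,
#' jitter of peak centers, a per-sample linear baseline drift, and additive
#' white noise per subband.  Defaults are calibrated so that classes remain
#' identifiable but single spectra are visibly noisy: 5% amplitude jitter,
#' 0.2 cm^-1 center jitter, additive noise at 1% of the nominal maximum
#' peak amplitude, and a drift slope SD of 1e-3 absorbance per cm^-1.
#'
#' @param amplitude_jitter_sd relative SD of multiplicative per-peak
#'   amplitude jitter (dimensionless).
#' @param center_jitter_sd SD of per-peak center jitter, cm^-1.
#' @param noise_sd SD of additive white noise per subband, absorbance units.
#' @param drift_slope_sd SD of the per-sample linear baseline drift slope,
#'   absorbance per cm^-1.
#' @param later_drift_slope fixed extra drift slope (absorbance per cm^-1)
#'   added to every spectrum drawn with `later = TRUE`, emulating spectra
#'   recorded in a later measurement session under slowly varying
#'   instrument conditions.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(amplitude_jitter_sd = 0.05,
                         center_jitter_sd = 0.2,
                         noise_sd = 0.01,
                         drift_slope_sd = 1e-3,
                         later_drift_slope = 1e-3) {
  vals <- c(amplitude_jitter_sd, center_jitter_sd, noise_sd, drift_slope_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all noise SDs must be finite and >= 0")
  structure(list(amplitude_jitter_sd = amplitude_jitter_sd,
                 center_jitter_sd = center_jitter_sd,
                 noise_sd = noise_sd,
                 drift_slope_sd = drift_slope_sd,
                 later_drift_slope = later_drift_slope),
            class = "noise_config")
}

# Peak-width range (FWHM, cm^-1) and amplitude range (absorbance) used by
# the template generator.  Widths are narrow relative to the 10-70 cm^-1
# band so that distinct compounds can carry distinguishing peaks.
.template_width_range <- c(0.8, 1.5)
.template_amp_range <- c(0.4, 1.0)
.template_slope_range <- c(0, 3e-3)

#' Separation between two class templates
#'
#' Measures how distinguishable two peak patterns are: for each template,
#' the largest distance from one of its peak centers to the nearest peak
#' center of the other template.  The returned value is the larger of the
#' two directed statistics, i.e. the distance by which the better
#' "signature" peak of the pair clears the other compound's pattern.
#'
#' @param a,b objects of class `class_template`.
#' @return A single non-negative number (cm^-1).
#' @export
template_separation <- function(a, b) {
  d <- abs(outer(a$peak_centers, b$peak_centers, "-"))
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

#' Generate a class template of absorption peaks
#'
#' Draws a reproducible set of Lorentzian peak positions, widths (FWHM) and
#' amplitudes for one compound class, plus a gentle linear baseline slope.
#' Templates are rejection-resampled so that every class differs from every
#' lower-numbered class (same seed) in at least one peak center by at least
#' twice the maximum peak width — each compound keeps a signature peak that
#' no other compound shadows, mimicking distinct spectral fingerprints.
#'
#' @param class_id positive integer class identifier.
#' @param n_peaks number of absorption peaks (>= 1), default 3.
#' @param wn_range numeric length-2 wavenumber interval in cm^-1,
#'   default `c(10, 70)`.
#' @param seed integer seed; the same `(class_id, seed)` pair always yields
#'   the identical template, independent of call order.
#' @param max_tries bounded number of resampling attempts per class before
#'   an error is raised (the range cannot host that many separable
#'   classes).
#' @return An object of class `class_template` with fields `class_id`,
#'   `peak_centers`, `peak_widths`, `peak_amplitudes`, `baseline_slope`.
#' @examples
#' tpl <- make_class_template(1, n_peaks = 3, seed = 42)
#' tpl$peak_centers
#' @export
make_class_template <- function(class_id, n_peaks = 3, wn_range = c(10, 70),
                                seed = 1, max_tries = 5000) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (length(wn_range) != 2 || diff(wn_range) <= 0)
    stop("wn_range must be a non-degenerate interval")
  templates <- .make_templates_upto(class_id, n_peaks, wn_range, seed, max_tries)
  templates[[class_id]]
}

# Builds templates for classes 1..class_id sequentially under one seed so
# that each new class is rejection-sampled against all earlier ones.  This
# makes make_class_template(k, ...) self-contained and deterministic.
.make_templates_upto <- function(class_id, n_peaks, wn_range, seed, max_tries) {
  sep_bound <- 2 * .template_width_range[2]
  margin <- .template_width_range[2]     # keep peaks off the band edges
  lo <- wn_range[1] + margin
  hi <- wn_range[2] - margin
  if (hi <= lo) stop("wn_range too narrow for the configured peak widths")
  templates <- vector("list", class_id)
  for (k in seq_len(class_id)) {
    set.seed(mix_seed(seed, 101L, k))
    prev_centers <- unlist(lapply(templates[seq_len(k - 1)],
                                  function(t) t$peak_centers))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      centers <- sort(runif(n_peaks, lo, hi))
      # peaks of one compound should not sit on top of each other
      if (n_peaks > 1 && min(diff(centers)) < sep_bound) next
      if (k == 1) { ok <- TRUE; break }
      sep_ok <- vapply(templates[seq_len(k - 1)], function(t) {
        d <- abs(outer(centers, t$peak_centers, "-"))
        max(apply(d, 1, min)) >= sep_bound && max(apply(d, 2, min)) >= sep_bound
      }, logical(1))
      if (all(sep_ok)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place ", k, " separable classes of ", n_peaks,
           " peaks in [", wn_range[1], ", ", wn_range[2], "] cm^-1 after ",
           max_tries, " attempts")
    widths <- runif(n_peaks, .template_width_range[1], .template_width_range[2])
    amps <- runif(n_peaks, .template_amp_range[1], .template_amp_range[2])
    amps[which.max(amps)] <- .template_amp_range[2]  # anchor the nominal max
    slope <- runif(1, .template_slope_range[1], .template_slope_range[2])
    templates[[k]] <- structure(
      list(class_id = as.integer(k), peak_centers = centers,
           peak_widths = widths, peak_amplitudes = amps,
           baseline_slope = slope),
      class = "class_template")
  }
  templates
}

# Noiseless template evaluation on a wavenumber grid: linear baseline plus
# Lorentzian peaks (height-normalized, FWHM parameterization).
.eval_template <- function(centers, widths, amps, slope, wn_grid, wn0) {
  y <- slope * (wn_grid - wn0)
  for (p in seq_along(centers)) {
    hw2 <- (widths[p] / 2)^2
    y <- y + amps[p] * hw2 / ((wn_grid - centers[p])^2 + hw2)
  }
  y
}

#' Sample one synthetic absorbance spectrum from a class template
#'
#' The spectrum is the template baseline plus the sum of its Lorentzian
#' peaks with per-peak amplitude and center jitter, plus a per-sample
#' linear drift line and additive white noise.  With all noise SDs zero the
#' result equals the deterministic template evaluation exactly.
#'
#' @param template a [make_class_template()] result.
#' @param noise a [noise_config()].
#' @param wn_grid strictly increasing wavenumber grid, cm^-1.
#' @param sample_seed integer seed for this draw; identical seeds give
#'   bit-identical spectra.
#' @param later logical; if `TRUE` the fixed `later_drift_slope` from the
#'   noise config is added, emulating a later measurement session.
#' @return Numeric vector of absorbances, `length(wn_grid)`.
#' @export
sample_spectrum <- function(template, noise, wn_grid, sample_seed,
                            later = FALSE) {
  stopifnot(inherits(template, "class_template"),
            inherits(noise, "noise_config"))
  if (any(diff(wn_grid) <= 0)) stop("wn_grid must be strictly increasing")
  set.seed(mix_seed(sample_seed, 211L, template$class_id))
  np <- length(template$peak_centers)
  amps <- template$peak_amplitudes *
    (1 + rnorm(np, 0, noise$amplitude_jitter_sd))
  amps <- pmax(amps, 0)
  centers <- template$peak_centers + rnorm(np, 0, noise$center_jitter_sd)
  drift <- rnorm(1, 0, noise$drift_slope_sd) +
    if (later) noise$later_drift_slope else 0
  wn0 <- wn_grid[1]
  y <- .eval_template(centers, template$peak_widths, amps,
                      template$baseline_slope, wn_grid, wn0)
  y <- y + drift * (wn_grid - mean(wn_grid))
  y + rnorm(length(wn_grid), 0, noise$noise_sd)
}

#' Generate a full synthetic spectra dataset
#'
#' Emulates a measurement campaign over `n_classes` compounds with
#' `n_per_class` replicate pellets each, digitized on `n_subbands`
#' wavenumber bins spanning 10-70 cm^-1.  Defaults (13 classes, 30 spectra
#' per class, 1194 subbands) reproduce the scale of a typical THz-TDS
#' compound-recognition study.
#'
#' @param n_classes number of compound classes (>= 1), default 13.
#' @param n_per_class spectra per class (>= 1), default 30.
#' @param n_subbands number of wavenumber bins (>= 1), default 1194.
#' @param noise a [noise_config()].
#' @param seed integer master seed; identical seeds yield bit-identical
#'   datasets.
#' @param n_peaks peaks per class template, default 3.
#' @param wn_range wavenumber interval, default `c(10, 70)` cm^-1.
#' @param later logical; mark the whole dataset as measured in a later
#'   session (adds the fixed extra drift to every spectrum).  Used to build
#'   drifted test pools distinct from the training campaign.
#' @param session integer tag separating independent measurement sessions
#'   under the same master seed (session 1 = training campaign).
#' @return A [thz_dataset()] with labels `1..n_classes`.
#' @examples
#' d <- generate_dataset(2, 3, 100, seed = 7)
#' table(d$labels)
#' @export
generate_dataset <- function(n_classes = 13, n_per_class = 30,
                             n_subbands = 1194, noise = noise_config(),
                             seed = 42, n_peaks = 3, wn_range = c(10, 70),
                             later = FALSE, session = if (later) 2L else 1L) {
  if (n_classes < 1 || n_per_class < 1 || n_subbands < 1)
    stop("all counts must be >= 1")
  wn_grid <- seq(wn_range[1], wn_range[2], length.out = n_subbands)
  templates <- .make_templates_upto(n_classes, n_peaks, wn_range, seed,
                                    max_tries = 5000)
  n <- n_classes * n_per_class
  X <- matrix(0, n, n_subbands)
  labels <- integer(n)
  ids <- character(n)
  row <- 0L
  for (k in seq_len(n_classes)) {
    for (r in seq_len(n_per_class)) {
      row <- row + 1L
      X[row, ] <- sample_spectrum(templates[[k]], noise, wn_grid,
                                  sample_seed = mix_seed(seed, session, k, r),
                                  later = later)
      labels[row] <- k
      ids[row] <- paste0("c", k, "_r", r, if (later) "_late" else "")
    }
  }
  thz_dataset(wn_grid, X, labels,
              class_names = paste0("BHC", seq_len(n_classes)),
              sample_ids = ids)
}
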