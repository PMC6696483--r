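Package: openthz
Title: Open-Set Recognition of Compounds from Terahertz Absorbance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Open-set classification of crystalline compounds from terahertz
    time-domain absorbance spectra. Spectra are reduced with principal
    component analysis and classified by a one-vs-all ensemble of soft-margin
    kernel support vector machines whose kernel parameters are learnt from
    the data by minimizing the cross-validated misclassification count with
    a multi-start Nelder-Mead search. Test samples claimed by no classifier
    are rejected into an extra "unknown" class; samples claimed by several
    classifiers are adjudicated by a k-nearest-neighbour vote. Includes a
    seeded generator of synthetic absorbance spectra (Lorentzian peak
    patterns, within-class jitter, baseline drift, additive noise) so the
    full leave-one-class-out evaluation protocol can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
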