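Package: meshmerge
Title: Merging and Quality Statistics for Fixed-Target Serial
    Synchrotron Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing integrated still-image reflection data
    from fixed-target serial synchrotron crystallography (SSX) raster
    scans. Implements unit-cell and space-group reciprocal-space math
    (d-spacings, asymmetric-unit mapping, systematic absences, unique
    reflection enumeration), per-image outlier rejection on spot count,
    resolution and unit-cell deviation, iterative per-image linear
    scaling with Monte-Carlo merging into half datasets, resolution-shell
    quality statistics (CC1/2, Rsplit, I/sigma, completeness, second
    intensity moment) with an automated resolution cutoff, Bayesian
    French-Wilson conversion of merged intensities to structure-factor
    amplitudes, fixed-target raster-scan planning and hit-rate
    bookkeeping, and a ground-truth-labelled synthetic still-data
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
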