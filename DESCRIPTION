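Package: doseQA
Title: Patient-Specific Dose-Recalculation QA with 3D Gamma Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for patient-specific dose-recalculation quality assurance
    in radiotherapy. Implements global 3D gamma-index evaluation of paired
    dose distributions with distance-to-agreement search and low-dose
    suppression, dose-volume-histogram metrics and organ-at-risk constraint
    checks, the relative mean-dose-difference statistic, and cohort-level
    log-linear regression of gamma passing rates against the volumes of air
    cavities and bony structures inside the target, including the 95%
    crossing-volume thresholds. A synthetic heterogeneous-phantom cohort
    generator emulates Monte Carlo reference doses with statistical noise
    and algorithm-specific heterogeneity error fields so every stage of the
    pipeline is exercisable without patient data. Reads DICOM RT Dose and
    RT Structure Set files as well as a plain-text grid exchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
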