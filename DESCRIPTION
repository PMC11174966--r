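Package: ecgph
Title: Neonatal ECG Morphology and Blood pH Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reproducible pipeline relating neonatal ECG morphology to blood-gas pH in
    the context of birth asphyxia monitoring. Extracts 10-second ECG segments adjacent to
    blood-gas sampling events, applies a Butterworth/notch/Savitzky-Golay filter cascade,
    detects QRS complexes with a Pan-Tompkins style detector, derives a representative
    beat per segment by principal component analysis, delineates the T wave, and computes
    ten morphological features (T/QRS, T amplitude, T slope and its ratios, HR, QT,
    Bazett-corrected QTc, RR average). Features are compared across acidosis, normal and
    alkalosis pH groups with a tie-corrected Kruskal-Wallis test and Dunn-Sidak post hoc
    comparisons with simultaneous intervals. A synthetic cohort generator with analytic
    beat-level ground truth makes every stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
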