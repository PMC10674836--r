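Package: irregularAF
Title: Two-Step Atrial Fibrillation Detection from Smartwatch ECG RR Irregularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Detects atrial fibrillation (AF) in short single-lead (smartwatch)
    ECG strips with a two-step rule: first flag an irregular ventricular rhythm
    using the count-RR statistic and the singular-value ratio of the Lorenz
    (Poincare) plot of RR intervals, then veto irregular rhythms that show
    "regularity within irregularity" as well-separated interval clusters found
    by constrained k-means. Includes wavelet-enhanced R-peak detection
    (maximal overlap discrete wavelet transform), ROC grid threshold tuning,
    diagnostic-accuracy metrics with McNemar's paired test, and a synthetic
    rhythm and ECG generator covering sinus rhythm, AF, premature
    atrial/ventricular complexes, AV block, and sick-sinus bradycardia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
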