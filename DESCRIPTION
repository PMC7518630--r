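Package: actirhythm
Title: Nonparametric Circadian Rhythm Statistics for High-Frequency Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes nonparametric summary statistics of rest-activity rhythms
    from high-frequency wrist accelerometry (ENMO) time series: interdaily
    stability (IS), phase-averaged intradaily variability (IV) with a
    subsampling-interval sweep, the detrended fluctuation analysis (DFA)
    scaling exponent (whole-series and separately for daytime and nighttime),
    and the proportion of variance (PoV) captured by narrow periodogram bands
    around the circadian fundamental frequency and its harmonics, together
    with a cosinor comparator. Includes readers for triaxial and ENMO CSV
    recordings, calendar-day gap cleaning, 24-hour average profiles, a
    synthetic generator of circadian ENMO-like series and reference noises
    (white, pink, Brownian) with known scaling exponents, and cohort-level
    reporting (group summaries, Mann-Whitney comparisons, metric correlation
    matrices).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'actirhythm-package.R'
    'utils.R'
    'enmo-io.R'
    'dfa.R'
    'nonparam.R'
    'spectral.R'
    'report.R'
    'synthetic.R'
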