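Package: cbfautoreg
Title: Quantitative Analysis of Cerebral Blood Flow Autoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the steady-state analysis of cerebral autoregulation in
    small-animal experiments. Computes absolute tissue perfusion (ml/100 g/min)
    from fluorescent-microsphere measurements with an arterial reference sample,
    calibrates relative laser-Doppler flowmetry traces (arbitrary units) to
    absolute flow using a microsphere baseline anchor, fits the mean arterial
    pressure versus cerebral blood flow relationship with a third-order
    polynomial, and extracts the lower and upper autoregulatory blood-pressure
    limits as the crossings of the fitted curve with a band of plus or minus 20
    percent of baseline flow. Includes group summaries (mean, standard error)
    with one-way ANOVA and Tukey multiple comparisons, and a synthetic-data
    generator producing triphasic pressure-flow sweeps and microsphere records
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
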