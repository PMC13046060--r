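Package: svprecision
Title: Precision Modelling for Small-Volume Kidney Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical precision modelling for image-based kidney dosimetry
    in molecular radiotherapy. Provides a generative model of partially
    correlated multiplicative measurement noise linking small-volume (SV) and
    whole-kidney-parenchyma (WKP) absorbed-dose estimates, the relative
    difference precision statistic and its pooled standard deviation over
    averaged SV subsets, a bounded nonlinear least-squares fit of the power
    law U(k) = alpha * k^-beta + gamma whose asymptote gamma estimates the
    residual WKP imprecision, normalization-factor (ratio) estimation with
    standard errors, rank-sum comparison of precision between SV sizes, a
    calibrated synthetic-cohort generator for simulation studies, and a
    command-line pipeline (simulate, analyze, fit, report) over long-format
    dose tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
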