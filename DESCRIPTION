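Package: lipochrom
Title: Biomimetic Chromatography Lipophilicity Indices and GA-MLR QSRR
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for converting fast-gradient chromatographic retention
    data into lipophilicity and biomimetic binding indices (CHI, CHI LogP,
    CHI_IAM, logK_HSA, percent HSA binding), comparing computed and
    experimental lipophilicity scales (correlation matrices,
    minimum-descriptor census, Ward hierarchical clustering, PCA), and
    building Quantitative Structure-Retention Relationship (QSRR) models by
    genetic-algorithm descriptor selection wrapped around multiple linear
    regression, with a full validation battery (leave-one-out Q2, external
    R2 and RMSE, Lin's concordance correlation coefficient) and a
    Williams-plot applicability domain.  Ships the chromatographic and
    computed-LogP measurements for a 26-compound library of ipsapirone
    derivatives as plain-text fixtures, plus generators for synthetic
    descriptor matrices, calibration runs and correlated index tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
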