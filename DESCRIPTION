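Package: lgchart
Title: Lindley-Geometric Distribution and Bootstrap Percentile Control Charts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two-parameter Lindley-Geometric (LG) lifetime
    distribution and for statistical process control of its percentiles.
    Provides density, distribution, quantile (via the lower branch of the
    Lambert W function) and random generation functions, series moments,
    maximum-likelihood fitting with goodness-of-fit statistics, parametric
    bootstrap percentile control limits for phase-I charting, phase-II
    subgroup monitoring, and Monte-Carlo estimation of average run lengths
    and parameter-sensitivity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pracma, fitdistrplus, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
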