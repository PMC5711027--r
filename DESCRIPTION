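Package: metabomatchr
Title: Metabolite Identification from Genetic Association Pseudospectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks candidate metabolites whose reference 1H-NMR
    spectra best explain a genetic-association pseudospectrum, i.e. the
    per-feature effect sizes and standard errors obtained by regressing
    binned NMR metabolome features on a genetic variant. Implements
    chi-squared and Z match statistics over chemical-shift match sets in
    peak and multiplet mode, shrinkage decorrelation restricted to feature
    neighborhoods, 2-compound and directional (+/-) scoring variants,
    ranked score tables with results figures, and a simulation framework
    (genotype and metabolome generation, per-feature association, replicate
    rank percentiles) for power analysis without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
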