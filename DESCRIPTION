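Package: admixtime
Title: Dating Population Admixture from Ancestry Covariance Decay
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the time of population admixture from one or more
    (possibly single) diploid genomes by fitting an exponential decay with an
    affine term to the genome-wide covariance of ancestry-informative site
    weights, computed against allele frequencies from two reference panels.
    Handles ancient-DNA features: pseudo-haploid genotype calls and high rates
    of missing data. Includes EIGENSTRAT text-format input/output, a fast
    autocorrelation (FFT) path for the binned covariance, weighted
    leave-one-chromosome-out block jackknife standard errors, a goodness-of-fit
    gate, and a haplotype-copying simulator of admixed genomes from synthetic
    Balding-Nichols source panels for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
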