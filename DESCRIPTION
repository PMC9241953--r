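Package: apmix
Title: Bait-Normalized Mixture-Model Scoring of AP-MS Pulldowns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores prey proteins in affinity-purification mass-spectrometry
    (AP-MS) experiments for membership in a bait protein's complex. Summed
    peptide counts are normalized by protein length and by the bait's own
    normalized abundance in each assay, pooled across replicate pulldowns on
    the log2 scale, and modelled with a one-dimensional Gaussian mixture
    fitted by expectation-maximization. Each protein receives the posterior
    probability of belonging to the high-abundance component; proteins with
    posterior above 0.5 and at least five raw peptide counts are called
    in-complex. Includes strict tabular readers and writers, a synthetic
    pulldown generator with ground truth for validation, a transcript
    phase-sorting filter for companion expression data, and a reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
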