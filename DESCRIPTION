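Package: summedstates
Title: Summed-State Reconstruction and Comparison of Person Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether multivoxel neural representations of
    people can be reconstructed as frequency-weighted sums of mental-state
    activity patterns, and for comparing that summed-state account against a
    trait-dimension account across neural, rating, text, choice, and
    reaction-time measures of interpersonal similarity. Includes dual
    normalization of state-frequency ratings, matched/unmatched reconstruction
    scoring, representational similarity analysis with Fisher-transformed
    group tests, semi-partial correlations and dependent-correlation
    difference tests, split-half reliability with disattenuation, choice and
    reaction-time models with participant-cluster bootstrap contrasts, and a
    fully seeded synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
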