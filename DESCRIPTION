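Package: infodem
Title: Infodemiology of Patient Attitudes on Social Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for mining patient attitudes toward medical
    treatments from social-media corpora: duplicate-post spam-account
    filtering, dictionary-based subtopic tagging with Gini-index term
    discrimination, lexicon-based three-class sentiment scoring, Granger
    causality between daily term-mention and sentiment series, and
    quadratically weighted Cohen's kappa for rater-agreement validation.
    Includes a seeded synthetic-corpus generator with known ground truth
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
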