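Package: gesturelaws
Title: Linguistic Laws in Great Ape Gesture Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests of linguistic laws (Zipf's law of brevity, the
    Menzerath-Altmann law, and compression of mean code length) in timed
    streams of animal gesture tokens. Provides segmentation of token
    streams into rapid sequences by an inter-token gap threshold,
    repertoire and sequence-composition summaries, permutation-based
    brevity and compression tests, Menzerath-Altmann power-law fits,
    intraclass-correlation reliability, hierarchical mixed-effects
    regressions of log gesture duration with full/null predictive
    comparison, and a synthetic token-stream generator with known
    ground-truth parameters for end-to-end validation and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
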