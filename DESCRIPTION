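Package: rhocis
Title: Combinatorial Cis-Regulatory Logic of Drosophila Rhodopsin Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the combinatorial cis-regulatory logic that
    restricts Drosophila rhodopsin expression to specific photoreceptor
    subtypes. Provides IUPAC consensus and position-weight-matrix scanning of
    promoter sequences with a normalized (percent-of-maximum) PWM similarity
    score, cross-species motif conservation calling on multi-species promoter
    alignments, in-silico construction of hybrid promoters and RCSI/RCSII swap
    constructs with validation against mutagenesis primers, a combinatorial
    transcription-factor logic that predicts and classifies per-subtype
    reporter expression outcomes, per-retina co-expression quantification with
    Mann-Whitney comparisons, and seeded synthetic-data generators (promoters
    with planted motifs, multi-species alignments with controlled motif fates,
    rhabdomere count tables) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
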