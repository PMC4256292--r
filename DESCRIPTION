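Package: mutspectra
Title: Mutation Spectra, Strand Asymmetry and Mismatch-Repair Efficiency
    from Reporter-Gene Fluctuation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing forward-mutation reporter assays in yeast:
    Luria-Delbruck fluctuation analysis (median and p0 estimators with
    nonparametric confidence limits), mutation-spectrum classification and
    site-specific rate estimation, hotspot detection against a wild-type
    baseline, assignment of replication errors to leading- or lagging-strand
    synthesis under a stated dNTP pool imbalance, mismatch-repair correction
    factors between repair-proficient and msh2-deficient backgrounds,
    homopolymer-run annotation, and a seeded synthetic-data generator that
    emulates Luria-Delbruck colony counts and mechanistically structured
    mutation spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
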