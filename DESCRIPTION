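Package: specshift
Title: Open Modification Search Strategies on Theoretical Peptide Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An evaluation framework for open modification search (OMS) on
    in-silico peptide spectra. Digests protein FASTA databases with trypsin,
    builds reversed-sequence decoys, generates annotated b/y theoretical
    spectra, and matches every bait spectrum against a merged target/decoy
    database with a fragment-mass inverted index. Best peptide-spectrum
    matches are selected either by the raw shared peaks count or after
    realigning the hit spectrum by the precursor mass difference at the best
    single shift location (shift SPC). Result quality is measured by
    target/decoy false discovery rates, a Green/Orange/Red explainability
    classification of each match, and the low information peaks rate (LIPR).
    A seeded synthetic proteome and planted-modification generator makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
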