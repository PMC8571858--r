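Package: herbarcode
Title: ITS Barcoding and QC of Herbarium and Fresh Plant Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for character-based DNA barcoding of herbarium and extant
    plant specimens using the nuclear ribosomal internal transcribed spacers
    (ITS1 and ITS2). Provides specimen quality-control summaries (DNA purity
    ratios, amplification and sequencing success rates, age regressions),
    annotation transfer of ITS1/5.8S/ITS2 intervals onto aligned sequences,
    detection of species-diagnostic SNP and deletion sites on a 5.8S-masked
    multiple alignment, barcode-based classification of query sequences,
    neighbor-joining distance trees with column-bootstrap support,
    monophyly-based flagging of putatively misidentified accessions, and a
    seed-deterministic synthetic-data generator that emulates the statistical
    structure of herbarium ITS collections for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
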