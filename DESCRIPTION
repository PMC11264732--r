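Package: cashcandi
Title: Quantification of Circulating Tumor DNA from Cell-Free DNA
    Methylation Profiles
Version: 0.1.0
Authors@R:
    person("cashcandi", "developers", email = "cashcandi@example.org",
           role = c("aut", "cre"))
Description: Discovers cancer-specific hypermethylated (and hypomethylated)
    regions from tissue and healthy-plasma methylation count tables, scores
    plasma samples by counting methylation-dense reads fully contained in
    those regions (a counts-per-million normalised candidate-read index),
    validates the index by in-silico dilution of tumor reads into healthy
    plasma, and evaluates cohort classification and longitudinal
    monitoring. A deterministic synthetic-data generator makes the whole
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
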