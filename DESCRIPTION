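Package: resistscan
Title: Positional Enrichment Scans and Resistance Quantification for Drug-Resistant Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates candidate drug-resistance loci by scanning cytoband
    regions for clusters of downregulated miRNA/mRNA probes with a one-sided
    Fisher exact (hypergeometric tail) test and building Manhattan tables;
    quantifies drug resistance as IC50 fold changes estimated from
    dose-response regression of viability on log concentration, including
    censored (">Cmax") results; detects miRNA seed (nucleotides 2-8)
    complementary sites in 3'-UTR sequences with canonical site-type
    classification; and performs qPCR relative quantification by the
    calibrated standard-curve method with reference-gene normalization.
    Includes a deterministic synthetic-data generator that plants a
    coordinately downregulated locus, known IC50s and known seed sites so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
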