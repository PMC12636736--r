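Package: trioscan
Title: Trio-Based Autosomal Recessive Candidate Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Filtering pipeline for identifying candidate genes under an
    autosomal recessive inheritance model from family trio sequencing data.
    Reads PED pedigrees and VCF variant calls (SNV/indel genotypes and
    copy-number records), extracts variants with the carrier-parent /
    homozygous-proband genotype pattern, classifies functional impact from
    Sequence Ontology consequence terms, aggregates candidates by gene,
    and validates or excludes candidates by segregation consistency across
    extended pedigrees. Includes a seeded Mendelian pedigree simulator that
    generates genome-wide background variation with a planted fully
    penetrant recessive causal variant and recessive copy-number deletions,
    plus small descriptive summaries of group behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
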